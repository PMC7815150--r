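# Sequence plumbing: FASTA IO, strand-aware slicing, spliced CDS extraction
# and translation. All genome coordinates are 1-based inclusive on the
# forward strand; "transcription order" for minus-strand features means
# decreasing forward coordinate.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read a FASTA file into a named character vector
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' wrapped sequence lines are joined and residues uppercased.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`; stored as an attribute and
#'   used to pick the Biostrings reader.
#' @return Named character vector of sequences with attribute `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "nucleotide") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id in %s: %s", path,
                  ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    warn(sprintf("empty sequence(s) in %s: %s", path,
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path; if `NULL` the FASTA text is returned invisibly
#'   instead of written.
#' @param width Line-wrap width.
#' @return The FASTA text, invisibly.
#' @export
write_fasta <- function(seqs, path = NULL, width = 60L) {
  lines <- unlist(purrr::imap(as.list(seqs), function(s, id) {
    body <- if (nzchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    } else {
      character()
    }
    c(paste0(">", id), body)
  }), use.names = FALSE)
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(lines, path)
  invisible(txt)
}

seq_slice <- function(genome, scaffold, start, end) {
  s <- genome[[scaffold]]
  if (is.null(s)) abort(sprintf("scaffold '%s' not in genome", scaffold))
  if (start < 1L || end > nchar(s) || start > end) {
    abort(sprintf("slice [%d,%d] out of bounds for scaffold '%s' (len %d)",
                  start, end, scaffold, nchar(s)))
  }
  substr(s, start, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the spliced coding sequence of an exon chain
#'
#' @param genome Named character vector of scaffold sequences.
#' @param scaffold Scaffold id.
#' @param exons Tibble/data.frame with `start`, `end` (1-based inclusive,
#'   forward strand), sorted ascending.
#' @param strand `"+"` or `"-"`; minus-strand chains are reverse-complemented
#'   so the result always reads 5' to 3' on the coding strand.
#' @return Character scalar CDS.
#' @export
spliced_cds <- function(genome, scaffold, exons, strand = "+") {
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- paste(
    mapply(function(s, e) seq_slice(genome, scaffold, s, e),
           exons$start, exons$end),
    collapse = ""
  )
  if (strand == "-") cds <- revcomp(cds) else cds
}

#' Translate a CDS, rendering in-frame stops as '*'
#'
#' A trailing partial codon (frameshifted CDS) is dropped.
#'
#' @param cds Character scalar of nucleotides.
#' @return Character scalar of amino acids.
#' @export
translate_cds <- function(cds) {
  usable <- nchar(cds) - nchar(cds) %% 3L
  if (usable < 3L) return("")
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, usable)),
                          no.init.codon = TRUE)
  ))
}

# Two coding-strand nucleotides immediately following, in transcription
# direction, the base at forward position `pos`.
tx_dinuc_after <- function(genome, scaffold, pos, strand) {
  len <- nchar(genome[[scaffold]])
  if (strand == "+") {
    if (pos + 2L > len) return(NA_character_)
    seq_slice(genome, scaffold, pos + 1L, pos + 2L)
  } else {
    if (pos - 2L < 1L) return(NA_character_)
    revcomp(seq_slice(genome, scaffold, pos - 2L, pos - 1L))
  }
}

# Two coding-strand nucleotides immediately preceding, in transcription
# direction, the base at forward position `pos`.
tx_dinuc_before <- function(genome, scaffold, pos, strand) {
  len <- nchar(genome[[scaffold]])
  if (strand == "+") {
    if (pos - 2L < 1L) return(NA_character_)
    seq_slice(genome, scaffold, pos - 2L, pos - 1L)
  } else {
    if (pos + 2L > len) return(NA_character_)
    revcomp(seq_slice(genome, scaffold, pos + 1L, pos + 2L))
  }
}

# Codon read in coding orientation whose first base sits `offset` codons
# upstream (negative) or downstream (positive) of the given forward-strand
# anchor position. Used by the START/STOP terminal scans.
tx_codon_at <- function(genome, scaffold, pos, strand) {
  len <- nchar(genome[[scaffold]])
  if (strand == "+") {
    if (pos < 1L || pos + 2L > len) return(NA_character_)
    seq_slice(genome, scaffold, pos, pos + 2L)
  } else {
    if (pos > len || pos - 2L < 1L) return(NA_character_)
    revcomp(seq_slice(genome, scaffold, pos - 2L, pos))
  }
}

# aa <-> nt arithmetic, centralized (1-based, phase-0 frame).
aa_to_nt_len <- function(aa) 3L * as.integer(aa)
nt_to_aa_len <- function(nt) as.integer(ceiling(nt / 3))
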