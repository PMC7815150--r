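# Synthetic tandem OR arrays with ground truth. Scaffolds carry implanted
# multi-exon genes (ATG-initiated, stop-terminated CDS split by gt..ag
# introns) in tandem arrangement, plus matching alignment records exhibiting
# the pathologies the pipeline repairs: redundant decoy queries per locus,
# fragmented alignments split at an intron with the fragment boundaries
# wrongly extended into it, and overlapping query spans at the junction.

#' Simulation parameters
#'
#' Defaults emulate the Hymenoptera OR regime: 4-9 exons per gene and
#' introns capped well below the stringent 2000-nt alignment cutoff, with
#' tandem copies separated by sub-kilobase to few-kilobase gaps.
#'
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   config.
#' @param n_scaffolds,genes_per_scaffold Array layout.
#' @param exons_per_gene Integer range (inclusive) of exons per gene.
#' @param exon_len_aa Range of exon lengths in codons.
#' @param intron_len Range of intron lengths (nt); max must be <= 2000.
#' @param intergenic_gap Range of gaps between tandem copies (nt).
#' @param flank Background padding at scaffold ends (nt).
#' @param pseudogene_fraction Fraction of genes receiving one pseudogenizing
#'   mutation (in-frame TGA or a 1-nt frameshift, chosen at random).
#' @param fraction_fragmented Fraction of genes whose self-alignment is
#'   split at a random intron into two fragments.
#' @param fragment_overlap_k Range of query-overlap sizes k (aa) for
#'   fragmented genes.
#' @param ensure_unique_splice Re-draw intron-end bases so the true gt/ag
#'   pair is the unique valid candidate in the stitching window (makes
#'   exact-recovery checks well-posed).
#' @param n_decoy_queries Decoy (mutated-copy) queries aligned per gene.
#' @param decoy_substitution_rate Amino-acid substitution rate for decoys.
#' @param minus_strand_fraction Fraction of genes implanted on the minus
#'   strand.
#' @return A list of class `or_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 5L,
                       genes_per_scaffold = 4L,
                       exons_per_gene = c(4L, 9L),
                       exon_len_aa = c(45L, 90L),
                       intron_len = c(80L, 1500L),
                       intergenic_gap = c(500L, 3000L),
                       flank = 400L,
                       pseudogene_fraction = 0,
                       fraction_fragmented = 0,
                       fragment_overlap_k = c(3L, 8L),
                       ensure_unique_splice = TRUE,
                       n_decoy_queries = 1L,
                       decoy_substitution_rate = 0.05,
                       minus_strand_fraction = 0.3) {
  stopifnot(
    n_scaffolds >= 1L, genes_per_scaffold >= 0L,
    all(exons_per_gene >= 1L), diff(exons_per_gene) >= 0L,
    all(exon_len_aa >= 2L), all(intron_len >= 40L),
    max(intron_len) <= 2000L,
    all(intergenic_gap >= 1L), flank >= 0L,
    pseudogene_fraction >= 0, pseudogene_fraction <= 1,
    fraction_fragmented >= 0, fraction_fragmented <= 1,
    all(fragment_overlap_k >= 1L),
    n_decoy_queries >= 0L,
    decoy_substitution_rate >= 0, decoy_substitution_rate <= 1,
    minus_strand_fraction >= 0, minus_strand_fraction <= 1
  )
  structure(as.list(environment()), class = "or_sim_config")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# Non-stop codons, grouped by the amino acid they encode.
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- vapply(codons, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE))
  }, character(1L))
  split(codons[aa != "*"], aa[aa != "*"])
}

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

runif_int <- function(range) {
  if (range[1L] == range[length(range)]) return(as.integer(range[1L]))
  sample(seq(range[1L], range[length(range)]), 1L)
}

#' Generate a synthetic OR-family bundle with ground truth
#'
#' @param config An [sim_config()].
#' @return A list of class `or_simulation`: `genome` (named character),
#'   `proteins` (self + decoy queries), `transcripts` (truth annotation
#'   tibble), `genes` (per-gene truth ledger incl. defects and fragmented
#'   junctions), `alignments` ([alignment_hits()] ledger of every emitted
#'   record) and `exonerate_text`.
#' @export
simulate_or_family <- function(config = sim_config()) {
  stopifnot(inherits(config, "or_sim_config"))
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  ct <- codon_table()
  genome <- character()
  gene_rows <- list()
  tx_rows <- list()
  hit_rows <- list()
  proteins <- character()

  for (s in seq_len(cfg$n_scaffolds)) {
    scaf <- sprintf("scaffold_%02d", s)
    parts <- rand_dna(cfg$flank)
    offset <- nchar(parts)
    for (g in seq_len(cfg$genes_per_scaffold)) {
      gid <- sprintf("OR_s%02d_g%02d", s, g)
      strand <- if (stats::runif(1L) < cfg$minus_strand_fraction) "-" else "+"
      gene <- build_gene(gid, cfg, ct)
      glen <- nchar(gene$seq)
      ins <- if (strand == "+") gene$seq else revcomp(gene$seq)
      map <- function(s0, e0) {
        if (strand == "+") c(offset + s0, offset + e0) else
          c(offset + glen - e0 + 1L, offset + glen - s0 + 1L)
      }
      # truth transcript (exons include the stop codon)
      ex_fwd <- t(mapply(function(a, b) map(a, b),
                         gene$exons$start, gene$exons$end))
      tx_rows[[length(tx_rows) + 1L]] <- tibble(
        transcript_id = paste0(gid, "_t1"), gene_id = gid,
        scaffold = scaf, strand = strand, source = "truth",
        exons = list(arrange(tibble(start = as.integer(ex_fwd[, 1L]),
                                    end = as.integer(ex_fwd[, 2L])),
                             .data$start))
      )
      proteins[gid] <- gene$protein

      frag_intron <- c(NA_integer_, NA_integer_)
      if (!is.null(gene$frag)) {
        fi <- map(gene$frag$intron_local[1L], gene$frag$intron_local[2L])
        frag_intron <- as.integer(fi)
      }
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        gene_id = gid, scaffold = scaf, strand = strand,
        n_exons = nrow(gene$exons), protein_len = nchar(gene$protein),
        pseudo = !is.null(gene$defect), defect = gene$defect %||% NA_character_,
        fragmented = !is.null(gene$frag),
        overlap_k = if (!is.null(gene$frag)) gene$frag$k else NA_integer_,
        frag_intron_start = frag_intron[1L], frag_intron_end = frag_intron[2L]
      )

      # alignment records: self (possibly fragmented) + decoys
      frag_sets <- alignment_fragment_sets(gene)
      for (fs in frag_sets) {
        hit_rows[[length(hit_rows) + 1L]] <-
          local_segments_to_hit(fs, gid, scaf, strand, map,
                                score = 5 * (max(fs$q_end) - min(fs$q_start) + 1L))
      }
      for (dcy in seq_len(cfg$n_decoy_queries)) {
        did <- sprintf("decoy_%s_%d", gid, dcy)
        proteins[did] <- mutate_protein(gene$protein,
                                        cfg$decoy_substitution_rate)
        for (fs in frag_sets) {
          trimmed <- trim_segments(fs)
          hit_rows[[length(hit_rows) + 1L]] <-
            local_segments_to_hit(trimmed, did, scaf, strand, map,
                                  score = 3 * (max(trimmed$q_end) -
                                               min(trimmed$q_start) + 1L) +
                                    sample(0:9, 1L))
        }
      }
      parts <- paste0(parts, ins,
                      if (g < cfg$genes_per_scaffold)
                        rand_dna(runif_int(cfg$intergenic_gap)) else "")
      offset <- nchar(parts)
    }
    parts <- paste0(parts, rand_dna(cfg$flank))
    genome[scaf] <- parts
  }

  alignments <- if (length(hit_rows)) {
    h <- bind_rows(hit_rows)
    h$hit_id <- sprintf("hit_%05d", seq_len(nrow(h)))
    alignment_hits(h)
  } else {
    empty_hits()
  }
  transcripts <- if (length(tx_rows)) bind_rows(tx_rows) else
    empty_transcripts()
  genes <- if (length(gene_rows)) bind_rows(gene_rows) else tibble()
  attr(genome, "alphabet") <- "nucleotide"
  attr(proteins, "alphabet") <- "protein"

  structure(
    list(config = cfg, genome = genome, proteins = proteins,
         transcripts = transcripts, genes = genes, alignments = alignments,
         exonerate_text = format_exonerate(alignments)),
    class = "or_simulation"
  )
}

# Build one gene in local coding coordinates (1-based on the gene's own
# sense sequence): [exon1][intron1]...[exonN], codon-aligned exons, ATG
# start, stop codon in the last exon. Applies at most one pseudogenizing
# mutation and (optionally) prepares a fragmented self-alignment whose true
# gt/ag pair is unique in the stitching window.
build_gene <- function(gid, cfg, ct) {
  n_ex <- runif_int(cfg$exons_per_gene)
  aa_len <- vapply(seq_len(n_ex), function(i) runif_int(cfg$exon_len_aa),
                   integer(1L))
  total_aa <- sum(aa_len)
  protein <- paste(c("M", sample(AA20, total_aa - 1L, replace = TRUE)),
                   collapse = "")
  res <- strsplit(protein, "")[[1L]]
  codons <- vapply(res, function(a) {
    opts <- ct[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L))
  codons[1L] <- "ATG"
  stopcdn <- sample(STOP_CODONS, 1L)

  defect <- NULL
  frameshift_exon <- NA_integer_
  if (stats::runif(1L) < cfg$pseudogene_fraction) {
    defect <- sample(c("inframe_stop", "frameshift"), 1L)
    if (defect == "inframe_stop") {
      pos <- sample(seq(2L, total_aa - 1L), 1L)
      codons[pos] <- "TGA"
    } else {
      frameshift_exon <- sample(seq_len(n_ex), 1L)
    }
  }

  cum <- cumsum(aa_len)
  exon_nt <- lapply(seq_len(n_ex), function(i) {
    idx <- seq(if (i == 1L) 1L else cum[i - 1L] + 1L, cum[i])
    s0 <- paste(codons[idx], collapse = "")
    if (i == n_ex) s0 <- paste0(s0, stopcdn)
    if (identical(i, frameshift_exon) || (!is.na(frameshift_exon) &&
                                          i == frameshift_exon)) {
      mid <- nchar(s0) %/% 2L
      s0 <- paste0(substr(s0, 1L, mid - 1L), substr(s0, mid + 1L, nchar(s0)))
    }
    s0
  })
  introns <- lapply(seq_len(max(0L, n_ex - 1L)), function(i) {
    len <- runif_int(cfg$intron_len)
    paste0("GT", rand_dna(len - 4L), "AG")
  })

  pieces <- character()
  exon_start <- integer(n_ex); exon_end <- integer(n_ex)
  pos <- 0L
  for (i in seq_len(n_ex)) {
    exon_start[i] <- pos + 1L
    pos <- pos + nchar(exon_nt[[i]])
    exon_end[i] <- pos
    pieces <- c(pieces, exon_nt[[i]])
    if (i < n_ex) {
      pieces <- c(pieces, introns[[i]])
      pos <- pos + nchar(introns[[i]])
    }
  }
  seq <- paste(pieces, collapse = "")
  exons <- tibble(start = exon_start, end = exon_end)

  frag <- NULL
  if (n_ex >= 2L && stats::runif(1L) < cfg$fraction_fragmented) {
    j <- if (n_ex == 2L) 1L else sample(seq_len(n_ex - 1L), 1L)
    k <- runif_int(cfg$fragment_overlap_k)
    ka <- as.integer(ceiling(k / 2)); kb <- k - ka
    frag <- list(j = j, k = k, ka = ka, kb = kb,
                 intron_local = c(exon_end[j] + 1L, exon_start[j + 1L] - 1L))
    if (cfg$ensure_unique_splice) {
      seq <- enforce_unique_splice(seq, exons, j, ka, kb)
    }
  }
  list(seq = seq, exons = exons, protein = protein, defect = defect,
       frag = frag, aa_len = aa_len)
}

# Mutate intron-interior bases to 'C' until donor_offset = 3*kb is the only
# cut in the 3k-nt window flanked by gt..ag ('C' can destroy but never
# create a GT or AG on the coding strand).
enforce_unique_splice <- function(seq, exons, j, ka, kb) {
  W <- 3L * (ka + kb)
  e_claim <- exons$end[j] + 3L * ka        # claimed end of fragment A's exon
  s_claim <- exons$start[j + 1L] - 3L * kb # claimed start of fragment B's
  intron <- c(exons$end[j] + 1L, exons$start[j + 1L] - 1L)
  protected <- c(intron[1L], intron[1L] + 1L, intron[2L] - 1L, intron[2L])
  mutable <- function(p) {
    p >= intron[1L] && p <= intron[2L] && !(p %in% protected)
  }
  d_true <- 3L * kb
  for (pass in 1:4) {
    changed <- FALSE
    for (d in 0:W) {
      if (d == d_true) next
      don <- c(e_claim - W + d + 1L, e_claim - W + d + 2L)
      acc <- c(s_claim + d - 2L, s_claim + d - 1L)
      don_ok <- substr(seq, don[1L], don[2L]) == "GT"
      acc_ok <- substr(seq, acc[1L], acc[2L]) == "AG"
      if (don_ok && acc_ok) {
        targets <- c(don, acc)
        hit <- targets[vapply(targets, mutable, logical(1L))]
        if (!length(hit)) {
          abort("cannot make splice candidate unique (no mutable base)")
        }
        substr(seq, hit[1L], hit[1L]) <- "C"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  seq
}

# Local-coordinate alignment segment sets for a gene: the self alignment,
# split at the fragmented intron when applicable, with the fragment
# boundaries wrongly extended into the intron (ka/kb codons per side). The
# stop codon is not aligned (protein queries end before it).
alignment_fragment_sets <- function(gene) {
  n_ex <- nrow(gene$exons)
  aa_cum <- cumsum(gene$aa_len)
  seg <- tibble(
    start = gene$exons$start,
    end = gene$exons$end,
    q_start = c(1L, aa_cum[-n_ex] + 1L),
    q_end = aa_cum
  )
  seg$end[n_ex] <- seg$end[n_ex] - 3L  # drop the stop codon
  if (is.null(gene$frag)) return(list(seg))
  j <- gene$frag$j; ka <- gene$frag$ka; kb <- gene$frag$kb
  a <- seg[seq_len(j), , drop = FALSE]
  b <- seg[seq(j + 1L, n_ex), , drop = FALSE]
  a$end[j] <- a$end[j] + 3L * ka
  a$q_end[j] <- a$q_end[j] + ka
  b$start[1L] <- b$start[1L] - 3L * kb
  b$q_start[1L] <- b$q_start[1L] - kb
  list(a, b)
}

# Inward-only boundary jitter for decoy alignments (whole codons, so decoy
# segments stay inside the gene's coverage islands).
trim_segments <- function(seg) {
  n <- nrow(seg)
  j1 <- sample(0:3, 1L); j2 <- sample(0:3, 1L)
  seg$start[1L] <- seg$start[1L] + 3L * j1
  seg$q_start[1L] <- seg$q_start[1L] + j1
  seg$end[n] <- seg$end[n] - 3L * j2
  seg$q_end[n] <- seg$q_end[n] - j2
  seg
}

mutate_protein <- function(protein, rate) {
  res <- strsplit(protein, "")[[1L]]
  hit <- which(stats::runif(length(res)) < rate)
  hit <- hit[hit > 1L]
  res[hit] <- sample(AA20, length(hit), replace = TRUE)
  paste(res, collapse = "")
}

# Map a local-coordinate segment set onto the scaffold and build one hit row.
local_segments_to_hit <- function(seg, query_id, scaffold, strand, map,
                                  score) {
  fwd <- t(mapply(function(a, b) map(a, b), seg$start, seg$end))
  segments <- tibble(
    t_start = as.integer(fwd[, 1L]), t_end = as.integer(fwd[, 2L]),
    q_start = as.integer(seg$q_start), q_end = as.integer(seg$q_end)
  )
  segments <- segments[if (strand == "+") order(segments$t_start) else
    order(-segments$t_start), , drop = FALSE]
  nt_before <- cumsum(c(0L, segments$t_end - segments$t_start + 1L))
  segments$phase <- as.integer(nt_before[seq_len(nrow(segments))] %% 3L)
  tibble(
    hit_id = NA_character_, query_id = query_id, target_id = scaffold,
    strand = strand, score = as.numeric(score),
    q_start = min(segments$q_start), q_end = max(segments$q_end),
    t_start = min(segments$t_start), t_end = max(segments$t_end),
    segments = list(segments)
  )
}

#' @export
print.or_simulation <- function(x, ...) {
  cat(sprintf(
    "<or_simulation> %d scaffold(s), %d gene(s) (%d pseudo, %d fragmented), %d alignment record(s)\n",
    length(x$genome), nrow(x$genes), sum(x$genes$pseudo),
    sum(x$genes$fragmented), nrow(x$alignments)))
  invisible(x)
}

#' Write a simulation bundle to disk
#'
#' @param sim An `or_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    proteins = file.path(dir, "proteins.fasta"),
    truth = file.path(dir, "truth.gff3"),
    alignments = file.path(dir, "alignments.exonerate")
  )
  write_fasta(sim$genome, paths[["genome"]])
  write_fasta(sim$proteins, paths[["proteins"]])
  write_gff3(sim$transcripts, paths[["truth"]], source = "truth")
  cat(sim$exonerate_text, file = paths[["alignments"]])
  invisible(paths)
}
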