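# GFF3 and BED12+1 input/output. Reading goes through rtracklayer; writing
# is deterministic text generation so that write -> parse -> write is a
# byte-level fixed point. GFF coordinates are 1-based inclusive; BED is
# 0-based half-open (the only place that convention appears).

#' Read transcript structures from a GFF3 file
#'
#' One row per mRNA/transcript feature; `exons` is a list-column of sorted,
#' non-overlapping intervals. Transcripts without exon children fall back to
#' their CDS children; transcripts with neither are dropped with a warning,
#' as are orphan exons whose Parent is unknown.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `transcript_id`, `gene_id`, `scaffold`,
#'   `strand`, `source`, `exons`.
#' @export
read_gff_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  if (!nrow(df)) return(empty_transcripts())
  df$type <- as.character(df$type)
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  parents <- if ("Parent" %in% names(df)) {
    purrr::map(df$Parent, as.character)
  } else {
    rep(list(character()), nrow(df))
  }

  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna_parent <- purrr::map_chr(parents[df$type %in% c("mRNA", "transcript")],
                                function(p) if (length(p)) p[1L] else NA_character_)
  is_child <- function(type) {
    idx <- which(df$type == type)
    out <- tibble(
      start = df$start[idx], end = df$end[idx],
      parent = purrr::map(parents[idx], identity)
    )
    tidyr::unnest(out, "parent")
  }
  exon_tab <- is_child("exon")
  cds_tab <- is_child("CDS")

  known <- mrna$ID[!is.na(mrna$ID)]
  orphan <- setdiff(unique(exon_tab$parent), known)
  # exons parented directly to genes (no mRNA) are also orphans here
  if (length(orphan)) {
    warn(sprintf("dropping %d exon(s) with unknown Parent (%s)",
                 sum(exon_tab$parent %in% orphan),
                 paste(utils::head(orphan, 3L), collapse = ", ")))
    exon_tab <- exon_tab[!exon_tab$parent %in% orphan, , drop = FALSE]
  }

  rows <- purrr::map(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    ex <- exon_tab[exon_tab$parent %in% tid, c("start", "end"), drop = FALSE]
    if (!nrow(ex)) ex <- cds_tab[cds_tab$parent %in% tid, c("start", "end"),
                                 drop = FALSE]
    if (!nrow(ex)) {
      warn(sprintf("transcript '%s' has no exon/CDS children; dropped", tid))
      return(NULL)
    }
    ex <- distinct(arrange(as_tibble(ex), .data$start))
    tibble(
      transcript_id = tid,
      gene_id = mrna_parent[i] %||% NA_character_,
      scaffold = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      source = as.character(mrna$source[i]),
      exons = list(tibble(start = as.integer(ex$start),
                          end = as.integer(ex$end)))
    )
  })
  out <- bind_rows(rows)
  if (!nrow(out)) return(empty_transcripts())
  out
}

empty_transcripts <- function() {
  tibble(transcript_id = character(), gene_id = character(),
         scaffold = character(), strand = character(),
         source = character(), exons = list())
}

#' Write transcript structures (or gene models) as GFF3
#'
#' Emits deterministic `gene`/`mRNA`/`exon`/`CDS` rows, sorted by scaffold,
#' start and id, so writing, re-reading with [read_gff_transcripts()] and
#' writing again reproduces the file byte for byte.
#'
#' @param x A transcript tibble (see [read_gff_transcripts()]) or an
#'   `or_models` tibble from the annotation pipeline.
#' @param path Optional output path.
#' @param source Value for the GFF source column; transcript tables keep
#'   their own `source` if present.
#' @return GFF3 text, invisibly when `path` is given.
#' @export
write_gff3 <- function(x, path = NULL, source = "olfactoR") {
  tx <- if (inherits(x, "or_models")) models_as_transcripts(x) else as_tibble(x)
  if (!"source" %in% names(tx) || all(is.na(tx$source))) tx$source <- source
  if (!"gene_id" %in% names(tx)) tx$gene_id <- NA_character_
  tx$gene_id <- dplyr::coalesce(tx$gene_id, paste0("gene:", tx$transcript_id))
  tx$start <- purrr::map_int(tx$exons, ~ min(.x$start))
  tx$end <- purrr::map_int(tx$exons, ~ max(.x$end))

  genes <- tx |>
    group_by(.data$gene_id, .data$scaffold, .data$strand, .data$source) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    arrange(.data$scaffold, .data$start, .data$end, .data$gene_id)

  lines <- "##gff-version 3"
  for (g in seq_len(nrow(genes))) {
    gi <- genes[g, ]
    lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              gi$scaffold, gi$source, gi$start, gi$end,
                              gi$strand, gi$gene_id))
    sub <- tx[tx$gene_id == gi$gene_id & tx$scaffold == gi$scaffold, ,
              drop = FALSE]
    sub <- arrange(sub, .data$start, .data$end, .data$transcript_id)
    for (t in seq_len(nrow(sub))) {
      ti <- sub[t, ]
      lines <- c(lines, sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                ti$scaffold, ti$source, ti$start, ti$end,
                                ti$strand, ti$transcript_id, ti$gene_id))
      ex <- arrange(ti$exons[[1L]], .data$start)
      stopifnot(all(ex$start <= ex$end))
      lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                ti$scaffold, ti$source, ex$start, ex$end,
                                ti$strand, ti$transcript_id))
      # phase: bases to skip at exon start to reach a codon boundary
      txo <- if (ti$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
      nt_before <- cumsum(c(0L, (ex$end - ex$start + 1L)[txo]))[seq_len(nrow(ex))]
      phase <- integer(nrow(ex))
      phase[txo] <- (3L - nt_before %% 3L) %% 3L
      lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                                ti$scaffold, ti$source, ex$start, ex$end,
                                ti$strand, phase, ti$transcript_id))
    }
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(txt)) }
  txt
}

models_as_transcripts <- function(models) {
  tibble(
    transcript_id = models$name,
    gene_id = paste0("gene:", models$name),
    scaffold = models$scaffold,
    strand = models$strand,
    source = "olfactoR",
    exons = purrr::map(models$exons, ~ arrange(.x[c("start", "end")], .data$start))
  )
}

#' Write gene models as BED12+1
#'
#' Twelve standard BED columns (0-based half-open, blocks from exons) plus a
#' 13th column carrying the model status string (completeness, start,
#' pseudogene flags, and the 7tm_6 domain count when available).
#'
#' @param models An `or_models` tibble.
#' @param path Optional output path.
#' @return BED text, invisibly when `path` is given.
#' @export
write_bed12 <- function(models, path = NULL) {
  if (nrow(models) && any(purrr::map_int(models$exons, nrow) == 0L)) {
    abort("model with no exons cannot be written")
  }
  models$.start <- purrr::map_int(models$exons, ~ min(.x$start))
  models <- arrange(models, .data$scaffold, .data$.start)
  models$.start <- NULL
  lines <- purrr::map_chr(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    ex <- arrange(m$exons[[1L]], .data$start)
    chrom_start <- min(ex$start) - 1L   # to 0-based
    chrom_end <- max(ex$end)            # half-open
    sizes <- ex$end - ex$start + 1L
    starts <- ex$start - 1L - chrom_start
    paste(c(
      m$scaffold, chrom_start, chrom_end, m$name, 0L, m$strand,
      chrom_start, chrom_end, "0", nrow(ex),
      paste(sizes, collapse = ","), paste(starts, collapse = ","),
      model_status_string(m)
    ), collapse = "\t")
  })
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (length(lines) == 0L) txt <- ""
  if (!is.null(path)) { writeLines(lines, path); return(invisible(txt)) }
  txt
}

model_status_string <- function(m) {
  parts <- c(
    m$completeness,
    if (isTRUE(m$has_start)) "start" else "no-start",
    if (length(m$defects[[1L]])) "pseudo" else "normal"
  )
  if ("n_7tm6" %in% names(m) && !is.na(m$n_7tm6)) {
    parts <- c(parts, sprintf("7tm_6:%d", m$n_7tm6))
  }
  paste(parts, collapse = ";")
}

#' Read a BED12(+1) file back into transcript structures
#'
#' The inverse of [write_bed12()] on exon structures; used mainly for
#' round-trip checking.
#'
#' @param path Path to a BED12 or BED12+1 file.
#' @return Transcript tibble as in [read_gff_transcripts()] (plus `status`
#'   when a 13th column is present).
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_transcripts())
  rows <- purrr::map(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) abort("BED line with fewer than 12 columns")
    chrom_start <- as.integer(f[2L])
    sizes <- as.integer(strsplit(f[11L], ",")[[1L]])
    starts <- as.integer(strsplit(f[12L], ",")[[1L]])
    ex <- tibble(start = chrom_start + starts + 1L,
                 end = chrom_start + starts + sizes)
    tibble(transcript_id = f[4L], gene_id = paste0("gene:", f[4L]),
           scaffold = f[1L], strand = f[6L], source = "olfactoR",
           exons = list(ex),
           status = if (length(f) >= 13L) f[13L] else NA_character_)
  })
  bind_rows(rows)
}

#' Write all pipeline outputs for a set of finalized gene models
#'
#' @param models An `or_models` tibble with `cds` and `protein` filled.
#' @param genome Named character vector of scaffold sequences (used for
#'   bounds checking).
#' @param dir Optional directory; when given, writes `annotation.gff3`,
#'   `annotation.bed`, `cds.fasta` and `proteins.fasta` there.
#' @return Named list with elements `gff3`, `bed12`, `cds_fasta`,
#'   `protein_fasta` (text), invisibly when `dir` is given.
#' @export
write_gene_models <- function(models, genome, dir = NULL) {
  if (nrow(models) && any(purrr::map_int(models$exons, nrow) == 0L)) {
    abort("model with no exons")
  }
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    len <- nchar(genome[[models$scaffold[i]]])
    stopifnot(all(ex$start >= 1L), all(ex$end <= len), all(ex$start <= ex$end))
  }
  out <- list(
    gff3 = write_gff3(models),
    bed12 = write_bed12(models),
    cds_fasta = write_fasta(setNames(models$cds, models$name)),
    protein_fasta = write_fasta(setNames(models$protein, models$name))
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(sub("\n$", "", out$gff3), file.path(dir, "annotation.gff3"))
    writeLines(sub("\n$", "", out$bed12), file.path(dir, "annotation.bed"))
    cat(out$cds_fasta, file = file.path(dir, "cds.fasta"))
    cat(out$protein_fasta, file = file.path(dir, "proteins.fasta"))
    return(invisible(out))
  }
  out
}
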