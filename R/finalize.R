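# Finalization of stitched models: boundary extension for the external
# refiner, START/STOP terminal scans, pseudogene defect detection,
# completeness classification, P1/P2 merging, isoform overlap resolution
# and naming.

#' Extend a hit's genomic span for refinement
#'
#' Each side extends by `min(span length, max_extension)` and is clamped to
#' the scaffold.
#'
#' @param start,end Model span (1-based inclusive).
#' @param scaffold_length Scaffold length (nt).
#' @param config An [or_config()].
#' @return Integer vector `c(start, end)` of the extended interval.
#' @export
extend_locus <- function(start, end, scaffold_length, config = or_config()) {
  span <- end - start + 1L
  ext <- min(span, config$max_extension)
  c(max(1L, start - ext), min(as.integer(scaffold_length), end + ext))
}

#' Classify a model as complete or partial
#'
#' @param protein_len Protein length in residues, terminal stop excluded.
#' @param config An [or_config()].
#' @return `"complete"` iff `protein_len >= config$min_complete_len`, else
#'   `"partial"`.
#' @export
classify_completeness <- function(protein_len, config = or_config()) {
  ifelse(protein_len >= config$min_complete_len, "complete", "partial")
}

# Terminal scans. Work in transcription direction: upstream of the first
# coding base for ATG (aborting at an intervening in-frame stop), downstream
# of the last coding base for a stop codon. Neither scan crosses a scaffold
# end. Returns the possibly-extended exon table plus flags.
scan_terminals <- function(exons, strand, genome, scaffold, config) {
  exons <- arrange(exons, .data$start)
  window <- config$terminal_search_window
  cds <- spliced_cds(genome, scaffold, exons, strand)
  has_start <- startsWith(cds, "ATG")
  if (!has_start) {
    for (j in seq_len(window)) {
      pos <- if (strand == "+") exons$start[1L] - 3L * j else
        exons$end[nrow(exons)] + 3L * j
      codon <- tx_codon_at(genome, scaffold, pos, strand)
      if (is.na(codon)) break
      if (codon %in% STOP_CODONS) break
      if (codon == "ATG") {
        if (strand == "+") exons$start[1L] <- exons$start[1L] - 3L * j else
          exons$end[nrow(exons)] <- exons$end[nrow(exons)] + 3L * j
        has_start <- TRUE
        break
      }
    }
  }
  usable <- nchar(cds) - nchar(cds) %% 3L
  has_stop <- usable >= 3L &&
    substr(cds, usable - 2L, usable) %in% STOP_CODONS
  if (!has_stop) {
    for (j in seq_len(window)) {
      pos <- if (strand == "+") exons$end[nrow(exons)] + 3L * (j - 1L) + 1L else
        exons$start[1L] - 3L * (j - 1L) - 1L
      codon <- tx_codon_at(genome, scaffold, pos, strand)
      if (is.na(codon)) break
      if (codon %in% STOP_CODONS) {
        if (strand == "+") exons$end[nrow(exons)] <-
            exons$end[nrow(exons)] + 3L * j else
          exons$start[1L] <- exons$start[1L] - 3L * j
        has_stop <- TRUE
        break
      }
    }
  }
  list(exons = exons, has_start = has_start, has_stop = has_stop)
}

#' Finalize stitched models into gene models
#'
#' Locates START and STOP codons within the terminal search window (20
#' codons by default), fills CDS and protein, records pseudogene defects
#' (in-frame stops strictly inside the CDS; frameshifts from non-modulo-3
#' CDS arithmetic) and classifies completeness. Finalization never shortens
#' a model.
#'
#' @param models Preliminary model tibble from [stitch_fragments()].
#' @param genome Named character vector of scaffold sequences.
#' @param config An [or_config()].
#' @param provenance Provenance label for these models (`"P1"` or `"P2"`).
#' @return An `or_models` tibble.
#' @export
finalize_models <- function(models, genome, config = or_config(),
                            provenance = "P1") {
  if (!nrow(models)) return(empty_models())
  rows <- purrr::map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    st <- scan_terminals(m$exons[[1L]], m$strand, genome, m$scaffold, config)
    exons <- st$exons
    cds <- spliced_cds(genome, m$scaffold, exons, m$strand)
    protein <- translate_cds(cds)
    defects <- m$defects[[1L]]
    if (nchar(cds) %% 3L != 0L) defects <- union(defects, "frameshift")
    body <- if (st$has_stop) substr(protein, 1L, nchar(protein) - 1L) else
      protein
    if (grepl("*", body, fixed = TRUE)) defects <- union(defects, "inframe_stop")
    protein_len <- nchar(body)
    span <- c(min(exons$start), max(exons$end))
    is_pseudo <- length(defects) > 0L
    n_ex <- nrow(exons)
    tibble(
      name = NA_character_, scaffold = m$scaffold, strand = m$strand,
      query_id = m$query_id, score = m$score,
      q_start = m$q_start, q_end = m$q_end,
      exons = list(tibble(start = as.integer(exons$start),
                          end = as.integer(exons$end))),
      n_exons = n_ex,
      start = as.integer(span[1L]), end = as.integer(span[2L]),
      has_start = st$has_start, has_stop = st$has_stop,
      defects = list(defects), pseudo = is_pseudo,
      cds = cds, protein = protein, protein_len = protein_len,
      completeness = unname(classify_completeness(protein_len, config)),
      provenance = provenance,
      source_hit_ids = m$source_hit_ids, junctions = m$junctions
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("or_models", class(tibble()))
  out
}

empty_models <- function() {
  out <- tibble(
    name = character(), scaffold = character(), strand = character(),
    query_id = character(), score = numeric(),
    q_start = integer(), q_end = integer(),
    exons = list(), n_exons = integer(), start = integer(), end = integer(),
    has_start = logical(), has_stop = logical(),
    defects = list(), pseudo = logical(),
    cds = character(), protein = character(), protein_len = integer(),
    completeness = character(), provenance = character(),
    source_hit_ids = list(), junctions = list()
  )
  class(out) <- c("or_models", class(tibble()))
  out
}

# Ranking used when one of two overlapping models must be retained:
# completeness, greater protein length, non-pseudogenous, presence of START,
# then P2 provenance, then leftmost start (determinism).
model_rank <- function(models) {
  order(
    models$completeness != "complete",
    -models$protein_len,
    models$pseudo,
    !models$has_start,
    models$provenance != "P2",
    models$start,
    models$name
  )
}

exonic_overlap_bases <- function(ex_a, ex_b) {
  ia <- IRanges::reduce(IRanges::IRanges(ex_a$start, ex_a$end))
  ib <- IRanges::reduce(IRanges::IRanges(ex_b$start, ex_b$end))
  sum(IRanges::width(IRanges::intersect(ia, ib)))
}

# Overlap fraction of two models relative to each: same-query pairs use the
# aligned query aa intervals (the duplicated-exon/isoform rule); pairs from
# different queries fall back to genomic exonic overlap.
overlap_fracs <- function(a, b) {
  if (!is.na(a$query_id) && identical(a$query_id, b$query_id)) {
    ov <- min(a$q_end, b$q_end) - max(a$q_start, b$q_start) + 1L
    ov <- max(0L, ov)
    c(ov / (a$q_end - a$q_start + 1L), ov / (b$q_end - b$q_start + 1L))
  } else {
    ov <- exonic_overlap_bases(a$exons[[1L]], b$exons[[1L]])
    c(ov / sum(a$exons[[1L]]$end - a$exons[[1L]]$start + 1L),
      ov / sum(b$exons[[1L]]$end - b$exons[[1L]]$start + 1L))
  }
}

# Should both models be kept (putative isoforms / duplicated exons)?
keep_both <- function(a, b, config) {
  if (!identical(a$scaffold, b$scaffold) || !identical(a$strand, b$strand)) {
    return(TRUE)
  }
  same_query <- !is.na(a$query_id) && identical(a$query_id, b$query_id)
  if (!same_query &&
      exonic_overlap_bases(a$exons[[1L]], b$exons[[1L]]) == 0L) {
    return(TRUE)
  }
  fr <- overlap_fracs(a, b)
  all(fr < config$isoform_overlap_frac)
}

#' Resolve overlapping models by the isoform rule
#'
#' Two models whose overlap is below the isoform threshold (default 20%) of
#' both are kept as putative isoforms/duplicated exons; otherwise the better
#' model wins (completeness, protein length, non-pseudogenous, START
#' presence, in that order).
#'
#' @param models An `or_models` tibble.
#' @param config An [or_config()].
#' @return Filtered `or_models` tibble.
#' @export
resolve_model_overlaps <- function(models, config = or_config()) {
  if (nrow(models) < 2L) return(models)
  ord <- model_rank(models)
  accepted <- integer()
  for (i in ord) {
    ok <- all(purrr::map_lgl(accepted, function(j) {
      keep_both(models[i, ], models[j, ], config)
    }))
    if (ok) accepted <- c(accepted, i)
  }
  out <- models[sort(accepted), , drop = FALSE]
  class(out) <- c("or_models", class(tibble()))
  out
}

#' Merge preliminary (P1) and refined (P2) models
#'
#' Models sharing any exonic base on the same strand compete and the better
#' one is retained; disjoint models are both kept.
#'
#' @param p1,p2 `or_models` tibbles (`p2` may be empty/NULL, in which case
#'   `p1` is returned unchanged).
#' @param config An [or_config()].
#' @return Merged `or_models` tibble.
#' @export
merge_p1_p2 <- function(p1, p2 = NULL, config = or_config()) {
  if (is.null(p2) || !nrow(p2)) return(p1)
  drop_p1 <- rep(FALSE, nrow(p1))
  keep_p2 <- rep(TRUE, nrow(p2))
  for (j in seq_len(nrow(p2))) {
    ov <- which(purrr::map_lgl(seq_len(nrow(p1)), function(i) {
      identical(p1$scaffold[i], p2$scaffold[j]) &&
        identical(p1$strand[i], p2$strand[j]) &&
        exonic_overlap_bases(p1$exons[[i]], p2$exons[[j]]) > 0L
    }))
    if (!length(ov)) next
    pair <- bind_rows(p1[ov, , drop = FALSE], p2[j, , drop = FALSE])
    best <- model_rank(pair)[1L]
    if (best == nrow(pair)) drop_p1[ov] <- TRUE else keep_p2[j] <- FALSE
  }
  out <- bind_rows(p1[!drop_p1, , drop = FALSE], p2[keep_p2, , drop = FALSE])
  class(out) <- c("or_models", class(tibble()))
  out
}

# Name models by genomic location with status suffixes: _NTE (no start),
# _PSE (pseudogene defects), _P (partial).
assign_model_names <- function(models) {
  if (!nrow(models)) return(models)
  models <- arrange(models, .data$scaffold, .data$start, .data$end)
  suffix <- paste0(
    ifelse(models$has_start, "", "_NTE"),
    ifelse(models$pseudo, "_PSE", ""),
    ifelse(models$completeness == "partial", "_P", "")
  )
  models$name <- sprintf("%s:%d-%d(%s)OR%d%s", models$scaffold, models$start,
                         models$end, models$strand, seq_len(nrow(models)),
                         suffix)
  models
}
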