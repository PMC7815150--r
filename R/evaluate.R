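# Annotation comparison at base, exon and locus level with a tolerance on
# the free ends of terminal exons (gffcompare-style semantics, fixed
# tolerance default 10 nt). Strand-aware throughout; internal exon
# boundaries must match exactly.

#' Compare a predicted annotation against a reference
#'
#' Semantics per level:
#' * **base** — TP = exonic bases shared on the same scaffold and strand,
#'   FN = reference-only bases, FP = prediction-only bases.
#' * **exon** — distinct exon intervals are matched one-to-one (greedy,
#'   left to right); boundaries must be identical except that a boundary
#'   which is a transcript-terminal free end in *both* exons may differ by
#'   up to `tolerance` nt.
#' * **locus** — transcripts are clustered into loci by exonic overlap; a
#'   reference locus is a TP iff at least one predicted transcript fully
#'   matches one of its transcripts (identical intron chain, terminal free
#'   ends within `tolerance`). Locus precision is the fraction of predicted
#'   loci with such a match.
#'
#' Also reported: percentages of reference exons/loci with zero predicted
#' overlap (missed) and of predicted exons/loci with zero reference overlap
#' (novel), and the matched-locus count.
#'
#' @param predicted,reference Transcript tibbles (see
#'   [read_gff_transcripts()]), `or_models` tibbles, or paths to GFF3 files.
#' @param tolerance Maximum displacement (nt) at terminal-exon free ends.
#' @return An object of class `or_eval`; `tidy()` gives the per-level
#'   TP/FP/FN/sensitivity/precision table, `glance()` the missed/novel/
#'   matching accounting.
#' @export
compare_annotations <- function(predicted, reference, tolerance = 10L) {
  pred <- as_transcripts(predicted)
  ref <- as_transcripts(reference)
  tolerance <- as.integer(tolerance)
  stopifnot(tolerance >= 0L)

  base <- base_level(pred, ref)
  pred_ex <- distinct_exons(pred)
  ref_ex <- distinct_exons(ref)
  exon_tp <- match_exons(pred_ex, ref_ex, tolerance)
  exon <- list(tp = exon_tp, fp = nrow(pred_ex) - exon_tp,
               fn = nrow(ref_ex) - exon_tp)

  pred_cl <- cluster_loci(pred)
  ref_cl <- cluster_loci(ref)
  match_mat <- transcript_match_matrix(pred, ref, tolerance)
  ref_tx_matched <- apply(match_mat, 2L, any)
  pred_tx_matched <- apply(match_mat, 1L, any)
  ref_loci_matched <- tapply_any(ref_tx_matched, ref_cl)
  pred_loci_matched <- tapply_any(pred_tx_matched, pred_cl)
  n_ref_loci <- length(ref_loci_matched)
  n_pred_loci <- length(pred_loci_matched)
  locus <- list(tp = sum(ref_loci_matched),
                fn = sum(!ref_loci_matched),
                fp = sum(!pred_loci_matched))

  levels <- tibble(
    level = c("base", "exon", "locus"),
    tp = c(base$tp, exon$tp, locus$tp),
    fp = c(base$fp, exon$fp, locus$fp),
    fn = c(base$fn, exon$fn, locus$fn)
  )
  levels$sensitivity <- 100 * levels$tp / (levels$tp + levels$fn)
  levels$precision <- 100 * levels$tp / (levels$tp + levels$fp)
  # locus precision follows the predicted side (one predicted locus may
  # match several reference loci)
  levels$precision[3L] <- 100 * sum(pred_loci_matched) / n_pred_loci

  missed_ex <- zero_overlap_frac(ref_ex, pred_ex)
  novel_ex <- zero_overlap_frac(pred_ex, ref_ex)
  missed_loci <- zero_overlap_locus_frac(ref, ref_cl, pred_ex)
  novel_loci <- zero_overlap_locus_frac(pred, pred_cl, ref_ex)

  structure(
    list(
      levels = levels,
      missed_exons_pct = 100 * missed_ex, novel_exons_pct = 100 * novel_ex,
      missed_loci_pct = 100 * missed_loci, novel_loci_pct = 100 * novel_loci,
      matching_loci = locus$tp, tolerance = tolerance,
      n_pred_transcripts = nrow(pred), n_ref_transcripts = nrow(ref),
      n_pred_loci = n_pred_loci, n_ref_loci = n_ref_loci
    ),
    class = "or_eval"
  )
}

as_transcripts <- function(x) {
  if (inherits(x, "or_models")) return(models_as_transcripts(x))
  if (is.character(x) && length(x) == 1L) return(read_gff_transcripts(x))
  as_tibble(x)
}

tapply_any <- function(flags, cl) {
  if (!length(cl)) return(logical())
  as.logical(tapply(flags, cl, any))
}

base_level <- function(pred, ref, by_strand = TRUE) {
  keys <- unique(c(strata_keys(pred), strata_keys(ref)))
  tp <- fp <- fn <- 0L
  for (k in keys) {
    rp <- reduced_ranges(pred, k)
    rr <- reduced_ranges(ref, k)
    tp <- tp + sum(IRanges::width(IRanges::intersect(rp, rr)))
    fp <- fp + sum(IRanges::width(IRanges::setdiff(rp, rr)))
    fn <- fn + sum(IRanges::width(IRanges::setdiff(rr, rp)))
  }
  list(tp = tp, fp = fp, fn = fn)
}

strata_keys <- function(tx) {
  if (!nrow(tx)) return(character())
  unique(paste(tx$scaffold, tx$strand, sep = "\r"))
}

reduced_ranges <- function(tx, key) {
  sel <- paste(tx$scaffold, tx$strand, sep = "\r") == key
  if (!any(sel)) return(IRanges::IRanges())
  ex <- bind_rows(tx$exons[sel])
  IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
}

# Distinct exon intervals with transcript-terminal free-end flags (flags are
# OR-ed over duplicate intervals).
distinct_exons <- function(tx) {
  if (!nrow(tx)) {
    return(tibble(scaffold = character(), strand = character(),
                  start = integer(), end = integer(),
                  free_start = logical(), free_end = logical()))
  }
  rows <- purrr::map(seq_len(nrow(tx)), function(i) {
    ex <- arrange(tx$exons[[i]], .data$start)
    n <- nrow(ex)
    tibble(scaffold = tx$scaffold[i], strand = tx$strand[i],
           start = ex$start, end = ex$end,
           free_start = seq_len(n) == 1L, free_end = seq_len(n) == n)
  })
  bind_rows(rows) |>
    group_by(.data$scaffold, .data$strand, .data$start, .data$end) |>
    summarise(free_start = any(.data$free_start),
              free_end = any(.data$free_end), .groups = "drop") |>
    arrange(.data$scaffold, .data$strand, .data$start, .data$end)
}

boundary_ok <- function(a, b, free_a, free_b, e) {
  if (free_a && free_b) abs(a - b) <= e else a == b
}

# Greedy left-to-right one-to-one exon matching; returns the TP count.
match_exons <- function(pred_ex, ref_ex, e) {
  if (!nrow(pred_ex) || !nrow(ref_ex)) return(0L)
  used <- rep(FALSE, nrow(ref_ex))
  tp <- 0L
  for (i in seq_len(nrow(pred_ex))) {
    for (j in seq_len(nrow(ref_ex))) {
      if (used[j]) next
      if (pred_ex$scaffold[i] != ref_ex$scaffold[j] ||
          pred_ex$strand[i] != ref_ex$strand[j]) next
      if (boundary_ok(pred_ex$start[i], ref_ex$start[j],
                      pred_ex$free_start[i], ref_ex$free_start[j], e) &&
          boundary_ok(pred_ex$end[i], ref_ex$end[j],
                      pred_ex$free_end[i], ref_ex$free_end[j], e)) {
        used[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  tp
}

# Cluster transcripts into loci by exonic overlap (same scaffold & strand);
# returns an integer component label per transcript row.
cluster_loci <- function(tx) {
  n <- nrow(tx)
  if (!n) return(integer())
  ex <- bind_rows(purrr::map(seq_len(n), function(i) {
    e <- tx$exons[[i]]
    tibble(i = i, scaffold = tx$scaffold[i], strand = tx$strand[i],
           start = e$start, end = e$end)
  }))
  edges <- NULL
  for (k in unique(paste(ex$scaffold, ex$strand, sep = "\r"))) {
    sub <- ex[paste(ex$scaffold, ex$strand, sep = "\r") == k, , drop = FALSE]
    ir <- IRanges::IRanges(sub$start, sub$end)
    ov <- IRanges::findOverlaps(ir, ir)
    a <- sub$i[S4Vectors::queryHits(ov)]
    b <- sub$i[S4Vectors::subjectHits(ov)]
    keep <- a < b
    if (any(keep)) edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(unique(edges)))
  as.integer(igraph::components(g)$membership)
}

transcript_introns <- function(ex) {
  ex <- ex[order(ex$start), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  cbind(ex$end[-n] + 1L, ex$start[-1L] - 1L)
}

transcripts_match <- function(ex_p, strand_p, scaf_p, ex_r, strand_r, scaf_r,
                              e) {
  if (scaf_p != scaf_r || strand_p != strand_r) return(FALSE)
  ip <- transcript_introns(ex_p)
  ir <- transcript_introns(ex_r)
  if (nrow(ip) != nrow(ir)) return(FALSE)
  if (nrow(ip) && !all(ip == ir)) return(FALSE)
  abs(min(ex_p$start) - min(ex_r$start)) <= e &&
    abs(max(ex_p$end) - max(ex_r$end)) <= e
}

transcript_match_matrix <- function(pred, ref, e) {
  m <- matrix(FALSE, nrow = nrow(pred), ncol = nrow(ref))
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(ref))) {
      m[i, j] <- transcripts_match(pred$exons[[i]], pred$strand[i],
                                   pred$scaffold[i], ref$exons[[j]],
                                   ref$strand[j], ref$scaffold[j], e)
    }
  }
  m
}

# Fraction of exons in `a_ex` with zero base overlap from `b_ex`.
zero_overlap_frac <- function(a_ex, b_ex) {
  if (!nrow(a_ex)) return(NaN)
  miss <- purrr::map_lgl(seq_len(nrow(a_ex)), function(i) {
    sel <- b_ex$scaffold == a_ex$scaffold[i] & b_ex$strand == a_ex$strand[i]
    !any(b_ex$start[sel] <= a_ex$end[i] & b_ex$end[sel] >= a_ex$start[i])
  })
  mean(miss)
}

# Fraction of loci (transcript clusters of `tx`) none of whose exonic bases
# are covered by `other_ex`.
zero_overlap_locus_frac <- function(tx, cl, other_ex) {
  if (!length(cl)) return(NaN)
  locus_missed <- purrr::map_lgl(sort(unique(cl)), function(c0) {
    idx <- which(cl == c0)
    all(purrr::map_lgl(idx, function(i) {
      ex <- tx$exons[[i]]
      sel <- other_ex$scaffold == tx$scaffold[i] &
        other_ex$strand == tx$strand[i]
      !any(purrr::map_lgl(seq_len(nrow(ex)), function(r) {
        any(other_ex$start[sel] <= ex$end[r] & other_ex$end[sel] >= ex$start[r])
      }))
    }))
  })
  mean(locus_missed)
}

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.or_eval <- function(x, ...) {
  cat(sprintf("<or_eval> tolerance e = %d nt\n", x$tolerance))
  lv <- x$levels
  cat(sprintf("  %-6s %8s %8s %8s %12s %10s\n",
              "level", "TP", "FP", "FN", "sensitivity", "precision"))
  for (i in seq_len(nrow(lv))) {
    cat(sprintf("  %-6s %8d %8d %8d %11.1f%% %9.1f%%\n", lv$level[i],
                lv$tp[i], lv$fp[i], lv$fn[i],
                round_half_up(lv$sensitivity[i]),
                round_half_up(lv$precision[i])))
  }
  cat(sprintf("  missed exons %.1f%% | novel exons %.1f%% | missed loci %.1f%% | novel loci %.1f%% | matching loci %d\n",
              round_half_up(x$missed_exons_pct),
              round_half_up(x$novel_exons_pct),
              round_half_up(x$missed_loci_pct),
              round_half_up(x$novel_loci_pct), x$matching_loci))
  invisible(x)
}

#' @describeIn compare_annotations Per-level TP/FP/FN and percentages.
#' @param x An `or_eval` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.or_eval <- function(x, ...) x$levels

#' @describeIn compare_annotations One-row missed/novel/matching accounting.
#' @exportS3Method generics::glance
glance.or_eval <- function(x, ...) {
  tibble(
    missed_exons_pct = x$missed_exons_pct,
    novel_exons_pct = x$novel_exons_pct,
    missed_loci_pct = x$missed_loci_pct,
    novel_loci_pct = x$novel_loci_pct,
    matching_loci = x$matching_loci,
    n_pred_transcripts = x$n_pred_transcripts,
    n_ref_transcripts = x$n_ref_transcripts,
    n_pred_loci = x$n_pred_loci,
    n_ref_loci = x$n_ref_loci,
    tolerance = x$tolerance
  )
}
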