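# "Virtual scaffold" coverage tracks: per-nucleotide counts of aligned exon
# bases. Maximal positive runs (alignment islands) demarcate candidate gene
# loci and separate tandem copies. Introns contribute no coverage.

#' Build per-nucleotide alignment-coverage tracks
#'
#' For every scaffold a virtual track of the same length starts at 0 and each
#' aligned exon segment increments its positions by one. Introns inside an
#' alignment do not contribute.
#'
#' @param hits An [alignment_hits()] tibble.
#' @param scaffold_lengths Named integer vector of scaffold lengths (nt).
#' @return An object of class `or_coverage`: a named list of integer
#'   run-length encodings, one per scaffold.
#' @export
build_coverage <- function(hits, scaffold_lengths) {
  stopifnot(!is.null(names(scaffold_lengths)))
  tracks <- purrr::imap(as.list(scaffold_lengths), function(len, scaf) {
    sub <- hits[hits$target_id == scaf, , drop = FALSE]
    if (!nrow(sub)) return(S4Vectors::Rle(0L, as.integer(len)))
    segs <- bind_rows(sub$segments)
    if (any(segs$t_start < 1L | segs$t_end > len)) {
      off <- which(purrr::map_lgl(sub$segments, function(s) {
        any(s$t_start < 1L | s$t_end > len)
      }))
      abort(sprintf("hit '%s': segment outside scaffold '%s' bounds [1,%d]",
                    sub$hit_id[off[1L]], scaf, as.integer(len)))
    }
    IRanges::coverage(IRanges::IRanges(segs$t_start, segs$t_end),
                      width = as.integer(len))
  })
  structure(tracks, class = "or_coverage")
}

#' @export
print.or_coverage <- function(x, ...) {
  cat(sprintf("<or_coverage> %d scaffold(s)\n", length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %s: length %d, %d covered base(s), max depth %d\n",
                nm, length(x[[nm]]), sum(as.vector(x[[nm]]) > 0L),
                max(c(0L, S4Vectors::runValue(x[[nm]])))))
  }
  invisible(x)
}

#' @describeIn build_coverage Tidy a coverage track into a run-length tibble
#'   with columns `scaffold`, `start`, `end`, `count`.
#' @param x An `or_coverage` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.or_coverage <- function(x, ...) {
  purrr::imap(unclass(x), function(rle, scaf) {
    tibble(
      scaffold = scaf,
      start = S4Vectors::start(rle),
      end = S4Vectors::end(rle),
      count = as.integer(S4Vectors::runValue(rle))
    )
  }) |> bind_rows()
}

#' @exportS3Method ggplot2::autoplot
autoplot.or_coverage <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("start", "end"),
                              names_to = NULL, values_to = "pos")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~scaffold, ncol = 1L, scales = "free_x") +
    ggplot2::labs(x = "scaffold position (nt)", y = "alignment coverage")
}

#' Demarcate alignment islands (rough gene loci)
#'
#' Maximal runs of positive coverage, left to right per scaffold. Each locus
#' records the ids of all alignments whose exon segments overlap it.
#'
#' @param coverage An `or_coverage` object from [build_coverage()].
#' @param hits The [alignment_hits()] tibble the track was built from
#'   (optional; needed to fill `hit_ids`).
#' @return Tibble with columns `locus_id`, `scaffold`, `start`, `end`,
#'   `n_hits`, `hit_ids` (list-column).
#' @export
find_islands <- function(coverage, hits = NULL) {
  loci <- purrr::imap(unclass(coverage), function(rle, scaf) {
    isl <- IRanges::slice(rle, lower = 1L, rangesOnly = TRUE)
    if (!length(isl)) return(NULL)
    tibble(scaffold = scaf,
           start = IRanges::start(isl), end = IRanges::end(isl))
  }) |> bind_rows()
  if (!nrow(loci)) {
    return(tibble(locus_id = character(), scaffold = character(),
                  start = integer(), end = integer(),
                  n_hits = integer(), hit_ids = list()))
  }
  loci <- arrange(loci, .data$scaffold, .data$start)
  loci$locus_id <- sprintf("locus_%04d", seq_len(nrow(loci)))
  loci$hit_ids <- purrr::pmap(loci[c("scaffold", "start", "end")],
    function(scaffold, start, end) {
      if (is.null(hits)) return(character())
      sub <- hits[hits$target_id == scaffold, , drop = FALSE]
      keep <- purrr::map_lgl(sub$segments, function(s) {
        any(s$t_start <= end & s$t_end >= start)
      })
      sub$hit_id[keep]
    })
  loci$n_hits <- lengths(loci$hit_ids)
  loci[c("locus_id", "scaffold", "start", "end", "n_hits", "hit_ids")]
}
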