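# The alignment-hit table is the package's central input container: one row
# per spliced protein-to-genome alignment, with the per-exon query<->target
# mapping nested in the `segments` list-column.

#' Construct/validate an alignment-hit table
#'
#' One row per spliced protein-to-genome alignment. `segments` is a
#' list-column of tibbles (`t_start`, `t_end`, `q_start`, `q_end`, `phase`)
#' in transcription order; target intervals are forward-strand, 1-based
#' inclusive, with `t_start <= t_end`. Query coordinates are 1-based
#' inclusive amino-acid positions on the query protein.
#'
#' @param df Data frame with columns `hit_id`, `query_id`, `target_id`,
#'   `strand`, `score`, `q_start`, `q_end`, `t_start`, `t_end`, `segments`.
#' @return A validated tibble of class `or_hits`.
#' @export
alignment_hits <- function(df) {
  need <- c("hit_id", "query_id", "target_id", "strand", "score",
            "q_start", "q_end", "t_start", "t_end", "segments")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("alignment_hits: missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)[need]
  stopifnot(all(df$strand %in% c("+", "-")))
  for (i in seq_len(nrow(df))) {
    seg <- df$segments[[i]]
    if (is.null(seg) || nrow(seg) == 0L) {
      abort(sprintf("hit '%s' has no segments", df$hit_id[i]))
    }
    if (!"phase" %in% names(seg)) seg$phase <- 0L
    stopifnot(all(seg$t_start <= seg$t_end))
    fwd <- seg[order(seg$t_start), , drop = FALSE]
    if (nrow(fwd) > 1L && any(fwd$t_start[-1L] <= fwd$t_end[-nrow(fwd)])) {
      abort(sprintf("hit '%s': overlapping exon segments", df$hit_id[i]))
    }
    # transcription order: ascending target for '+', descending for '-'
    seg <- seg[if (df$strand[i] == "+") order(seg$t_start) else
                 order(-seg$t_start), , drop = FALSE]
    if (!anyNA(seg$q_start)) {
      if (is.unsorted(seg$q_start)) {
        abort(sprintf("hit '%s': segment query intervals not in transcription order",
                      df$hit_id[i]))
      }
      if (min(seg$q_start) < df$q_start[i] || max(seg$q_end) > df$q_end[i]) {
        abort(sprintf("hit '%s': segment query span outside hit query span",
                      df$hit_id[i]))
      }
    }
    df$segments[[i]] <- as_tibble(seg)
  }
  class(df) <- c("or_hits", class(tibble()))
  df
}

new_hits_tibble <- function(rows) {
  out <- bind_rows(rows)
  class(out) <- c("or_hits", class(tibble()))
  out
}

empty_hits <- function() {
  alignment_hits(tibble(
    hit_id = character(), query_id = character(), target_id = character(),
    strand = character(), score = numeric(),
    q_start = integer(), q_end = integer(),
    t_start = integer(), t_end = integer(),
    segments = list()
  ))
}
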