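# Optional second-pass refinement (the P1 -> P2 step). Each preliminary hit's
# locus is extended by up to `max_extension` per side and handed, together
# with its best query protein, to a pluggable refiner. The refiner is either
# an R function or an external executable following a small subprocess
# contract. When no refiner is configured the pipeline runs P1-only.

#' Refine preliminary models with an external gene predictor
#'
#' For each P1 model the genomic locus is extended by
#' `min(span, max_extension)` per side and the extended sequence plus the
#' model's best query protein are passed to `refiner`. Refined (P2) models
#' are finalized and merged with the P1 set via [merge_p1_p2()].
#'
#' `refiner` may be:
#' * `NULL` — refinement is skipped (P1-only pipeline);
#' * an R function `function(target_seq, query_protein)` returning a data
#'   frame of exon intervals (`start`, `end`, 1-based on the extended
#'   slice's forward strand) or `NULL`;
#' * the path to an executable invoked as `refiner <target.fa> <query.fa>`
#'   that prints GFF3 transcript structures in slice coordinates (a
#'   GeneWise-class tool behind a small shell wrapper). Non-zero exit or
#'   unparsable output yields a warning and no P2 model.
#'
#' @param models P1 `or_models` tibble.
#' @param genome Named character vector of scaffold sequences.
#' @param queries Named character vector of query proteins.
#' @param config An [or_config()].
#' @param refiner See above.
#' @return Merged `or_models` tibble.
#' @export
refine_models <- function(models, genome, queries, config = or_config(),
                          refiner = NULL) {
  if (is.null(refiner) || !nrow(models)) return(models)
  p2_rows <- purrr::map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    scaffold_len <- nchar(genome[[m$scaffold]])
    ext <- extend_locus(m$start, m$end, scaffold_len, config)
    slice <- seq_slice(genome, m$scaffold, ext[1L], ext[2L])
    qseq <- queries[[m$query_id]]
    local_exons <- tryCatch(
      call_refiner(refiner, slice, qseq, m$query_id),
      error = function(e) {
        warn(sprintf("refiner failed for model at %s:%d-%d: %s",
                     m$scaffold, m$start, m$end, conditionMessage(e)))
        NULL
      })
    if (is.null(local_exons) || !nrow(local_exons)) return(NULL)
    exons <- tibble(start = ext[1L] - 1L + as.integer(local_exons$start),
                    end = ext[1L] - 1L + as.integer(local_exons$end))
    if (any(exons$start < 1L) || any(exons$end > scaffold_len)) {
      warn("refiner returned coordinates outside the extended locus; skipped")
      return(NULL)
    }
    tibble(query_id = m$query_id, scaffold = m$scaffold, strand = m$strand,
           q_start = m$q_start, q_end = m$q_end, score = m$score,
           exons = list(arrange(exons, .data$start)),
           source_hit_ids = m$source_hit_ids,
           defects = list(character()), junctions = list(empty_junctions()))
  })
  p2_rows <- purrr::compact(p2_rows)
  if (!length(p2_rows)) return(models)
  p2 <- finalize_models(bind_rows(p2_rows), genome, config, provenance = "P2")
  merge_p1_p2(models, p2, config)
}

call_refiner <- function(refiner, target_seq, query_protein, query_id) {
  if (is.function(refiner)) {
    return(refiner(target_seq, query_protein))
  }
  if (!is.character(refiner) || length(refiner) != 1L) {
    abort("refiner must be NULL, a function, or an executable path")
  }
  tdir <- tempfile("refiner")
  dir.create(tdir)
  on.exit(unlink(tdir, recursive = TRUE), add = TRUE)
  tfa <- file.path(tdir, "target.fa")
  qfa <- file.path(tdir, "query.fa")
  write_fasta(c(target = target_seq), tfa)
  write_fasta(setNames(query_protein, query_id), qfa)
  out <- file.path(tdir, "out.gff3")
  status <- suppressWarnings(system2(refiner, c(tfa, qfa), stdout = out,
                                     stderr = FALSE))
  if (!identical(status, 0L)) abort(sprintf("refiner exited with status %s",
                                            status))
  tx <- read_gff_transcripts(out)
  if (!nrow(tx)) return(NULL)
  tx$exons[[1L]]
}
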