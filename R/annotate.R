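# End-to-end annotation pipeline: redundant spliced alignments in,
# non-redundant splice-corrected gene models out.

#' Annotate a tandem gene family from spliced protein-to-genome alignments
#'
#' Runs the full pipeline: per-scaffold alignment-coverage tracks; coverage
#' islands to separate tandem copies; best-alignment/best-query selection
#' per island; collection and GT-AG-validated stitching of the best query's
#' fragments; optional external refinement (P1/P2 merge); START/STOP
#' finalization, pseudogene flagging and completeness classification;
#' isoform overlap resolution; location-based naming.
#'
#' @param alignments Path to an Exonerate-with-GFF alignment file, its text,
#'   or an [alignment_hits()] tibble.
#' @param genome Path to the genome FASTA or a named character vector.
#' @param queries Path to the query-protein FASTA or a named character
#'   vector.
#' @param config An [or_config()].
#' @param refiner Optional refiner passed to [refine_models()].
#' @return An object of class `or_annotation` with elements `models`
#'   (`or_models` tibble), `loci`, `coverage`, `hits` and `config`. `tidy()`
#'   returns the model table, `glance()` one summary row.
#' @examples
#' sim <- simulate_or_family(sim_config(seed = 1, n_scaffolds = 1,
#'                                      genes_per_scaffold = 2))
#' ann <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
#' tidy(ann)
#' @export
annotate_genes <- function(alignments, genome, queries,
                           config = or_config(), refiner = NULL) {
  hits <- if (inherits(alignments, "or_hits")) alignments else
    read_exonerate(alignments)
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    genome <- read_fasta(genome, "nucleotide")
  }
  if (is.character(queries) && length(queries) == 1L && is.null(names(queries))) {
    queries <- read_fasta(queries, "protein")
  }
  unknown <- setdiff(unique(hits$target_id), names(genome))
  if (length(unknown)) {
    abort(paste0("alignment targets missing from genome FASTA: ",
                 paste(utils::head(unknown, 3L), collapse = ", ")))
  }
  unknown_q <- setdiff(unique(hits$query_id), names(queries))
  if (length(unknown_q)) {
    abort(paste0("alignment queries missing from protein FASTA: ",
                 paste(utils::head(unknown_q, 3L), collapse = ", ")))
  }

  lengths <- setNames(nchar(genome), names(genome))
  coverage <- build_coverage(hits, lengths)
  loci <- find_islands(coverage, hits)
  loci <- best_hits_per_island(loci, hits)

  pairs <- distinct(tibble(query = loci$best_query_id,
                           scaffold = loci$scaffold))
  pairs <- pairs[!is.na(pairs$query), , drop = FALSE]
  premodels <- purrr::pmap(pairs, function(query, scaffold) {
    frags <- collect_best_query_hits(query, scaffold, hits)
    purrr::map(fragment_chains(frags), function(chain) {
      stitch_fragments(chain, genome, queries[[query]], config)
    }) |> bind_rows()
  }) |> bind_rows()

  p1 <- finalize_models(premodels, genome, config, provenance = "P1")
  merged <- refine_models(p1, genome, queries, config, refiner)
  resolved <- resolve_model_overlaps(merged, config)
  models <- assign_model_names(resolved)

  structure(
    list(models = models, loci = loci, coverage = coverage, hits = hits,
         config = config, scaffold_lengths = lengths),
    class = "or_annotation"
  )
}

#' @export
print.or_annotation <- function(x, ...) {
  cat(sprintf(
    "<or_annotation> %d hit(s) -> %d locus/loci -> %d gene model(s)\n",
    nrow(x$hits), nrow(x$loci), nrow(x$models)))
  print(glance(x))
  invisible(x)
}

#' @describeIn annotate_genes Model table of an annotation.
#' @param x,object An `or_annotation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.or_annotation <- function(x, ...) x$models

#' @describeIn annotate_genes One-row summary of an annotation.
#' @exportS3Method generics::glance
glance.or_annotation <- function(x, ...) {
  m <- x$models
  tibble(
    n_hits = nrow(x$hits), n_loci = nrow(x$loci), n_models = nrow(m),
    n_complete = sum(m$completeness == "complete"),
    n_partial = sum(m$completeness == "partial"),
    n_with_start = sum(m$has_start), n_without_start = sum(!m$has_start),
    n_pseudo = sum(m$pseudo)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.or_annotation <- function(object, ...) {
  cov <- tidy(object$coverage)
  long <- tidyr::pivot_longer(cov, c("start", "end"),
                              names_to = NULL, values_to = "pos")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~scaffold, ncol = 1L, scales = "free_x") +
    ggplot2::labs(x = "scaffold position (nt)", y = "alignment coverage")
  if (nrow(object$models)) {
    rects <- tibble(scaffold = object$models$scaffold,
                    xmin = object$models$start, xmax = object$models$end)
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE)
  }
  p
}
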