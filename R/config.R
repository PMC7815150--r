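#' Annotation parameters
#'
#' Collects the tunable parameters of the annotation pipeline with their
#' defaults. All downstream functions take a config built here, so there is a
#' single source of truth for thresholds.
#'
#' @param min_complete_len Minimum predicted protein length (amino acids,
#'   terminal stop excluded) for a model to be classified `complete` rather
#'   than `partial`. Default 300.
#' @param max_extension Maximum genomic extension (nucleotides) allowed on
#'   each side of a preliminary hit when handing its locus to an external
#'   refiner. Each side extends by `min(hit span, max_extension)`. Default
#'   6000.
#' @param terminal_search_window Number of codons scanned upstream for a START
#'   (ATG) and downstream for a STOP codon during finalization. Default 20.
#' @param isoform_overlap_frac Overlap fraction below which two genomically
#'   overlapping models are both kept as putative isoforms / duplicated
#'   exons. Default 0.20; the rule is "keep both iff the overlap is < this
#'   fraction of both models".
#' @param eval_tolerance Maximum displacement (nucleotides) tolerated at the
#'   free ends of terminal exons when matching exons/transcripts during
#'   evaluation. Default 10.
#' @param min_intron Minimum length (nucleotides) for an intron created by
#'   fragment stitching; junction gaps below this are recorded as frameshift
#'   defects. Default 30.
#' @param consensus_min_helix Minimum run length (residues) for a consensus
#'   transmembrane helix in the three-way majority vote. Default 9.
#'
#' @return A list of class `or_config`.
#' @examples
#' or_config(min_complete_len = 100)
#' @export
or_config <- function(min_complete_len = 300,
                      max_extension = 6000,
                      terminal_search_window = 20,
                      isoform_overlap_frac = 0.20,
                      eval_tolerance = 10,
                      min_intron = 30,
                      consensus_min_helix = 9) {
  stopifnot(
    min_complete_len > 0, max_extension > 0, terminal_search_window > 0,
    isoform_overlap_frac > 0, isoform_overlap_frac < 1,
    eval_tolerance >= 0, min_intron > 0, consensus_min_helix > 0
  )
  structure(
    list(
      min_complete_len = as.integer(min_complete_len),
      max_extension = as.integer(max_extension),
      terminal_search_window = as.integer(terminal_search_window),
      isoform_overlap_frac = isoform_overlap_frac,
      eval_tolerance = as.integer(eval_tolerance),
      min_intron = as.integer(min_intron),
      consensus_min_helix = as.integer(consensus_min_helix)
    ),
    class = "or_config"
  )
}

#' @export
print.or_config <- function(x, ...) {
  cat("<or_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
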