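# Best-alignment selection per coverage island and splice-aware stitching of
# fragmented alignments. A fragmented gene shows up as two congruent
# alignments of the same query whose query spans overlap by k residues (the
# overlap was wrongly extended into the intron on both sides). All 3k+1 cut
# points over the constant-length 3k-nt overlap window are enumerated; only
# cuts flanked by a "gt" donor and an "ag" acceptor on the coding strand
# survive, and the candidate whose translated overlap scores best against
# the query residues (BLOSUM62) is kept.

blosum_env <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum_env$m <- e$BLOSUM62
  }
  blosum_env$m
}

score_against_query <- function(translated, query_res) {
  m <- get_blosum62()
  a <- strsplit(translated, "")[[1L]]
  b <- strsplit(query_res, "")[[1L]]
  n <- min(length(a), length(b))
  if (!n) return(0)
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  ok <- a %in% rownames(m) & b %in% colnames(m)
  sum(m[cbind(a[ok], b[ok])])
}

#' Select the best alignment (and query) for each coverage island
#'
#' The supporting hit with the maximal alignment score wins; ties break by
#' lexicographically smallest query id, then leftmost target start.
#'
#' @param loci Locus tibble from [find_islands()].
#' @param hits The [alignment_hits()] tibble.
#' @return `loci` with `best_hit_id`, `best_query_id` and `best_score`
#'   filled.
#' @export
best_hits_per_island <- function(loci, hits) {
  picks <- purrr::map(loci$hit_ids, function(ids) {
    sub <- hits[hits$hit_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) {
      return(tibble(best_hit_id = NA_character_,
                    best_query_id = NA_character_, best_score = NA_real_))
    }
    sub <- arrange(sub, dplyr::desc(.data$score), .data$query_id, .data$t_start)
    tibble(best_hit_id = sub$hit_id[1L], best_query_id = sub$query_id[1L],
           best_score = sub$score[1L])
  })
  dplyr::bind_cols(loci, bind_rows(picks))
}

#' Collect all alignments of a best query on one scaffold
#'
#' Once a query has won an island, all of its alignments on that scaffold are
#' retained (they are candidate fragments of the same gene); alignments of
#' non-best queries are discarded from modeling.
#'
#' @param best_query Query protein id.
#' @param scaffold Scaffold id.
#' @param hits The [alignment_hits()] tibble.
#' @return Hits of that query on that scaffold, sorted by target position.
#' @export
collect_best_query_hits <- function(best_query, scaffold, hits) {
  sub <- hits[hits$query_id == best_query & hits$target_id == scaffold, ,
              drop = FALSE]
  arrange(sub, .data$t_start, .data$t_end)
}

#' Are two fragments congruently arranged?
#'
#' `a` and `b` are single-row hits of the same query on the same scaffold
#' with `a` upstream of `b` in transcription order. They are congruent iff
#' they lie on the same strand, their target intervals are disjoint and
#' ordered consistently with transcription, and their query spans advance
#' without nesting.
#'
#' @param a,b Single-row hit tibbles.
#' @return Logical scalar.
#' @export
fragments_congruent <- function(a, b) {
  if (a$strand != b$strand || a$target_id != b$target_id ||
      a$query_id != b$query_id) {
    return(FALSE)
  }
  target_ok <- if (a$strand == "+") b$t_start > a$t_end else b$t_end < a$t_start
  target_ok && b$q_start > a$q_start && b$q_end > a$q_end
}

# Order hits in transcription direction and split them into maximal runs of
# pairwise-congruent consecutive fragments.
fragment_chains <- function(frags) {
  if (!nrow(frags)) return(list())
  chains <- list()
  for (str in unique(frags$strand)) {
    sub <- frags[frags$strand == str, , drop = FALSE]
    sub <- if (str == "+") arrange(sub, .data$t_start) else
      arrange(sub, dplyr::desc(.data$t_end))
    cur <- 1L
    idx <- list()
    run <- 1L
    for (i in seq_len(nrow(sub))[-1L]) {
      if (fragments_congruent(sub[i - 1L, ], sub[i, ])) {
        run <- c(run, i)
      } else {
        idx[[length(idx) + 1L]] <- run
        run <- i
      }
    }
    idx[[length(idx) + 1L]] <- run
    chains <- c(chains, purrr::map(idx, ~ sub[.x, , drop = FALSE]))
  }
  chains
}

empty_junctions <- function() {
  tibble(k_aa = integer(), window_nt = integer(), n_candidates = integer(),
         n_valid = integer(), donor_offset = integer(),
         intron_start = integer(), intron_end = integer(),
         score = numeric(), stitched = logical())
}

# Enumerate splice candidates for one junction with k > 0 aa query overlap.
# A_ex / B_ex are the flanking exons (forward intervals); returns the chosen
# cut or NULL when no gt..ag candidate exists.
enumerate_junction <- function(genome, scaffold, strand, A_ex, B_ex, k,
                               query_res) {
  W <- aa_to_nt_len(k)
  lenA <- A_ex["end"] - A_ex["start"] + 1L
  lenB <- B_ex["end"] - B_ex["start"] + 1L
  if (lenA <= W || lenB <= W) return(NULL)
  cands <- purrr::map(0:W, function(d) {
    if (strand == "+") {
      cutA <- A_ex[["end"]] - W + d
      cutB <- B_ex[["start"]] + d
      donor <- tx_dinuc_after(genome, scaffold, cutA, "+")
      acceptor <- tx_dinuc_before(genome, scaffold, cutB, "+")
      a_part <- if (d > 0L) seq_slice(genome, scaffold,
                                      A_ex[["end"]] - W + 1L, cutA) else ""
      b_part <- if (d < W) seq_slice(genome, scaffold, cutB,
                                     B_ex[["start"]] + W - 1L) else ""
      seq <- paste0(a_part, b_part)
    } else {
      cutA <- A_ex[["start"]] + W - d
      cutB <- B_ex[["end"]] - d
      donor <- tx_dinuc_after(genome, scaffold, cutA, "-")
      acceptor <- tx_dinuc_before(genome, scaffold, cutB, "-")
      a_part <- if (d > 0L) revcomp(seq_slice(genome, scaffold, cutA,
                                              A_ex[["start"]] + W - 1L)) else ""
      b_part <- if (d < W) revcomp(seq_slice(genome, scaffold,
                                             B_ex[["end"]] - W + 1L, cutB)) else ""
      seq <- paste0(a_part, b_part)
    }
    ok <- identical(donor, "GT") && identical(acceptor, "AG")
    list(d = d, ok = ok,
         score = if (ok) score_against_query(translate_cds(seq), query_res)
                 else -Inf)
  })
  valid <- purrr::keep(cands, "ok")
  if (!length(valid)) {
    return(list(n_valid = 0L, n_candidates = W + 1L, window_nt = W))
  }
  scores <- purrr::map_dbl(valid, "score")
  best <- valid[[which.max(scores)]]   # which.max: ties -> smallest d (5'-most)
  list(d = best$d, score = best$score, n_valid = length(valid),
       n_candidates = W + 1L, window_nt = W)
}

#' Stitch congruent alignment fragments into a gene model
#'
#' Adjacent fragments whose query spans overlap by `k > 0` residues are
#' joined by enumerating every cut of the 3k-nt overlap window that is
#' flanked by `gt`/`ag` on the coding strand and keeping the cut whose
#' translated overlap best matches the query (BLOSUM62; ties go to the
#' 5'-most donor). Non-overlapping fragments are joined directly, the gap
#' becoming an intron. Junctions with no valid gt..ag cut split the chain
#' into separate models.
#'
#' @param fragments [alignment_hits()] rows of one query on one scaffold and
#'   strand, pairwise congruent in transcription order.
#' @param genome Named character vector of scaffold sequences.
#' @param query_protein Query protein sequence (character scalar).
#' @param config An [or_config()].
#' @return Tibble of preliminary models with list-columns `exons`,
#'   `source_hit_ids`, `defects` and `junctions` (one row per junction:
#'   `k_aa`, `window_nt`, `n_candidates`, `n_valid`, `donor_offset`,
#'   `intron_start`, `intron_end`, `score`, `stitched`).
#' @export
stitch_fragments <- function(fragments, genome, query_protein,
                             config = or_config()) {
  stopifnot(nrow(fragments) >= 1L)
  strand <- fragments$strand[1L]
  scaffold <- fragments$target_id[1L]
  frags <- if (strand == "+") arrange(fragments, .data$t_start) else
    arrange(fragments, dplyr::desc(.data$t_end))

  models <- list()
  open_model <- function(frag) {
    seg <- frag$segments[[1L]]
    list(exons = tibble(start = seg$t_start, end = seg$t_end),
         q_start = frag$q_start, q_end = frag$q_end,
         score = frag$score, hit_ids = frag$hit_id,
         defects = character(), junctions = empty_junctions())
  }
  cur <- open_model(frags[1L, ])

  close_model <- function(cur) {
    ex <- arrange(cur$exons, .data$start)
    tibble(
      query_id = fragments$query_id[1L], scaffold = scaffold, strand = strand,
      q_start = cur$q_start, q_end = cur$q_end, score = cur$score,
      exons = list(ex), source_hit_ids = list(cur$hit_ids),
      defects = list(unique(cur$defects)), junctions = list(cur$junctions)
    )
  }

  for (i in seq_len(nrow(frags))[-1L]) {
    b <- frags[i, ]
    segB <- b$segments[[1L]]
    exB <- tibble(start = segB$t_start, end = segB$t_end)
    # flanking exons in transcription order
    last_idx <- if (strand == "+") which.max(cur$exons$end) else
      which.min(cur$exons$start)
    first_idx <- if (strand == "+") which.min(exB$start) else
      which.max(exB$end)
    A_ex <- c(start = cur$exons$start[last_idx], end = cur$exons$end[last_idx])
    B_ex <- c(start = exB$start[first_idx], end = exB$end[first_idx])
    k <- cur$q_end - b$q_start + 1L

    if (k <= 0L) {
      gap <- if (strand == "+") B_ex[["start"]] - A_ex[["end"]] - 1L else
        A_ex[["start"]] - B_ex[["end"]] - 1L
      if (gap < config$min_intron) cur$defects <- c(cur$defects, "frameshift")
      cur$junctions <- bind_rows(cur$junctions, tibble(
        k_aa = 0L, window_nt = 0L, n_candidates = 0L, n_valid = NA_integer_,
        donor_offset = NA_integer_,
        intron_start = if (strand == "+") A_ex[["end"]] + 1L else B_ex[["end"]] + 1L,
        intron_end = if (strand == "+") B_ex[["start"]] - 1L else A_ex[["start"]] - 1L,
        score = NA_real_, stitched = TRUE
      ))
      cur$exons <- bind_rows(cur$exons, exB)
    } else {
      query_res <- substr(query_protein, b$q_start, cur$q_end)
      cut <- enumerate_junction(genome, scaffold, strand, A_ex, B_ex, k,
                                query_res)
      if (is.null(cut) || cut$n_valid == 0L) {
        warn(sprintf(
          "query '%s' on %s: no gt..ag splice candidate for %d-aa overlap junction; fragments left unstitched",
          b$query_id, scaffold, k))
        cur$junctions <- bind_rows(cur$junctions, tibble(
          k_aa = k, window_nt = if (is.null(cut)) NA_integer_ else cut$window_nt,
          n_candidates = if (is.null(cut)) NA_integer_ else cut$n_candidates,
          n_valid = 0L, donor_offset = NA_integer_,
          intron_start = NA_integer_, intron_end = NA_integer_,
          score = NA_real_, stitched = FALSE
        ))
        models[[length(models) + 1L]] <- close_model(cur)
        cur <- open_model(b)
        next
      }
      W <- cut$window_nt
      d <- cut$d
      if (strand == "+") {
        cur$exons$end[last_idx] <- A_ex[["end"]] - W + d
        exB$start[first_idx] <- B_ex[["start"]] + d
        intron <- c(A_ex[["end"]] - W + d + 1L, B_ex[["start"]] + d - 1L)
      } else {
        cur$exons$start[last_idx] <- A_ex[["start"]] + W - d
        exB$end[first_idx] <- B_ex[["end"]] - d
        intron <- c(B_ex[["end"]] - d + 1L, A_ex[["start"]] + W - d - 1L)
      }
      if (intron[2L] - intron[1L] + 1L < config$min_intron) {
        cur$defects <- c(cur$defects, "frameshift")
      }
      cur$junctions <- bind_rows(cur$junctions, tibble(
        k_aa = k, window_nt = W, n_candidates = cut$n_candidates,
        n_valid = cut$n_valid, donor_offset = d,
        intron_start = intron[1L], intron_end = intron[2L],
        score = cut$score, stitched = TRUE
      ))
      cur$exons <- bind_rows(cur$exons, exB)
    }
    cur$q_end <- b$q_end
    cur$score <- cur$score + b$score
    cur$hit_ids <- c(cur$hit_ids, b$hit_id)
  }
  models[[length(models) + 1L]] <- close_model(cur)
  bind_rows(models)
}
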