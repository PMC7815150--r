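# Brute-force oracles and tiny fixture builders. Oracles are deliberately
# naive (per-position loops, exhaustive enumeration) and independent of the
# package's IRanges/graph-based implementations.

make_hit <- function(hit_id, query_id, scaffold, strand, score, segments) {
  if (!"phase" %in% names(segments)) {
    ord <- if (strand == "+") order(segments$t_start) else
      order(-segments$t_start)
    segments <- segments[ord, , drop = FALSE]
    nt <- cumsum(c(0L, segments$t_end - segments$t_start + 1L))
    segments$phase <- as.integer(nt[seq_len(nrow(segments))] %% 3L)
  }
  tibble::tibble(
    hit_id = hit_id, query_id = query_id, target_id = scaffold,
    strand = strand, score = as.numeric(score),
    q_start = min(segments$q_start), q_end = max(segments$q_end),
    t_start = min(segments$t_start), t_end = max(segments$t_end),
    segments = list(segments)
  )
}

# Per-position recount of exon-segment coverage.
oracle_coverage <- function(hits, len) {
  counts <- integer(len)
  for (i in seq_len(nrow(hits))) {
    seg <- hits$segments[[i]]
    for (r in seq_len(nrow(seg))) {
      for (p in seg$t_start[r]:seg$t_end[r]) counts[p] <- counts[p] + 1L
    }
  }
  counts
}

# Maximal positive runs by linear scan.
oracle_islands <- function(counts) {
  out <- NULL
  in_run <- FALSE
  for (p in seq_along(counts)) {
    if (counts[p] > 0L && !in_run) { s <- p; in_run <- TRUE }
    if (counts[p] == 0L && in_run) {
      out <- rbind(out, c(s, p - 1L)); in_run <- FALSE
    }
  }
  if (in_run) out <- rbind(out, c(s, length(counts)))
  out
}

# Per-residue vote for the TMH consensus.
oracle_consensus <- function(sets, len, min_helix = 9L) {
  votes <- integer(len)
  for (hs in sets) {
    for (r in seq_len(nrow(hs))) {
      for (p in hs$start[r]:hs$end[r]) if (p >= 1 && p <= len)
        votes[p] <- votes[p] + 1L
    }
  }
  memb <- votes >= 2L
  out <- NULL
  p <- 1L
  while (p <= len) {
    if (memb[p]) {
      s <- p
      while (p <= len && memb[p]) p <- p + 1L
      if (p - s >= min_helix) out <- rbind(out, c(s, p - 1L))
    } else {
      p <- p + 1L
    }
  }
  out
}

# ---- evaluator oracle -------------------------------------------------------

oracle_exon_table <- function(tx) {
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (r in seq_len(nrow(ex))) {
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = tx$scaffold[i], strand = tx$strand[i],
        start = ex$start[r], end = ex$end[r],
        free_start = r == 1L, free_end = r == nrow(ex)
      )
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    return(data.frame(scaffold = character(), strand = character(),
                      start = integer(), end = integer(),
                      free_start = logical(), free_end = logical()))
  }
  # dedupe identical intervals, OR-ing the free flags
  key <- paste(df$scaffold, df$strand, df$start, df$end)
  out <- NULL
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    row <- sub[1L, , drop = FALSE]
    row$free_start <- any(sub$free_start)
    row$free_end <- any(sub$free_end)
    out <- rbind(out, row)
  }
  out[order(out$scaffold, out$strand, out$start, out$end), , drop = FALSE]
}

oracle_compare <- function(pred, ref, e) {
  # base level via logical position vectors
  strata <- unique(rbind(
    unique(data.frame(scaffold = pred$scaffold, strand = pred$strand)),
    unique(data.frame(scaffold = ref$scaffold, strand = ref$strand))
  ))
  tp_b <- fp_b <- fn_b <- 0L
  for (s in seq_len(nrow(strata))) {
    cover <- function(tx) {
      sel <- tx$scaffold == strata$scaffold[s] & tx$strand == strata$strand[s]
      v <- logical(0)
      for (i in which(sel)) {
        ex <- tx$exons[[i]]
        m <- max(ex$end)
        if (m > length(v)) v <- c(v, logical(m - length(v)))
        for (r in seq_len(nrow(ex))) v[ex$start[r]:ex$end[r]] <- TRUE
      }
      v
    }
    vp <- cover(pred); vr <- cover(ref)
    n <- max(length(vp), length(vr))
    vp <- c(vp, logical(n - length(vp))); vr <- c(vr, logical(n - length(vr)))
    tp_b <- tp_b + sum(vp & vr)
    fp_b <- fp_b + sum(vp & !vr)
    fn_b <- fn_b + sum(!vp & vr)
  }

  # exon level: greedy left-to-right one-to-one matching
  pe <- oracle_exon_table(pred)
  re <- oracle_exon_table(ref)
  used <- rep(FALSE, nrow(re))
  tp_e <- 0L
  bnd <- function(a, b, fa, fb) if (fa && fb) abs(a - b) <= e else a == b
  for (i in seq_len(nrow(pe))) {
    for (j in seq_len(nrow(re))) {
      if (used[j]) next
      if (pe$scaffold[i] != re$scaffold[j] || pe$strand[i] != re$strand[j])
        next
      if (bnd(pe$start[i], re$start[j], pe$free_start[i], re$free_start[j]) &&
          bnd(pe$end[i], re$end[j], pe$free_end[i], re$free_end[j])) {
        used[j] <- TRUE; tp_e <- tp_e + 1L; break
      }
    }
  }

  # locus level: transitive clustering by pairwise exon overlap
  cluster <- function(tx) {
    n <- nrow(tx)
    cl <- seq_len(n)
    overlaps <- function(i, j) {
      if (tx$scaffold[i] != tx$scaffold[j] || tx$strand[i] != tx$strand[j])
        return(FALSE)
      a <- tx$exons[[i]]; b <- tx$exons[[j]]
      for (r in seq_len(nrow(a))) {
        for (q in seq_len(nrow(b))) {
          if (a$start[r] <= b$end[q] && a$end[r] >= b$start[q]) return(TRUE)
        }
      }
      FALSE
    }
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (cl[i] != cl[j] && overlaps(i, j)) {
          cl[cl == cl[j]] <- cl[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    match(cl, unique(cl))
  }
  tx_match <- function(a_ex, a_str, a_scf, b_ex, b_str, b_scf) {
    if (a_scf != b_scf || a_str != b_str) return(FALSE)
    a_ex <- a_ex[order(a_ex$start), , drop = FALSE]
    b_ex <- b_ex[order(b_ex$start), , drop = FALSE]
    if (nrow(a_ex) != nrow(b_ex)) return(FALSE)
    n <- nrow(a_ex)
    if (n > 1L) {
      for (r in seq_len(n - 1L)) {
        if (a_ex$end[r] != b_ex$end[r] ||
            a_ex$start[r + 1L] != b_ex$start[r + 1L]) return(FALSE)
      }
    }
    abs(a_ex$start[1L] - b_ex$start[1L]) <= e &&
      abs(a_ex$end[n] - b_ex$end[n]) <= e
  }
  pc <- cluster(pred); rc <- cluster(ref)
  pm <- rep(FALSE, nrow(pred)); rm <- rep(FALSE, nrow(ref))
  for (i in seq_len(nrow(pred))) for (j in seq_len(nrow(ref))) {
    if (tx_match(pred$exons[[i]], pred$strand[i], pred$scaffold[i],
                 ref$exons[[j]], ref$strand[j], ref$scaffold[j])) {
      pm[i] <- TRUE; rm[j] <- TRUE
    }
  }
  ref_loci_matched <- vapply(unique(rc), function(c0) any(rm[rc == c0]),
                             logical(1L))
  pred_loci_matched <- vapply(unique(pc), function(c0) any(pm[pc == c0]),
                              logical(1L))
  list(
    base = c(tp = tp_b, fp = fp_b, fn = fn_b),
    exon = c(tp = tp_e, fp = nrow(pe) - tp_e, fn = nrow(re) - tp_e),
    locus = c(tp = sum(ref_loci_matched), fp = sum(!pred_loci_matched),
              fn = sum(!ref_loci_matched)),
    locus_precision = 100 * sum(pred_loci_matched) /
      max(1L, length(pred_loci_matched)) *
      ifelse(length(pred_loci_matched) == 0L, NA, 1)
  )
}

# Random toy annotations on a coarse grid; `jitter` displaces transcript
# free ends. Boundary spacing >> 2 * tolerance keeps greedy matching
# well-posed.
rand_toy_annotation <- function(n_tx = 3L, jitter = 0L) {
  rows <- list()
  for (t in seq_len(n_tx)) {
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(1:4, 1L)
    start <- sample(seq(51L, 4000L, by = 100L), 1L)
    ex <- NULL
    pos <- start
    for (r in seq_len(n_ex)) {
      len <- sample(c(50L, 100L), 1L)
      ex <- rbind(ex, c(pos, pos + len - 1L))
      pos <- pos + len + sample(c(100L, 200L), 1L)
    }
    ex <- tibble::tibble(start = ex[, 1L], end = ex[, 2L])
    if (jitter > 0L) {
      ex$start[1L] <- max(1L, ex$start[1L] + sample(-jitter:jitter, 1L))
      ex$end[nrow(ex)] <- ex$end[nrow(ex)] + sample(-jitter:jitter, 1L)
    }
    rows[[t]] <- tibble::tibble(
      transcript_id = sprintf("tx_%d", t), gene_id = sprintf("g_%d", t),
      scaffold = sample(c("sA", "sB"), 1L), strand = strand,
      source = "toy", exons = list(ex)
    )
  }
  dplyr::bind_rows(rows)
}

# A perturbed copy of `ref`: jittered free ends, occasional dropped or
# invented transcripts.
perturb_annotation <- function(ref, jitter = 12L) {
  pred <- ref
  keep <- runif(nrow(pred)) > 0.2
  if (!any(keep)) keep[1L] <- TRUE
  pred <- pred[keep, , drop = FALSE]
  for (i in seq_len(nrow(pred))) {
    ex <- pred$exons[[i]]
    ex$start[1L] <- max(1L, ex$start[1L] + sample(-jitter:jitter, 1L))
    ex$end[nrow(ex)] <- ex$end[nrow(ex)] + sample(-jitter:jitter, 1L)
    pred$exons[[i]] <- ex
  }
  extra <- rand_toy_annotation(n_tx = sample(0:2, 1L))
  if (nrow(extra)) {
    extra$transcript_id <- paste0("extra_", extra$transcript_id)
    extra$gene_id <- paste0("extra_", extra$gene_id)
  }
  out <- dplyr::bind_rows(pred, extra)
  out$transcript_id <- sprintf("p_%d", seq_len(nrow(out)))
  out
}

# Handcrafted worked-example fixture: one 150-aa query whose two alignment
# fragments span residues 5-50 and 45-150, the hallmark wrong-extension
# pathology (true junction after codon 47, k = 6 aa overlap).
worked_example <- function(seed = 42L) {
  withr::with_seed(seed, {
    ct_bases <- c("A", "C", "G", "T")
    non_stop <- function() {
      repeat {
        cdn <- paste(sample(ct_bases, 3L, replace = TRUE), collapse = "")
        if (!cdn %in% c("TAA", "TAG", "TGA")) return(cdn)
      }
    }
    codons <- c("ATG", replicate(149L, non_stop()))
    protein <- olfactoR::translate_cds(paste(codons, collapse = ""))
    exon1 <- paste(codons[1:47], collapse = "")     # 141 nt
    exon2 <- paste(codons[48:150], collapse = "")   # 309 nt
    intron <- paste0("GT", paste(sample(ct_bases, 196L, replace = TRUE),
                                 collapse = ""), "AG")
    flank <- paste(sample(ct_bases, 100L, replace = TRUE), collapse = "")
    genome <- c(scaf = paste0(flank, exon1, intron, exon2, flank))
    # forward coordinates
    e1s <- 101L; e1e <- e1s + 141L - 1L            # 101..241
    i1s <- e1e + 1L; i1e <- i1s + 200L - 1L        # 242..441
    e2s <- i1e + 1L; e2e <- e2s + 309L - 1L        # 442..750
    ka <- 3L; kb <- 3L
    fragA <- make_hit("hA", "OR1", "scaf", "+", 250, tibble::tibble(
      t_start = e1s + 4L * 3L, t_end = e1e + 3L * ka,  # codon 5 .. +9 nt
      q_start = 5L, q_end = 50L
    ))
    fragB <- make_hit("hB", "OR1", "scaf", "+", 550, tibble::tibble(
      t_start = e2s - 3L * kb, t_end = e2e,
      q_start = 45L, q_end = 150L
    ))
    list(genome = genome, protein = protein,
         fragments = olfactoR::alignment_hits(dplyr::bind_rows(fragA, fragB)),
         true_intron = c(i1s, i1e))
  })
}

empty_hits_fixture <- function() {
  olfactoR::alignment_hits(tibble::tibble(
    hit_id = character(), query_id = character(), target_id = character(),
    strand = character(), score = numeric(),
    q_start = integer(), q_end = integer(),
    t_start = integer(), t_end = integer(), segments = list()
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
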