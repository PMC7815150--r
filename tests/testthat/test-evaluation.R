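# Base/exon/locus comparison semantics, terminal-exon tolerance, and
# equivalence with an exhaustive brute-force oracle.

two_exon_tx <- function(id, scaffold, strand, e1, e2, prefix = "t") {
  tibble::tibble(
    transcript_id = paste0(prefix, id), gene_id = paste0("g", id),
    scaffold = scaffold, strand = strand, source = "toy",
    exons = list(tibble::tibble(start = c(e1[1L], e2[1L]),
                                end = c(e1[2L], e2[2L])))
  )
}

test_that("an annotation compared against itself scores 100 everywhere", {
  ref <- dplyr::bind_rows(
    two_exon_tx(1L, "s1", "+", c(101L, 200L), c(301L, 400L)),
    two_exon_tx(2L, "s1", "-", c(1001L, 1100L), c(1301L, 1500L))
  )
  ev <- compare_annotations(ref, ref, 10L)
  expect_equal(ev$levels$sensitivity, rep(100, 3L))
  expect_equal(ev$levels$precision, rep(100, 3L))
  expect_equal(ev$missed_loci_pct, 0)
  expect_equal(ev$matching_loci, 2L)
})

test_that("disjoint annotations score zero and miss everything", {
  ref <- two_exon_tx(1L, "s1", "+", c(101L, 200L), c(301L, 400L))
  pred <- two_exon_tx(2L, "s1", "+", c(2001L, 2100L), c(2301L, 2400L), "p")
  ev <- compare_annotations(pred, ref, 10L)
  expect_equal(ev$levels$sensitivity, rep(0, 3L))
  expect_equal(ev$levels$precision, rep(0, 3L))
  expect_equal(ev$missed_loci_pct, 100)
  expect_equal(ev$novel_loci_pct, 100)
})

test_that("features on opposite strands never match", {
  ref <- two_exon_tx(1L, "s1", "+", c(101L, 200L), c(301L, 400L))
  pred <- two_exon_tx(1L, "s1", "-", c(101L, 200L), c(301L, 400L), "p")
  ev <- compare_annotations(pred, ref, 10L)
  expect_equal(ev$levels$tp, rep(0L, 3L))
})

test_that("terminal free ends flip between displacement 10 and 11 at e=10", {
  ref <- two_exon_tx(1L, "s1", "+", c(101L, 200L), c(301L, 400L))
  shift_end <- function(d) {
    p <- two_exon_tx(1L, "s1", "+", c(101L, 200L), c(301L, 400L + d), "p")
    compare_annotations(p, ref, 10L)
  }
  ok <- shift_end(10L)
  expect_equal(ok$levels$tp[ok$levels$level == "exon"], 2L)
  expect_equal(ok$levels$tp[ok$levels$level == "locus"], 1L)
  bad <- shift_end(11L)
  expect_equal(bad$levels$tp[bad$levels$level == "exon"], 1L)
  expect_equal(bad$levels$fp[bad$levels$level == "exon"], 1L)
  expect_equal(bad$levels$fn[bad$levels$level == "exon"], 1L)
  expect_equal(bad$levels$tp[bad$levels$level == "locus"], 0L)
})

test_that("internal boundaries get no tolerance", {
  ref <- two_exon_tx(1L, "s1", "+", c(101L, 200L), c(301L, 400L))
  pred <- two_exon_tx(1L, "s1", "+", c(101L, 205L), c(301L, 400L), "p")
  ev <- compare_annotations(pred, ref, 10L)
  # first exon's end is internal (intron boundary): 5-nt shift breaks it
  expect_equal(ev$levels$tp[ev$levels$level == "exon"], 1L)
  expect_equal(ev$levels$tp[ev$levels$level == "locus"], 0L)
})

test_that("one reference exon matched by two predictions yields one TP", {
  ref <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", scaffold = "s1", strand = "+",
    source = "toy", exons = list(tibble::tibble(start = 101L, end = 200L))
  )
  pred <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "p1", gene_id = "p1", scaffold = "s1",
                   strand = "+", source = "toy",
                   exons = list(tibble::tibble(start = 101L, end = 200L))),
    tibble::tibble(transcript_id = "p2", gene_id = "p2", scaffold = "s1",
                   strand = "+", source = "toy",
                   exons = list(tibble::tibble(start = 105L, end = 196L)))
  )
  ev <- compare_annotations(pred, ref, 10L)
  lv <- ev$levels[ev$levels$level == "exon", ]
  expect_equal(lv$tp, 1L)
  expect_equal(lv$fp, 1L)
  expect_equal(lv$fn, 0L)
})

test_that("increasing tolerance never decreases exon TP", {
  withr::with_seed(7L, {
    for (rep in 1:10) {
      ref <- rand_toy_annotation(n_tx = 3L)
      pred <- perturb_annotation(ref)
      tps <- vapply(c(0L, 5L, 10L, 15L), function(e) {
        ev <- compare_annotations(pred, ref, e)
        ev$levels$tp[ev$levels$level == "exon"]
      }, numeric(1L))
      expect_true(all(diff(tps) >= 0))
    }
  })
})

test_that("swapping predicted and reference swaps sensitivity and precision", {
  withr::with_seed(17L, {
    for (rep in 1:10) {
      # boundaries on a coarse grid: matches are exact-or-far, so the
      # greedy matching is symmetric and the property well-posed
      ref <- rand_toy_annotation(n_tx = sample(2:4, 1L))
      pred <- rand_toy_annotation(n_tx = sample(2:4, 1L))
      f <- compare_annotations(pred, ref, 10L)
      b <- compare_annotations(ref, pred, 10L)
      for (lvl in c("base", "exon")) {
        expect_equal(f$levels$sensitivity[f$levels$level == lvl],
                     b$levels$precision[b$levels$level == lvl])
        expect_equal(f$levels$precision[f$levels$level == lvl],
                     b$levels$sensitivity[b$levels$level == lvl])
      }
    }
  })
})

test_that("random toy pairs agree with the brute-force oracle", {
  withr::with_seed(31L, {
    for (rep in 1:25) {
      ref <- rand_toy_annotation(n_tx = sample(1:4, 1L))
      pred <- perturb_annotation(ref)
      for (e in c(0L, 10L)) {
        ev <- compare_annotations(pred, ref, e)
        want <- oracle_compare(pred, ref, e)
        got <- ev$levels
        expect_equal(unname(got$tp), unname(c(want$base["tp"],
                                              want$exon["tp"],
                                              want$locus["tp"])))
        expect_equal(unname(got$fp), unname(c(want$base["fp"],
                                              want$exon["fp"],
                                              want$locus["fp"])))
        expect_equal(unname(got$fn), unname(c(want$base["fn"],
                                              want$exon["fn"],
                                              want$locus["fn"])))
        expect_equal(got$precision[3L], want$locus_precision)
      }
    }
  })
})

test_that("base TP respects the conservation bound", {
  withr::with_seed(57L, {
    for (rep in 1:5) {
      ref <- rand_toy_annotation(n_tx = 3L)
      pred <- perturb_annotation(ref)
      ev <- compare_annotations(pred, ref, 10L)
      total <- function(tx) sum(vapply(tx$exons, function(e) {
        sum(e$end - e$start + 1L)
      }, numeric(1L)))
      expect_lte(ev$levels$tp[1L], min(total(pred), total(ref)))
    }
  })
})
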