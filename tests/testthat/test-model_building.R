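# Best-hit selection, congruence, and GT-AG stitch enumeration.

test_that("best hit per island follows score then query id then position", {
  segs <- function(s) tibble::tibble(t_start = s, t_end = s + 29L,
                                     q_start = 1L, q_end = 10L)
  hits <- alignment_hits(dplyr::bind_rows(
    make_hit("h1", "qB", "s1", "+", 700, segs(10L)),
    make_hit("h2", "qA", "s1", "+", 500, segs(12L)),
    make_hit("h3", "qC", "s1", "+", 700, segs(11L))
  ))
  loci <- best_hits_per_island(find_islands(build_coverage(hits, c(s1 = 100L)),
                                            hits), hits)
  expect_equal(loci$best_hit_id, "h1")  # 700 beats 500; qB < qC on tie
  expect_equal(loci$best_query_id, "qB")

  # exact tie on score and query id -> leftmost target start
  hits2 <- alignment_hits(dplyr::bind_rows(
    make_hit("h1", "qA", "s1", "+", 700, segs(20L)),
    make_hit("h2", "qA", "s1", "+", 700, segs(10L))
  ))
  loci2 <- best_hits_per_island(find_islands(build_coverage(hits2, c(s1 = 100L)),
                                             hits2), hits2)
  expect_equal(loci2$best_hit_id, "h2")
})

test_that("collect_best_query_hits keeps only that query, in genomic order", {
  segs <- function(s) tibble::tibble(t_start = s, t_end = s + 29L,
                                     q_start = 1L, q_end = 10L)
  hits <- alignment_hits(dplyr::bind_rows(
    make_hit("h1", "qA", "s1", "+", 10, segs(500L)),
    make_hit("h2", "qB", "s1", "+", 10, segs(100L)),
    make_hit("h3", "qA", "s1", "+", 10, segs(100L)),
    make_hit("h4", "qA", "s2", "+", 10, segs(1L))
  ))
  got <- collect_best_query_hits("qA", "s1", hits)
  expect_equal(got$hit_id, c("h3", "h1"))
})

test_that("congruence requires strand, order and non-nested query spans", {
  mk <- function(id, strand, ts, qs, qe) {
    make_hit(id, "q", "s1", strand,
             10, tibble::tibble(t_start = ts, t_end = ts + 50L,
                                q_start = qs, q_end = qe))
  }
  a <- mk("a", "+", 100L, 1L, 60L)
  b <- mk("b", "+", 400L, 55L, 150L)
  expect_true(fragments_congruent(a, b))
  expect_false(fragments_congruent(b, a))          # order reversed
  b2 <- mk("b2", "-", 400L, 55L, 150L)
  expect_false(fragments_congruent(a, b2))         # opposite strands
  nested <- mk("n", "+", 400L, 10L, 40L)
  expect_false(fragments_congruent(a, nested))     # nested query span
})

test_that("the worked wrong-extension example enumerates an 18-nt window", {
  wx <- worked_example()
  m <- stitch_fragments(wx$fragments, wx$genome, wx$protein, or_config())
  expect_equal(nrow(m), 1L)
  j <- m$junctions[[1L]]
  expect_equal(j$k_aa, 6L)             # residues 45..50 aligned twice
  expect_equal(j$window_nt, 18L)       # 3k nt enumerated
  expect_equal(j$n_candidates, 19L)    # offsets 0..18
  expect_true(j$stitched)
  expect_equal(c(j$intron_start, j$intron_end), wx$true_intron)
})

test_that("non-overlapping fragments concatenate without enumeration", {
  wx <- worked_example()
  frags <- wx$fragments
  # trim fragment B so query spans are disjoint (ends at 50 / starts at 51)
  segB <- frags$segments[[2L]]
  segB$q_start <- 51L
  segB$t_start <- segB$t_start + 18L
  frags$segments[[2L]] <- segB
  frags$q_start[2L] <- 51L
  frags$t_start[2L] <- segB$t_start
  m <- stitch_fragments(frags, wx$genome, wx$protein, or_config())
  expect_equal(nrow(m), 1L)
  expect_equal(m$junctions[[1L]]$k_aa, 0L)
  expect_equal(m$junctions[[1L]]$n_candidates, 0L)
  expect_equal(nrow(m$exons[[1L]]), 2L)
})

test_that("a junction with no gt..ag candidate leaves fragments separate", {
  wx <- worked_example()
  genome <- wx$genome
  # destroy every GT/AG in the region between the fragments
  intron <- wx$true_intron
  sub <- substr(genome[["scaf"]], intron[1L] - 20L, intron[2L] + 20L)
  sub <- gsub("G", "C", sub)
  substr(genome[["scaf"]], intron[1L] - 20L, intron[2L] + 20L) <- sub
  expect_warning(
    m <- stitch_fragments(wx$fragments, genome, wx$protein, or_config()),
    "no gt..ag"
  )
  expect_equal(nrow(m), 2L)
  expect_false(m$junctions[[1L]]$stitched[1L])
})

test_that("stitching a single-fragment model returns it unchanged", {
  sim <- simulate_or_family(sim_config(seed = 6L, n_scaffolds = 1L,
                                       genes_per_scaffold = 1L,
                                       n_decoy_queries = 0L))
  h <- sim$alignments[1L, ]
  m <- stitch_fragments(h, sim$genome, sim$proteins[[h$query_id]],
                        or_config())
  expect_equal(nrow(m), 1L)
  seg <- h$segments[[1L]]
  expect_equal(m$exons[[1L]],
               tibble::tibble(start = sort(seg$t_start),
                              end = sort(seg$t_end)))
  expect_equal(nrow(m$junctions[[1L]]), 0L)
})

test_that("stitched junctions satisfy gt..ag on the coding strand", {
  sim <- simulate_or_family(sim_config(seed = 23L, n_scaffolds = 3L,
                                       genes_per_scaffold = 3L,
                                       fraction_fragmented = 1))
  ann <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  checked <- 0L
  for (i in seq_len(nrow(ann$models))) {
    m <- ann$models[i, ]
    j <- m$junctions[[1L]]
    j <- j[j$k_aa > 0L & j$stitched, , drop = FALSE]
    for (r in seq_len(nrow(j))) {
      don <- if (m$strand == "+") {
        substr(sim$genome[[m$scaffold]], j$intron_start[r],
               j$intron_start[r] + 1L)
      } else {
        olfactoR:::revcomp(substr(sim$genome[[m$scaffold]],
                                  j$intron_end[r] - 1L, j$intron_end[r]))
      }
      acc <- if (m$strand == "+") {
        substr(sim$genome[[m$scaffold]], j$intron_end[r] - 1L,
               j$intron_end[r])
      } else {
        olfactoR:::revcomp(substr(sim$genome[[m$scaffold]],
                                  j$intron_start[r], j$intron_start[r] + 1L))
      }
      expect_equal(don, "GT")
      expect_equal(acc, "AG")
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("fragmented simulator genes are repaired to truth exactly", {
  sim <- simulate_or_family(sim_config(seed = 14L, n_scaffolds = 2L,
                                       genes_per_scaffold = 4L,
                                       fraction_fragmented = 1))
  ann <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  truth <- sim$genes[sim$genes$fragmented, ]
  expect_gt(nrow(truth), 0L)
  for (g in seq_len(nrow(truth))) {
    m <- ann$models[ann$models$query_id == truth$gene_id[g], ]
    expect_equal(nrow(m), 1L)
    j <- m$junctions[[1L]]
    j <- j[j$k_aa > 0L, , drop = FALSE]
    expect_equal(nrow(j), 1L)
    expect_equal(j$intron_start, truth$frag_intron_start[g])
    expect_equal(j$intron_end, truth$frag_intron_end[g])
    expect_equal(j$n_valid, 1L)  # unique-candidate construction
  }
})

test_that("per-island model counts stay within fragment bounds", {
  sim <- simulate_or_family(sim_config(seed = 19L, n_scaffolds = 2L,
                                       genes_per_scaffold = 3L,
                                       fraction_fragmented = 0.5,
                                       n_decoy_queries = 2L))
  ann <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  expect_gte(nrow(ann$models), 1L)
  expect_lte(nrow(ann$models),
             sum(!grepl("^decoy", ann$hits$query_id)))
})
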