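# Locus extension, START/STOP finalization, completeness classification,
# P1/P2 merging and isoform overlap resolution.

test_that("locus extension is proportional, capped at 6000 and clamped", {
  cfg <- or_config()
  expect_equal(extend_locus(1L, 900L, 1000L, cfg), c(1L, 1000L))
  expect_equal(extend_locus(10000L, 11999L, 50000L, cfg),
               c(8000L, 13999L))                      # span 2000 -> 2000/side
  expect_equal(extend_locus(20000L, 28999L, 50000L, cfg),
               c(14000L, 34999L))                     # span 9000 -> capped 6000
})

test_that("completeness classification flips exactly at the cutoff", {
  cfg <- or_config()
  expect_equal(classify_completeness(300L, cfg), "complete")
  expect_equal(classify_completeness(299L, cfg), "partial")
  cfg100 <- or_config(min_complete_len = 100L)
  expect_equal(classify_completeness(150L, cfg100), "complete")
  expect_equal(classify_completeness(99L, cfg100), "partial")
})

premodel_row <- function(exons, strand = "+", query = "q", score = 100) {
  tibble::tibble(
    query_id = query, scaffold = "s", strand = strand,
    q_start = 1L, q_end = 10L, score = score,
    exons = list(exons), source_hit_ids = list("h"),
    defects = list(character()),
    junctions = list(olfactoR:::empty_junctions())
  )
}

test_that("START scan extends the first exon by whole codons", {
  # CDS lacking ATG; a start codon sits exactly 10 codons upstream in frame
  withr::with_seed(1L, {
    body <- paste(replicate(20L, sample(c("GCT", "TCA", "CAT"), 1L)),
                  collapse = "")
    upstream <- paste0("ATG", strrep("CCA", 9L))  # ATG then 9 benign codons
    genome <- c(s = paste0(strrep("T", 50L), upstream, body, "TAATTT"))
  })
  s0 <- 50L + 30L + 1L
  pm <- premodel_row(tibble::tibble(start = s0, end = s0 + 59L))
  fm <- finalize_models(pm, genome, or_config())
  expect_true(fm$has_start)
  expect_equal(fm$exons[[1L]]$start[1L], s0 - 30L)  # exactly 10 codons
  expect_true(fm$has_stop)                          # TAA right downstream
  expect_true(startsWith(fm$cds, "ATG"))
})

test_that("an in-frame stop inside the CDS flags a pseudogene", {
  genome <- c(s = paste0("ATGGCTGCT", "TGA", "GCTGCTGCT", "TAA"))
  pm <- premodel_row(tibble::tibble(start = 1L, end = 21L))
  fm <- finalize_models(pm, genome, or_config())
  expect_true("inframe_stop" %in% fm$defects[[1L]])
  expect_true(fm$pseudo)
  expect_match(fm$protein, "\\*")
})

test_that("an upstream in-frame stop aborts the START search", {
  genome <- c(s = paste0("ATG", "TAA", "GCTGCTGCTGCTGCTGCT", "TAG"))
  # model starts after the ATG TAA prefix; scan hits TAA before any ATG
  pm <- premodel_row(tibble::tibble(start = 7L, end = 24L))
  fm <- finalize_models(pm, genome, or_config())
  expect_false(fm$has_start)
  expect_equal(fm$exons[[1L]]$start[1L], 7L)
})

test_that("finalization never shortens a model", {
  sim <- simulate_or_family(sim_config(seed = 25L, n_scaffolds = 2L,
                                       genes_per_scaffold = 3L,
                                       pseudogene_fraction = 0.4))
  ann <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  for (i in seq_len(nrow(ann$models))) {
    m <- ann$models[i, ]
    hit_span <- range(unlist(purrr::map(
      ann$hits$segments[ann$hits$hit_id %in% m$source_hit_ids[[1L]]],
      ~ c(.x$t_start, .x$t_end))))
    expect_lte(m$start, hit_span[1L])
    expect_gte(m$end, hit_span[2L])
  }
})

test_that("P1/P2 merge keeps disjoint models and resolves overlaps by rank", {
  sim <- simulate_or_family(sim_config(seed = 5L, n_scaffolds = 1L,
                                       genes_per_scaffold = 2L))
  ann <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  p1 <- ann$models
  expect_equal(merge_p1_p2(p1, NULL), p1)
  expect_equal(merge_p1_p2(p1, p1[0L, ]), p1)

  # identical structures -> one retained (P2 provenance wins the tie)
  p2 <- p1
  p2$provenance <- "P2"
  merged <- merge_p1_p2(p1, p2)
  expect_equal(nrow(merged), nrow(p1))
  expect_true(all(merged$provenance == "P2"))

  # overlapping, p1 pseudogenous / p2 clean with equal length -> p2 wins
  p1b <- p1[1L, ]
  p1b$pseudo <- TRUE
  p1b$defects <- list("inframe_stop")
  p2b <- p1[1L, ]
  p2b$provenance <- "P2"
  merged2 <- merge_p1_p2(p1b, p2b)
  expect_equal(nrow(merged2), 1L)
  expect_equal(merged2$provenance, "P2")

  # disjoint -> both kept
  p2c <- p1[2L, ]
  p2c$provenance <- "P2"
  merged3 <- merge_p1_p2(p1[1L, ], p2c)
  expect_equal(nrow(merged3), 2L)
})

test_that("P1-only and identity-stub-P2 runs produce identical models", {
  sim <- simulate_or_family(sim_config(seed = 28L, n_scaffolds = 2L,
                                       genes_per_scaffold = 3L))
  ann1 <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  identity_refiner <- local({
    models <- ann1$models
    function(target_seq, query_protein) {
      # echo the P1 structure in slice coordinates
      i <- which(vapply(seq_len(nrow(models)), function(k) {
        cds <- models$cds[k]
        grepl(substr(cds, 1L, 60L),
              paste(target_seq, olfactoR:::revcomp(target_seq)), fixed = TRUE)
      }, logical(1L)))[1L]
      m <- models[i, ]
      ext <- extend_locus(m$start, m$end, nchar(target_seq) + m$start,
                          or_config())
      ex <- m$exons[[1L]]
      tibble::tibble(start = ex$start - ext[1L] + 1L,
                     end = ex$end - ext[1L] + 1L)
    }
  })
  ann2 <- annotate_genes(sim$alignments, sim$genome, sim$proteins,
                         refiner = identity_refiner)
  expect_equal(ann2$models$exons, ann1$models$exons)
  expect_equal(ann2$models$name, ann1$models$name)
})

test_that("a refiner returning a longer ORF wins the merge", {
  sim <- simulate_or_family(sim_config(seed = 33L, n_scaffolds = 1L,
                                       genes_per_scaffold = 1L,
                                       n_decoy_queries = 0L))
  ann1 <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  m <- ann1$models[1L, ]
  # stub: P1 structure with the first exon trimmed (shorter protein) should
  # LOSE; P1 structure itself echoed back as P2 with a trim elsewhere tests
  # the ranking; here we hand back the full structure while the pipeline's
  # own P1 is artificially truncated via a smaller completeness cutoff
  truncated <- m
  ex <- truncated$exons[[1L]]
  ex$start[1L] <- ex$start[1L] + 99L
  truncated$exons[[1L]] <- ex
  truncated <- finalize_models(
    tibble::tibble(query_id = m$query_id, scaffold = m$scaffold,
                   strand = m$strand, q_start = m$q_start, q_end = m$q_end,
                   score = m$score, exons = list(ex),
                   source_hit_ids = m$source_hit_ids,
                   defects = list(character()),
                   junctions = list(olfactoR:::empty_junctions())),
    sim$genome, or_config())
  full_p2 <- m
  full_p2$provenance <- "P2"
  merged <- merge_p1_p2(truncated, full_p2)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$provenance, "P2")
  expect_gte(merged$protein_len, truncated$protein_len)
})

test_that("refiner failures degrade gracefully to P1-only", {
  sim <- simulate_or_family(sim_config(seed = 34L, n_scaffolds = 1L,
                                       genes_per_scaffold = 1L))
  failing <- function(target_seq, query_protein) stop("boom")
  expect_warning(
    ann <- annotate_genes(sim$alignments, sim$genome, sim$proteins,
                          refiner = failing),
    "refiner failed")
  ann0 <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  expect_equal(ann$models$exons, ann0$models$exons)
})

test_that("isoform resolution keeps sub-threshold overlaps and ranks the rest", {
  sim <- simulate_or_family(sim_config(seed = 36L, n_scaffolds = 1L,
                                       genes_per_scaffold = 2L))
  ann <- annotate_genes(sim$alignments, sim$genome, sim$proteins)
  a <- ann$models[1L, ]

  mk_variant <- function(a, q_start, q_end, complete = TRUE) {
    b <- a
    b$q_start <- q_start; b$q_end <- q_end
    b$completeness <- if (complete) "complete" else "partial"
    b$protein_len <- if (complete) 400L else 100L
    b
  }
  # same query, 100-aa spans overlapping by 19 aa -> both kept
  a1 <- mk_variant(a, 1L, 100L)
  a2 <- mk_variant(a, 82L, 181L)
  both <- resolve_model_overlaps(dplyr::bind_rows(a1, a2), or_config())
  expect_equal(nrow(both), 2L)

  # overlap 60%: complete beats partial
  b1 <- mk_variant(a, 1L, 100L, complete = TRUE)
  b2 <- mk_variant(a, 41L, 140L, complete = FALSE)
  won <- resolve_model_overlaps(dplyr::bind_rows(b2, b1), or_config())
  expect_equal(nrow(won), 1L)
  expect_equal(won$completeness, "complete")

  # genomically disjoint different-query models are always kept
  expect_equal(nrow(resolve_model_overlaps(ann$models, or_config())),
               nrow(ann$models))
})
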