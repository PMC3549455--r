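test_that("generators are byte-identical across runs with the same seed", {
  expect_identical(sample_gc3_landscape(seed = 3), sample_gc3_landscape(seed = 3))
  expect_identical(sample_ortholog_pairs(seed = 3), sample_ortholog_pairs(seed = 3))
  expect_false(identical(sample_gc3_landscape(seed = 3),
                         sample_gc3_landscape(seed = 4)))
  s1 <- synthesize_cds("MKTAYIAKQR", 50, seed = 9)
  expect_identical(s1, synthesize_cds("MKTAYIAKQR", 50, seed = 9))
})

test_that("landscape sampling hits the configured class structure", {
  cfg <- landscape_config()
  g <- sample_gc3_landscape(cfg, seed = 17)
  expect_equal(nrow(g), 183L)
  expect_equal(sum(g$size_class == "macro"), 144L)
  expect_equal(sum(g$size_class == "micro"), 39L)
  ma <- g$gc3[g$size_class == "macro"]; mi <- g$gc3[g$size_class == "micro"]
  expect_lt(abs(mean(ma) - cfg$macro$mean), 3 * cfg$macro$sd / sqrt(144))
  expect_lt(abs(mean(mi) - cfg$micro$mean), 3 * cfg$micro$sd / sqrt(39))
  expect_true(all(g$gc3 >= 0 & g$gc3 <= 100))

  empty_cfg <- landscape_config(macro = list(mean = 41.5, sd = 8.6, n = 0L),
                                micro = list(mean = 56.4, sd = 10.5, n = 0L))
  expect_equal(nrow(sample_gc3_landscape(empty_cfg, seed = 1)), 0L)
})

test_that("copula coupling reaches its configured rank correlation", {
  set.seed(2)
  hi <- sample_coupled_gaussians(500, 50, 10, 50, 10, rho_s = 0.99)
  expect_gt(spearman_rank(hi$x, hi$y)$rho, 0.9)
  indep <- sample_coupled_gaussians(500, 50, 10, 50, 10, rho_s = 0)
  expect_lt(abs(spearman_rank(indep$x, indep$y)$rho), 0.1)
})

test_that("group-3 chicken exceeds group-3 snake at the configured separation", {
  hits <- vapply(1:50, function(s) {
    ort <- sample_ortholog_pairs(seed = s)
    g3 <- dplyr::filter(ort, pair_group == "3")
    mean(g3$gc3[g3$species == "chicken"]) > mean(g3$gc3[g3$species == "snake"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("synthesize_cds honours translation and the target GC3", {
  ala <- synthesize_cds(strrep("A", 100), 100, seed = 1)
  codons <- substring(ala, seq(1, 298, 3), seq(3, 300, 3))
  expect_true(all(codons %in% c("GCC", "GCG")))
  expect_equal(gc3(ala), 100)

  mw <- synthesize_cds("MW", 100, seed = 1)
  expect_equal(gc3(mw), 100)
  expect_error(synthesize_cds("MW", 40, seed = 1), "feasible range")

  prot <- random_protein(500)
  cds <- synthesize_cds(prot, 45, seed = 31)
  expect_equal(translate_dna(cds), prot)
  expect_lt(abs(gc3(cds) - 45), 2)
})

test_that("synthesize_est plants spans where it says it does", {
  cds <- synthesize_cds(random_protein(50), 50, seed = 3)
  e0 <- synthesize_est(cds, 0, 0, seed = 1)
  expect_equal(c(e0$start, e0$end), c(0L, nchar(cds)))
  e1 <- synthesize_est(cds, 100, 80, seed = 1)
  expect_equal(c(e1$start, e1$end), c(100L, 100L + nchar(cds)))
  expect_equal(substr(e1$sequence, 101, 100 + nchar(cds)), cds)
  expect_error(synthesize_est(cds, 0, 0, error_rate = 0.2), "error_rate")
})

test_that("synthesize_contig lays out exons consistently with its spans", {
  cds <- synthesize_cds(random_protein(90), 55, seed = 4)
  ct <- synthesize_contig(cds, layout = list(flank = 200L, intron_length = 50L,
                                             n_introns = 2L), seed = 5)
  expect_equal(nrow(ct$spans), 3L)
  rebuilt <- paste(purrr::map_chr(seq_len(nrow(ct$spans)), function(i) {
    substr(ct$sequence, ct$spans$start[i] + 1, ct$spans$end[i])
  }), collapse = "")
  expect_equal(rebuilt, cds)

  pure_nc <- synthesize_contig(character(0),
                               layout = list(flank = 300L, intron_length = 0L,
                                             n_introns = 0L), seed = 6)
  expect_equal(nrow(pure_nc$spans), 0L)
  expect_equal(nchar(pure_nc$sequence), 300L)
})

test_that("plant_enrichment produces the requested design", {
  pe <- plant_enrichment(n_genes = 50, n_terms = 1, relative_risk = 1, seed = 7)
  expect_equal(length(unique(pe$annotations$term)), 1L)
  expect_equal(length(pe$list_a), 50L)
  expect_true(all(!pe$list_a %in% pe$list_b))
})
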