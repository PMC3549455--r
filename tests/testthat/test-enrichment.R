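test_that("over-representation matches the Fisher oracle and filters small terms", {
  list_a <- sprintf("A%03d", 1:100)
  list_b <- sprintf("B%03d", 1:100)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = list_a[1:30], term = "big"),
    tibble::tibble(gene_id = c(list_a[1:2], list_b[1]), term = "tiny")
  )
  res <- over_representation(list_a, list_b, ann, min_term_size = 5)
  expect_equal(res$term, "big")                 # "tiny" below min_term_size
  expect_equal(c(res$a, res$b, res$c, res$d), c(30, 70, 0, 100))
  expect_equal(res$direction, "A")
  expect_equal(res$p,
               fisher_exact_2x2(matrix(c(30, 0, 70, 100), 2))$p_two_sided)
  expect_error(over_representation(character(), list_b, ann), "non-empty")
  expect_error(over_representation(list_a, list_a, ann), "disjoint")
})

test_that("swapping the lists flips direction and leaves p unchanged", {
  pe <- plant_enrichment(n_genes = 80, n_terms = 12, relative_risk = 3, seed = 5)
  r_ab <- over_representation(pe$list_a, pe$list_b, pe$annotations)
  r_ba <- over_representation(pe$list_b, pe$list_a, pe$annotations)
  m <- dplyr::inner_join(r_ab, r_ba, by = "term")
  expect_equal(m$p.x, m$p.y, tolerance = 1e-12)
  expect_true(all(m$direction.x != m$direction.y |
                    abs(m$a.x / (m$a.x + m$b.x) - m$c.x / (m$c.x + m$d.x)) < 1e-9))
})

test_that("BH q-values are monotone in p-rank and bounded by the largest p", {
  pe <- plant_enrichment(n_genes = 100, n_terms = 30, relative_risk = 2, seed = 11)
  res <- over_representation(pe$list_a, pe$list_b, pe$annotations)
  expect_true(all(diff(res$q) >= -1e-12))       # sorted by p
  expect_gte(res$q[nrow(res)], res$p[nrow(res)])
  expect_equal(res$q, p.adjust(res$p, "BH"))
})

test_that("a planted enriched term is detected across seeds", {
  hits <- vapply(1:40, function(s) {
    pe <- plant_enrichment(n_genes = 100, n_terms = 20, relative_risk = 3,
                           seed = s)
    res <- over_representation(pe$list_a, pe$list_b, pe$annotations)
    res$term[which.min(res$q)] == pe$planted_term
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("under the null the p-value distribution is well behaved", {
  ps <- unlist(lapply(1:30, function(s) {
    pe <- plant_enrichment(n_genes = 60, n_terms = 10, relative_risk = 1,
                           seed = 1000 + s)
    over_representation(pe$list_a, pe$list_b, pe$annotations)$p
  }))
  # Fisher p is conservative on discrete tables: at most binomial excess at 0.05
  frac <- mean(ps < 0.05)
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("chromosome concentration flags clustered terms", {
  rec <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                        chromosome = rep("1", 12))
  cc <- chromosome_concentration(rec$gene_id, rec)
  expect_equal(cc$fraction_on_top, 1)
  expect_true(cc$flagged)

  spread <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                           chromosome = as.character(1:12))
  cc2 <- chromosome_concentration(spread$gene_id, spread)
  expect_equal(cc2$fraction_on_top, 1 / 12)
  expect_false(cc2$flagged)

  histone_like <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                                 chromosome = c(rep("1", 8), "2", "3"))
  cc3 <- chromosome_concentration(histone_like$gene_id, histone_like)
  expect_equal(cc3$fraction_on_top, 0.8)
  expect_true(cc3$flagged)

  expect_error(chromosome_concentration("gX", spread), "known chromosome")
})

test_that("per-term GC summaries compare term mean to cohort mean", {
  gc_tbl <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                           gc = c(rep(60, 5), rep(43.2, 15)))
  gs <- category_gc_summary(sprintf("g%02d", 1:5), gc_tbl)
  expect_equal(gs$term_mean, 60)
  expect_equal(gs$difference, 60 - mean(gc_tbl$gc))
  one <- category_gc_summary("g07", gc_tbl)
  expect_equal(one$term_mean, 43.2)
  # null terms drawn from the cohort centre on zero difference
  set.seed(90)
  diffs <- vapply(1:100, function(i) {
    category_gc_summary(sample(gc_tbl$gene_id, 6), gc_tbl)$difference
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2)
})

test_that("enrichment_analysis attaches diagnostics to significant terms", {
  pe <- plant_enrichment(n_genes = 100, n_terms = 10, relative_risk = 4, seed = 2)
  recs <- tibble::tibble(gene_id = c(pe$list_a, pe$list_b),
                         chromosome = sample(as.character(1:10), 200, TRUE))
  gcs <- tibble::tibble(gene_id = c(pe$list_a, pe$list_b),
                        gc = rnorm(200, 47.4, 8))
  ea <- enrichment_analysis(pe$list_a, pe$list_b, pe$annotations,
                            gene_records = recs, gene_gc = gcs)
  top <- ea$results[1, ]
  expect_equal(top$term, pe$planted_term)
  expect_false(is.na(top$fraction_on_top))
  expect_false(is.na(top$term_mean_gc))
})
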