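test_that("exact Mann-Whitney matches full enumeration, including ties", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 1 / 3)
  expect_true(r$exact)
  set.seed(31)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:4, 1)
    vals <- sample(1:5, na + nb, replace = TRUE)  # ties likely
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(mann_whitney_u(a, b)$p_two_sided, oracle_mw_exact(a, b),
                 info = sprintf("case %d", i))
  }
})

test_that("the normal approximation behaves at larger n", {
  x <- rep(c(1, 2, 3), 10)
  r <- mann_whitney_u(x, x)            # identical multisets, n = 30 each
  expect_false(r$exact)
  expect_equal(r$p_two_sided, 1)
  set.seed(8)
  a <- rnorm(40); b <- rnorm(40, 3)
  expect_lt(mann_whitney_u(a, b)$p_two_sided, 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("spearman matches the rank formula and base R, and is monotone-invariant", {
  r <- spearman_rank(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))   # = 0.8 by the d^2 formula
  expect_equal(spearman_rank(1:10, exp(1:10))$rho, 1)
  expect_equal(spearman_rank(1:10, rev(1:10))$rho, -1)
  set.seed(14)
  x <- rnorm(50); y <- rnorm(50) + 0.5 * x
  r2 <- spearman_rank(x, y)
  expect_equal(r2$rho, cor(x, y, method = "spearman"))
  expect_equal(spearman_rank(exp(x), y)$rho, r2$rho)  # monotone transform
  expect_equal(r2$rho, cor(rank(x), rank(y)))          # Pearson on ranks
  expect_error(spearman_rank(c(1, 1, 1), 1:3), "zero variance")
})

test_that("Fisher exact p matches hypergeometric enumeration and base R", {
  r <- fisher_exact_2x2(matrix(c(26, 29, 118, 10), 2))
  expect_equal(r$odds_ratio, 260 / 3422)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_two_sided, 1)
  r2 <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r2$p_two_sided, 2 / choose(20, 10))
  set.seed(77)
  for (i in 1:50) {
    m <- matrix(rpois(4, 8), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p_two_sided,
                 fisher.test(m)$p.value, tolerance = 1e-9)
  }
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_equal(p0$p_two_sided, 1)
})

test_that("hypergeometric pmf over fixed-margin tables sums to 1", {
  for (margins in list(c(10, 8, 7), c(144, 39, 55), c(5, 5, 9))) {
    r1 <- margins[1]; r2c <- margins[2]; c1 <- margins[3]
    n <- r1 + r2c
    support <- max(0, r1 + c1 - n):min(r1, c1)
    expect_equal(sum(dhyper(support, c1, n - c1, r1)), 1, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis + Dunn behave on degenerate and separated groups", {
  same <- list(a = rep(1, 10), b = rep(1, 10), c = rep(1, 10))
  r <- kruskal_wallis_dunn(same)
  expect_equal(r$overall$H, 0)
  expect_equal(r$overall$p, 1)
  expect_true(all(r$pairs$p_adjusted == 1))

  set.seed(3)
  apart <- list(lo = runif(30, 0, 1), mid = runif(30, 10, 11),
                hi = runif(30, 20, 21))
  r2 <- kruskal_wallis_dunn(apart)
  expect_lt(r2$overall$p, 1e-10)
  expect_true(all(r2$pairs$p_adjusted < 0.001))
  # cross-check H and p against base R
  kt <- kruskal.test(unlist(apart), rep(names(apart), lengths(apart)))
  expect_equal(r2$overall$H, unname(kt$statistic))
  expect_equal(r2$overall$p, kt$p.value)
})

test_that("two-group Dunn direction agrees with Mann-Whitney", {
  set.seed(9)
  a <- rnorm(25, 40, 5); b <- rnorm(25, 55, 5)
  kd <- kruskal_wallis_dunn(list(a = a, b = b))
  ut <- mann_whitney_u(a, b)
  expect_lt(kd$pairs$mean_rank_a, kd$pairs$mean_rank_b)
  expect_lt(ut$statistic, length(a) * length(b) / 2)  # same direction
})

test_that("describe gives mean, sample sd and sem", {
  r1 <- describe(50)
  expect_equal(r1$mean, 50); expect_true(is.na(r1$sd))
  r2 <- describe(c(40, 60))
  expect_equal(r2$mean, 50)
  expect_equal(r2$sd, sqrt(200), tolerance = 1e-12)
  expect_equal(r2$sem, r2$sd / sqrt(2))
  expect_error(describe(numeric(0)), "empty")
})

test_that("mixture comparison recovers a well-separated two-component mixture", {
  set.seed(101)
  n <- 10000
  comp <- runif(n) < 0.5
  vals <- ifelse(comp, rnorm(n, 35, 5), rnorm(n, 65, 5))
  res <- fit_mixture_and_compare(vals)
  expect_s3_class(res, "mixture_comparison")
  means <- sort(res$fit2$parameters$mean)
  expect_lt(abs(means[1] - 35), 1.0)
  expect_lt(abs(means[2] - 65), 1.0)
  expect_lt(res$comparison$p_F, 1e-6)
  expect_gt(res$comparison$akaike_weight_2, 0.99)
  # nested-model contract
  expect_lte(res$fit2$ss, res$fit1$ss)
  expect_gte(res$comparison$F, 0)
  # p_F and delta AICc agree in direction
  expect_lt(res$comparison$delta_aicc, 0)
})

test_that("mixture comparison degrades gracefully on unimodal data", {
  set.seed(55)
  vals <- rnorm(183, 45, 11)
  res <- fit_mixture_and_compare(vals)
  expect_gte(res$comparison$F, 0)
  expect_true(res$comparison$p_F >= 0 && res$comparison$p_F <= 1)
  expect_error(fit_mixture_and_compare(rnorm(10)), "30")
  expect_error(fit_mixture_and_compare(rnorm(100, 50, 3), bin_width = 25),
               "fewer bins")
})

test_that("AICc and Akaike weight follow their closed forms", {
  set.seed(66)
  res <- fit_mixture_and_compare(c(rnorm(100, 35, 6), rnorm(80, 60, 7)))
  for (f in list(res$fit1, res$fit2)) {
    K <- f$n_params + 1
    expect_equal(f$aicc,
                 f$n_bins * log(f$ss / f$n_bins) + 2 * K +
                   2 * K * (K + 1) / (f$n_bins - K - 1))
  }
  d <- res$fit2$aicc - res$fit1$aicc
  expect_equal(res$comparison$akaike_weight_2, 1 / (1 + exp(d / 2)))
})

test_that("the EM likelihood alternative recovers components and matches mclust", {
  set.seed(123)
  vals <- c(rnorm(120, 35, 5), rnorm(80, 60, 6))
  em <- fit_mixture_em(vals)
  ord <- order(em$fit2$mean)
  expect_lt(abs(em$fit2$mean[ord[1]] - 35), 1.5)
  expect_lt(abs(em$fit2$mean[ord[2]] - 60), 1.5)
  expect_lt(abs(em$fit2$weight[ord[1]] - 0.6), 0.1)
  expect_gt(em$comparison$akaike_weight_2, 0.99)
  expect_gte(em$comparison$lrt, 0)
  withr::local_package("mclust")
  m2 <- Mclust(vals, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(em$loglik[2], m2$loglik, tolerance = 1e-4)
})
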