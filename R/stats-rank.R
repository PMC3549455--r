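#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of a location shift between two samples. For
#' small problems (combined n at or below `exact_limit`) the p-value is
#' exact, computed by enumerating every assignment of the pooled values to
#' the two groups (a permutation distribution, so ties are handled
#' exactly); larger problems use the normal approximation with tie
#' correction and a continuity correction.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param exact_limit Combined-size crossover between exact enumeration and
#'   the normal approximation (default 16).
#' @return One-row tibble: `method`, `statistic` (U of sample `a`),
#'   `p_two_sided`, `n_a`, `n_b`, `exact`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact_limit = 16L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("mann_whitney_u(): both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  exact <- n <= exact_limit
  if (exact) {
    combos <- utils::combn(n, na)
    u_all <- apply(combos, 2, function(idx) sum(rk[idx])) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    v <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (v == 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  tibble::tibble(method = "Mann-Whitney U", statistic = u_obs,
                 p_two_sided = p, n_a = na, n_b = nb, exact = exact)
}

#' Spearman rank correlation
#'
#' Average-rank transform of both variables followed by the product-moment
#' correlation of the ranks; the two-sided p-value uses the t approximation
#' with n - 2 degrees of freedom. Pairs with a missing value on either side
#' are dropped first.
#'
#' @param x,y Equal-length numeric vectors with at least 3 complete pairs.
#' @return One-row tibble: `rho`, `p_two_sided`, `n`.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearman_rank(): need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("spearman_rank(): zero variance in ranks; rho undefined", call. = FALSE)
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  tibble::tibble(rho = rho, p_two_sided = p, n = n)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the observed
#' table's probability (within relative tolerance 1e-7). The sample odds
#' ratio ad/bc is reported alongside.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: `method`, `odds_ratio`, `p_two_sided`, `n`,
#'   `exact`.
#' @examples
#' fisher_exact_2x2(matrix(c(26, 29, 118, 10), 2))
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == 2L), all(m >= 0), all(m == round(m)))
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    warning("fisher_exact_2x2(): a zero margin; p = 1", call. = FALSE)
    p <- 1
  } else {
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- stats::dhyper(support, c1, n - c1, r1)
    p_obs <- stats::dhyper(a, c1, n - c1, r1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  tibble::tibble(method = "Fisher exact", odds_ratio = or,
                 p_two_sided = p, n = n, exact = TRUE)
}

#' Kruskal-Wallis test with Dunn's post test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value, followed by
#' Dunn's pairwise z tests on the pooled ranks with Bonferroni-adjusted
#' two-sided p-values (capped at 1).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each
#'   non-empty).
#' @return List with `overall` (one-row tibble: `H`, `df`, `p`) and
#'   `pairs` (tibble: `group_a`, `group_b`, `z`, `mean_rank_a`,
#'   `mean_rank_b`, `p`, `p_adjusted`).
#' @export
kruskal_wallis_dunn <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L, all(lengths(groups) >= 1L))
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(pooled)
  rk <- rank(pooled)
  rsum <- tapply(rk, factor(g, levels = names(groups)), sum)
  ns <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(rsum^2 / ns) - 3 * (N + 1)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  C <- 1 - tie_term / (N^3 - N)
  if (C == 0) {
    H <- 0; p <- 1   # all observations identical
  } else {
    H <- H / C
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  mean_rank <- rsum / ns
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  combos <- utils::combn(names(groups), 2)
  n_pairs <- ncol(combos)
  pairs <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    ga <- combos[1, i]; gb <- combos[2, i]
    se <- sqrt(sigma2 * (1 / ns[[ga]] + 1 / ns[[gb]]))
    z <- if (se == 0) 0 else (mean_rank[[ga]] - mean_rank[[gb]]) / se
    p_pair <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group_a = ga, group_b = gb, z = z,
                   mean_rank_a = mean_rank[[ga]], mean_rank_b = mean_rank[[gb]],
                   p = p_pair, p_adjusted = min(1, p_pair * n_pairs))
  })
  list(overall = tibble::tibble(method = "Kruskal-Wallis", H = H,
                                df = k - 1, p = p),
       pairs = pairs)
}

#' Descriptive summary (mean, sample SD, SEM)
#'
#' @param values Non-empty numeric vector (`NA`s dropped).
#' @return One-row tibble: `mean`, `sd` (n - 1 denominator, `NA` for a
#'   single value), `sem`, `n`.
#' @export
describe <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("describe(): empty input", call. = FALSE)
  n <- length(values)
  s <- if (n >= 2L) stats::sd(values) else NA_real_
  tibble::tibble(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}
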