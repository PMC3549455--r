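# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Fourfold-degenerate codons by brute force through Biostrings' own
# translation machinery (DNAString -> AAString), independent of the
# package's code-table lookup.
oracle_fourfold <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  keep <- vapply(codons, function(cd) {
    variants <- paste0(substr(cd, 1, 2), bases)
    aa <- vapply(variants, function(v) {
      as.character(Biostrings::translate(Biostrings::DNAString(v),
                                         no.init.codon = TRUE))
    }, character(1))
    length(unique(aa)) == 1L && aa[[1]] != "*"
  }, logical(1))
  sort(codons[keep])
}

# Quadratic-time affine-gap Smith-Waterman score (gap of length L costs
# open + L * extend), for cross-checking pairwiseAlignment on small
# instances.
oracle_sw_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (deletion from a)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      s <- mat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings,
# computing U by pair counting (not rank sums).
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random amino-acid string over the 20 standard residues.
random_protein <- function(n) {
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# Two-sided 95% confidence bounds for a Spearman rho via the Fisher z
# transform with the rank-correlation variance inflation 1.06/(n - 3).
spearman_ci <- function(rho, n) {
  z <- atanh(rho)
  hw <- 1.96 * sqrt(1.06 / (n - 3))
  tanh(c(z - hw, z + hw))
}

# Evaluate code under a temporary seed, restoring global RNG state.
with_test_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Gaussian draws clamped to the percent scale (mirrors the generators'
# truncation convention).
rnorm_clamped <- function(n, mean, sd) pmin(pmax(rnorm(n, mean, sd), 0), 100)
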