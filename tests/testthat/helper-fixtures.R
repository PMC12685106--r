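# Shared fixtures: small cohort configurations sized for unit tests.

tiny_config <- function(seed = 42L, ...) {
  args <- list(
    n_cancer = 6L, n_benign = 4L, image_shape = c(8L, 8L),
    n_background_peaks = 30L, n_proteins = 40L,
    n_differential_proteins = 10L, n_correlated_proteins = 2L,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(msi_sim_config, args)
}

# a deliberately simple spectrum constructor
spec <- function(mz, intensity = rep(1, length(mz))) {
  o <- order(mz)
  list(mz = mz[o], intensity = intensity[o])
}

# brute-force Benjamini-Hochberg: q_i = min over j >= i of p_(j) * n / j
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(sort(p)[i:n] * n / (i:n)))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# brute-force two-sided Fisher: enumerate all tables with the observed
# margins, sum hypergeometric probabilities <= that of the observed table
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  hyper <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(r1 + r2, c1))
  }
  p_obs <- hyper(tab[1, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(a_range, function(a) {
    p <- hyper(a)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# Welch two-sample t from first principles
welch_brute <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  c(t = t, p = 2 * pt(-abs(t), df))
}
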