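# Independent oracles, deliberately implemented with different machinery
# than the package code paths they check.

# Sorting-based first-order features: percentile by explicit linear
# interpolation at position (n-1)q of the sorted sample; moments by direct
# sums.
oracle_features <- function(x) {
  x <- sort(x)
  n <- length(x)
  pct <- function(q) {
    h <- (n - 1) * q
    lo <- floor(h)
    if (lo + 1 >= n) return(x[n])
    x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
  }
  # mean(x) (not sum(x)/n): R refines the mean in a second pass, and a
  # one-ulp difference in mu is amplified through the centred moments far
  # beyond 1e-12 when |mu| >> sd; the oracle's independence lies in the
  # sorted-percentile and direct moment-sum formulas, not in the summation
  # primitive
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, max = x[n], min = x[1],
       kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
       skewness = if (m2 > 0) m3 / m2^1.5 else 0,
       p10 = pct(.10), p25 = pct(.25), p50 = pct(.50),
       p75 = pct(.75), p90 = pct(.90))
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# choose(n1+n2, n1) labelings (combn, not the package's DP recursion).
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * (N - n1) / 2
  labelings <- utils::combn(N, n1)
  us <- apply(labelings, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# AUC by exhaustive pair counting (double loop).
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Small noiseless phantom used across quantification tests.
tiny_phantom <- function(noise_sd = 0, seed = 1L, ...) {
  phantom_spec(grid_shape = c(16L, 16L, 4L), voxel_spacing = c(2, 2, 6),
               lesion_center = c(5, 8, 2), lesion_radius = 5,
               noise_sd = noise_sd, seed = seed, ...)
}

# Cohort with only metadata columns, for hand-built feature tests.
bare_cohort <- function(n_fav, n_unf) {
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n_fav + n_unf)),
    outcome = rep(c("favorable", "unfavorable"), c(n_fav, n_unf)),
    stringsAsFactors = FALSE)
}
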