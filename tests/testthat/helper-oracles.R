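# Independent oracles used to cross-check the package implementations.

# Bray-Curtis by the naive double loop over the closed form.
naive_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- 1 - 2 * sum(pmin(m[i, ], m[j, ])) / (sum(m[i, ]) + sum(m[j, ]))
  }
  d
}

# Single-linkage fragment binning via hclust(method = "single") cut at the
# threshold: clusters merge while the minimum gap is <= the threshold, which
# is the complement of the "new bin when gap > threshold" chaining rule.
oracle_bins <- function(sizes, threshold) {
  if (length(sizes) == 1) return(1L)
  hc <- hclust(dist(sizes), method = "single")
  unname(cutree(hc, h = threshold))
}

# Closed-form OLS via the normal equations, with the slope t-test.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  t <- beta[2] / se
  list(slope = beta[2], intercept = beta[1],
       p = 2 * pt(-abs(t), n - 2))
}

# One-factor PERMANOVA sums of squares by the group-sum distance formula:
# SS_total = sum_{i<j} d^2 / n ; SS_within = sum_g sum_{i<j in g} d^2 / n_g.
oracle_permanova_r2 <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  (ss_total - ss_within) / ss_total
}

rdirichlet1 <- function(n, alpha = 1) {
  g <- rgamma(n, shape = alpha)
  g / sum(g)
}

# Small fast scenario for pipeline-level tests.
small_scenario_config <- function(seed = 1, ...) {
  scenario_config(seed = seed, otu_pool_size = 40, n_seawater_samples = 3,
                  noise_peak_rate = 10, ...)
}
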