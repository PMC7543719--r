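# Independent brute-force oracles, deliberately naive so they share no code
# with the implementation paths they check.

# D_RS / AUC by exhaustive pair enumeration with half credit for ties.
pairs_auc_oracle <- function(lower_sample, upper_sample) {
  s <- 0
  for (a in lower_sample) for (b in upper_sample)
    s <- s + (b > a) + 0.5 * (b == a)
  s / (length(lower_sample) * length(upper_sample))
}

# Textbook Pearson correlation of two vectors.
pearson_oracle <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Full correlation matrix from the textbook formula, pair by pair.
cor_matrix_oracle <- function(ts) {
  n <- nrow(ts)
  R <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    R[i, j] <- R[j, i] <- pearson_oracle(ts[i, ], ts[j, ])
  R
}

# Removed regions by scanning every voxel of a label/mask volume pair.
voxel_scan_oracle <- function(labels, mask) {
  removed <- integer(0)
  for (k in seq_along(labels)) {
    if (mask[k] == 1 && labels[k] != 0) removed <- union(removed, labels[k])
  }
  sort(removed)
}

# Per-node intra-hemispheric strength by explicit loops.
strength_loop_oracle <- function(fc, atlas) {
  n <- nrow(atlas)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- c()
    for (j in seq_len(n)) {
      if (j != i && atlas$hemisphere[j] == atlas$hemisphere[i])
        acc <- c(acc, fc[i, j])
    }
    out[i] <- mean(acc)
  }
  names(out) <- atlas$region_id
  out
}

# Random symmetric unit-diagonal matrix in atlas order.
random_symmetric_fc <- function(n) {
  M <- matrix(stats::runif(n * n, -1, 1), n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

# Small fast cohort configuration for pipeline-level unit tests.
small_cohort_config <- function(...) {
  cohort_config(n_subjects = 31, n_seizure_free = 12, n_regions = 40,
                record_minutes = 10 / 60, n_hubs_per_hemisphere = 3,
                resection_size = 6, ...)
}
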