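# Independent brute-force oracles. These deliberately avoid the package's
# DVH/statistics code paths: metrics are computed from sorted voxel doses
# and counting, the signed-rank p by full 2^n enumeration, and Spearman's
# rho from the average-rank product-moment formula written out directly.

# Minimum dose received by at least `frac` of the voxels (step function on
# the sorted doses; no interpolation).
oracle_dose_at_fraction <- function(doses, frac) {
  d <- sort(doses, decreasing = TRUE)
  k <- ceiling(frac * length(d) - 1e-9)
  d[max(k, 1L)]
}

oracle_volume_at_dose <- function(doses, d_gy) {
  100 * mean(doses >= d_gy)
}

oracle_cn <- function(dose_values, target_mask, ref) {
  ri <- dose_values >= ref
  tvri <- sum(ri & target_mask)
  tv <- sum(target_mask)
  vri <- sum(ri)
  if (vri == 0) 0 else (tvri / tv) * (tvri / vri)
}

# Exact two-sided signed-rank p by explicit enumeration of all 2^n sign
# assignments (n <= ~14 for test use).
oracle_wilcoxon_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% r)
  p_lo <- mean(sums <= v + 1e-9)
  p_hi <- mean(sums >= v - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Small random dose grid + mask fixture
random_grid_fixture <- function(dims = c(12, 10, 8), seed = 1,
                                spacing = c(2, 2, 2)) {
  set.seed(seed)
  vals <- array(stats::runif(prod(dims), 0, 70), dim = dims)
  mask <- array(stats::runif(prod(dims)) < 0.4, dim = dims)
  if (!any(mask)) mask[1] <- TRUE
  list(dose = dose_grid(vals, spacing),
       mask = structure_mask("rand", mask, spacing))
}

uniform_fixture <- function(gy, dims = c(6, 6, 6), spacing = c(2, 2, 2)) {
  list(dose = dose_grid(array(gy, dims), spacing),
       mask = structure_mask("u", array(TRUE, dims), spacing))
}
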