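# Independent oracles and shared fixtures for the test suite. The
# oracles deliberately use naive per-element loops so they share no code
# path with the package implementation.

# Brute-force slice RGF: classify every breast pixel by its distance bin
# independently, with an explicit double loop.
oracle_slice_rgf <- function(breast, ft) {
  w <- which(breast > 0, arr.ind = TRUE)
  ci <- mean(w[, 1]); cj <- mean(w[, 2])
  R <- sqrt(nrow(w) / pi)
  r <- (1:100) / 100
  num <- den <- rep(0, 100)
  for (p in seq_len(nrow(w))) {
    d <- sqrt((w[p, 1] - ci)^2 + (w[p, 2] - cj)^2)
    inbin <- d >= r * R - 0.5 & d < r * R + 0.5
    den <- den + inbin
    if (ft[w[p, 1], w[p, 2]] > 0) num <- num + inbin
  }
  ifelse(den == 0, NA_real_, num / den)
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n + m, n) group assignments.
oracle_wilcoxon_p <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  Ws <- apply(utils::combn(length(pooled), n), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# Closed-form OLS slope.
oracle_ols_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

dice <- function(a, b) 2 * sum(a > 0 & b > 0) / (sum(a > 0) + sum(b > 0))

# Disc mask of given radius (pixel units) centred in a square grid.
disc_mask <- function(radius, n = 2 * ceiling(radius) + 21) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  (d <= radius) * 1L
}

# Random breast/FT mask pair on a small grid (FT a random subset).
random_mask_pair <- function(n = 64) {
  repeat {
    breast <- matrix(stats::runif(n * n) < stats::runif(1, 0.2, 0.7), n, n) * 1L
    if (sum(breast) >= 20) break
  }
  ft <- breast * (matrix(stats::runif(n * n), n, n) < stats::runif(1, 0, 1))
  list(breast = breast, ft = ft * 1L)
}

# Down-scaled phantom settings used where full-size volumes would be
# wastefully slow: ~18 x 28 x 20 mm half-axes.
small_spec <- function(...) {
  phantom_spec(shape = c(48L, 46L, 56L), breast_halfaxes_mm = c(18, 28, 20),
               ...)
}

# Same breast sampled on a 2 mm grid, to exercise the resampling path.
small_spec_2mm <- function(...) {
  phantom_spec(shape = c(30L, 28L, 34L), voxel_spacing_mm = c(2, 2, 2),
               breast_halfaxes_mm = c(18, 28, 20), ...)
}

# Reconstruct a labeled_volume from an oriented_breast (for round-trip
# rotation tests).
ob_as_volume <- function(ob) {
  labeled_volume(ob$breast_mask, ob$ft_mask, ob$intensities,
                 spacing = c(1, 1, 1), nipple = ob$nipple)
}

# A synthetic rgf_curve from explicit values.
make_curve <- function(values, provenance = NULL) {
  rgfbreast:::rgf_curve(seq_len(100) / 100, values, provenance)
}
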