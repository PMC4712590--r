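#' Names of the 13 RGF texture features
#'
#' Feature numbering follows the fixed order used throughout the
#' package: 1 mean RGF; 2 standard deviation of RGF; 3 slope of the
#' linear regression of RGF on r; 4 radial position of the maximum;
#' 5 minimum; 6 maximum; 7 maximum minus minimum; 8 mean of the radially
#' inner 50 % (r <= 0.5); 9 mean of the outer 50 % (r > 0.5); 10 inner
#' minus outer mean; 11 mean of the highest 10 % of values; 12 mean of
#' the lowest 10 %; 13 highest minus lowest 10 % mean.
#'
#' @return character vector of length 13.
#' @export
rgf_feature_names <- function() {
  c("mean_rgf", "sd_rgf", "slope", "r_at_max", "min_rgf", "max_rgf",
    "range_rgf", "mean_inner50", "mean_outer50", "diff_inner_outer",
    "mean_top10", "mean_bottom10", "diff_top_bottom")
}

#' Compute the 13 RGF texture features of a curve
#'
#' All statistics are taken over the defined (non-NA) curve values only.
#' The slope is the ordinary least-squares coefficient of RGF on r; the
#' radial position of the maximum is the smallest r attaining it; the
#' inner 50 % is r <= 0.5 inclusive; the highest/lowest 10 % are the
#' largest/smallest `round(n/10)` order statistics (10 of 100 for a
#' fully defined curve, proportionally fewer otherwise). The three
#' difference features are exact identities of their parents.
#'
#' @param curve an `rgf_curve` with at least 90 defined values.
#' @return named numeric vector of length 13 (names from
#'   [rgf_feature_names()]).
#' @export
compute_features <- function(curve) {
  stopifnot(inherits(curve, "rgf_curve"))
  ok <- !is.na(curve$value)
  if (sum(!ok) > 10L)
    stop("curve has ", sum(!ok), " undefined radii (> 10); too truncated ",
         "for feature extraction")
  r <- curve$r[ok]
  v <- curve$value[ok]
  n <- length(v)

  slope <- if (stats::var(r) > 0) stats::cov(r, v) / stats::var(r) else NA_real_
  vmax <- max(v); vmin <- min(v)
  inner <- v[r <= 0.5]; outer <- v[r > 0.5]
  m <- max(1L, round(n / 10))
  vs <- sort(v)
  top <- mean(vs[(n - m + 1L):n]); bottom <- mean(vs[seq_len(m)])

  out <- c(mean(v),
           stats::sd(v),
           slope,
           min(r[v == vmax]),
           vmin,
           vmax,
           vmax - vmin,
           mean(inner),
           mean(outer),
           mean(inner) - mean(outer),
           top,
           bottom,
           top - bottom)
  names(out) <- rgf_feature_names()
  out
}

#' RGF features for the three regions of a subject
#'
#' @param ob an `oriented_breast` with an FT mask.
#' @return a 3 x 13 numeric matrix, rows posterior / middle / anterior,
#'   columns the features of [rgf_feature_names()].
#' @export
features_for_subject <- function(ob) {
  curves <- subject_rgf(ob)
  t(vapply(curves, compute_features, numeric(13L)))
}
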