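#' Area-equivalent breast radius of a coronal slice
#'
#' The radius R of the circle whose area equals the breast area of the
#' slice: R = sqrt(A / pi) with A the breast pixel count times the pixel
#' area. By construction pi R^2 reproduces the pixel area exactly.
#'
#' @param slice_mask 2D binary matrix (non-empty).
#' @param pixel_area_mm2 area of one pixel (1 for the 1 mm grid of the
#'   oriented breast).
#' @return radius in mm.
#' @export
breast_radius <- function(slice_mask, pixel_area_mm2 = 1) {
  n <- sum(slice_mask > 0)
  if (n == 0) stop("empty breast slice")
  sqrt(n * pixel_area_mm2 / pi)
}

#' Radial glandular fraction of one coronal slice
#'
#' For relative radii r_k = k/100 (k = 1..100), RGF(r_k) is the fraction
#' of fibroglandular pixels among the breast pixels lying on the circle
#' of radius r_k * R centred at the breast mask's centre of mass, where R
#' is the area-equivalent breast radius. The circle is rasterized as the
#' one-pixel annulus of centre distances in \[r_k R - 0.5, r_k R + 0.5);
#' annuli of unit width partition the plane, so every pixel has an
#' unambiguous bin. Only pixels inside the breast mask enter numerator
#' and denominator (circles can exit the non-circular breast); radii
#' whose annulus contains no breast pixel are undefined (`NA`).
#'
#' @param breast_slice 2D binary matrix, non-empty.
#' @param ft_slice 2D binary matrix, subset of `breast_slice`.
#' @param provenance optional identifier carried on the curve.
#' @return an `rgf_curve`: list with `r` (100 radii), `value` (100
#'   fractions in \[0,1\] or NA) and `provenance`.
#' @export
slice_rgf <- function(breast_slice, ft_slice, provenance = NULL) {
  b <- breast_slice > 0
  if (!any(b)) stop("empty breast slice")
  f <- ft_slice > 0
  if (any(f & !b)) stop("FT slice is not a subset of the breast slice")
  w <- which(b, arr.ind = TRUE)
  ci <- mean(w[, 1]); cj <- mean(w[, 2])
  d <- sqrt((w[, 1] - ci)^2 + (w[, 2] - cj)^2)
  isft <- f[w]
  R <- sqrt(nrow(w) / pi)
  r <- seq_len(100L) / 100
  val <- vapply(r, function(rk) {
    sel <- d >= rk * R - 0.5 & d < rk * R + 0.5
    den <- sum(sel)
    if (den == 0) NA_real_ else sum(isft[sel]) / den
  }, numeric(1))
  rgf_curve(r, val, provenance)
}

rgf_curve <- function(r, value, provenance = NULL) {
  stopifnot(length(r) == 100L, length(value) == 100L,
            all(diff(r) > 0),
            all(is.na(value) | (value >= 0 & value <= 1)))
  structure(list(r = as.numeric(r), value = as.numeric(value),
                 provenance = provenance),
            class = "rgf_curve")
}

#' @export
print.rgf_curve <- function(x, ...) {
  nd <- sum(!is.na(x$value))
  cat("<rgf_curve>", if (!is.null(x$provenance)) paste0("[", x$provenance, "]"),
      nd, "of 100 radii defined; mean RGF",
      sprintf("%.3f", mean(x$value, na.rm = TRUE)), "\n")
  invisible(x)
}

#' @export
plot.rgf_curve <- function(x, ..., ylim = c(0, 1)) {
  graphics::plot(x$r, x$value, type = "l", xlab = "relative radius r",
                 ylab = "RGF", ylim = ylim, ...)
  invisible(x)
}

#' Divide the breast into posterior, middle and anterior regions
#'
#' Splits the ordered coronal slice range (chest wall to nipple) into
#' three equal thirds and identifies each region's central slice, around
#' which a five-slice averaging window is placed. With N slices the
#' regions cover 1-based slice indices \[1, floor(N/3)\],
#' (floor(N/3), floor(2N/3)\] and (floor(2N/3), N\]; the central slice is
#' the floor of the region's mean index.
#'
#' @param slices list of coronal slices from [coronal_slices()], or an
#'   integer slice count.
#' @return a `region_scheme`: `n_slices`, `region_start`, `region_end`,
#'   `centers` (all 1-based), `window = 5`, and region names.
#' @export
define_regions <- function(slices) {
  n <- if (is.numeric(slices)) as.integer(slices) else length(slices)
  if (n < 15L)
    stop("need at least 15 coronal slices for three 5-slice windows; ",
         "got ", n, " (resample finer or use a larger breast)")
  b1 <- floor(n / 3); b2 <- floor(2 * n / 3)
  start <- c(1L, b1 + 1L, b2 + 1L)
  end <- c(b1, b2, n)
  centers <- floor((start - 1 + end - 1) / 2) + 1L
  structure(list(n_slices = n, region_start = start, region_end = end,
                 centers = as.integer(centers), window = 5L,
                 regions = c("posterior", "middle", "anterior")),
            class = "region_scheme")
}

#' Region RGF curve by five-slice averaging
#'
#' The region's RGF is the pointwise mean, at each relative radius, of
#' the slice RGF curves of the five coronal slices centred on the
#' region's central slice. Undefined values are skipped at each radius;
#' the region value is undefined only where all contributing slices are.
#' Slices with an empty breast mask are excluded with a warning.
#'
#' @param slices list of coronal slices (posterior to anterior).
#' @param scheme a `region_scheme` for these slices.
#' @param region `"posterior"`, `"middle"` or `"anterior"` (or 1..3).
#' @return an `rgf_curve` with the region id as provenance.
#' @export
region_rgf <- function(slices, scheme, region) {
  stopifnot(inherits(scheme, "region_scheme"),
            length(slices) == scheme$n_slices)
  if (is.character(region)) region <- match(region, scheme$regions)
  stopifnot(region %in% 1:3)
  s <- scheme$centers[region]
  win <- (s - 2L):(s + 2L)
  if (any(win < 1L) || any(win > scheme$n_slices))
    stop("five-slice window does not fit the slice range")
  curves <- list()
  for (i in win) {
    if (sum(slices[[i]]$breast) == 0) {
      warning("coronal slice ", i, " has an empty breast mask; excluded")
      next
    }
    curves[[length(curves) + 1L]] <-
      slice_rgf(slices[[i]]$breast, slices[[i]]$ft, provenance = i)
  }
  if (length(curves) == 0)
    stop("all five slices of region ", scheme$regions[region], " are empty")
  vals <- sapply(curves, function(cv) cv$value)
  m <- rowMeans(vals, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  rgf_curve(curves[[1]]$r, m, provenance = scheme$regions[region])
}

#' Region RGF curves for one subject
#'
#' Runs [coronal_slices()], [define_regions()] and [region_rgf()] for the
#' three regions of an oriented breast.
#'
#' @param ob an `oriented_breast` with an FT mask.
#' @return named list of three `rgf_curve`s: posterior, middle, anterior.
#' @export
subject_rgf <- function(ob) {
  sl <- coronal_slices(ob)
  sch <- define_regions(sl)
  stats::setNames(lapply(1:3, function(k) region_rgf(sl, sch, k)),
                  sch$regions)
}
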