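#' Fibroglandular tissue segmentation adapter
#'
#' Pluggable FT segmentation for intensity volumes. The default,
#' `precomputed`, passes an existing FT mask through untouched — the
#' pipeline is designed around externally supplied segmentations. Two
#' simple intensity methods are provided so the end-to-end pipeline can
#' run on rendered phantoms: a fixed attenuation threshold, and
#' two-cluster k-means on the intensities within the breast with the
#' higher-mean cluster taken as FT.
#'
#' @param vol a `labeled_volume` with a breast mask; intensity methods
#'   require `intensities`.
#' @param method `"precomputed"`, `"threshold"` or `"kmeans2"`.
#' @param hu_threshold intensity cut for the threshold method (FT =
#'   breast voxels with intensity >= threshold).
#' @param seed integer seed for the k-means initialization.
#' @return the volume with `ft_mask` populated (subset of the breast
#'   mask by construction).
#' @export
segment_ft <- function(vol, method = c("precomputed", "threshold", "kmeans2"),
                       hu_threshold = NULL, seed = 1L) {
  stopifnot(inherits(vol, "labeled_volume"))
  method <- match.arg(method)
  if (method == "precomputed") {
    if (is.null(vol$ft_mask))
      stop("method 'precomputed' requires an FT mask on the volume")
    return(vol)
  }
  if (is.null(vol$intensities))
    stop("method '", method, "' requires an intensity volume")
  idx <- which(vol$breast_mask > 0)
  vals <- vol$intensities[idx]
  ft <- array(0L, dim(vol$breast_mask))
  if (method == "threshold") {
    if (is.null(hu_threshold))
      stop("method 'threshold' requires hu_threshold")
    ft[idx[vals >= hu_threshold]] <- 1L
  } else {
    if (stats::sd(vals) < 1e-8) {
      warning("breast intensities are (near-)uniform; k-means is ",
              "degenerate, returning an empty FT mask")
    } else {
      set.seed(seed)
      centers <- unname(stats::quantile(vals, c(0.25, 0.75)))
      if (diff(centers) == 0) centers <- range(vals)
      km <- stats::kmeans(vals, centers = centers)
      ft[idx[km$cluster == which.max(km$centers)]] <- 1L
    }
  }
  vol$ft_mask <- ft
  vol
}
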