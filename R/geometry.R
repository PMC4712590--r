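#' Resample a volume to cubic 1 mm voxels
#'
#' Separable linear interpolation onto a 1 mm isotropic grid covering the
#' same physical extent (bilinear within a plane, linear across planes).
#' Intensities are interpolated directly; masks are interpolated as real
#' fields and re-binarized at 0.5, after which the FT mask is intersected
#' with the breast mask so the subset invariant survives thresholding.
#' A volume that is already 1 mm isotropic is returned unchanged.
#'
#' @param vol a `labeled_volume` with known, strictly positive spacing.
#' @return a `labeled_volume` with `spacing = c(1, 1, 1)`.
#' @export
resample_isotropic <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  sp <- vol$spacing
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("degenerate voxel spacing")
  if (all(sp == 1)) return(vol)

  dm <- dim(vol$breast_mask)
  mats <- lapply(1:3, function(k) interp_matrix(dm[k], sp[k]))

  resample1 <- function(a, mask) {
    if (is.null(a)) return(NULL)
    x <- array(as.double(a), dim(a))
    for (k in 1:3) x <- apply_along_axis(x, mats[[k]], k)
    if (mask) {
      m <- array(0L, dim(x)); m[x >= 0.5] <- 1L; m
    } else x
  }
  breast <- resample1(vol$breast_mask, TRUE)
  ft <- resample1(vol$ft_mask, TRUE)
  if (!is.null(ft)) ft <- ft * breast
  nip <- vol$nipple
  if (!is.null(nip)) {
    nip <- as.integer(round((nip - 0.5) * sp + 0.5))
    nip <- pmin(pmax(nip, 1L), dim(breast))
  }
  labeled_volume(breast, ft, resample1(vol$intensities, FALSE),
                 spacing = c(1, 1, 1), nipple = nip)
}

# Linear-interpolation matrix taking n_old samples at `spacing` mm onto a
# 1 mm grid over the same extent, cell-centred: voxel i covers
# ((i-1)*s, i*s) with its sample at (i-0.5)*s. The half-cell offset keeps
# 1 mm sample positions off the midpoints between coarser source samples,
# where thresholded masks would otherwise be biased by exact 0.5 ties.
interp_matrix <- function(n_old, spacing) {
  n_new <- max(1L, as.integer(round(n_old * spacing)))
  t <- (seq_len(n_new) - 0.5) / spacing + 0.5  # fractional source index
  lo <- pmin(pmax(floor(t), 1), max(n_old - 1, 1))
  w <- pmin(pmax(t - lo, 0), 1)
  M <- matrix(0, n_new, n_old)
  M[cbind(seq_len(n_new), lo)] <- 1 - w
  if (n_old > 1) M[cbind(seq_len(n_new), lo + 1)] <- M[cbind(seq_len(n_new), lo + 1)] + w
  M
}

apply_along_axis <- function(a, M, axis) {
  dm <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(a, perm)
  out <- M %*% matrix(x, nrow = dm[axis])
  array(aperm(array(out, c(nrow(M), dm[perm[2]], dm[perm[3]])),
              order(perm)), replace(dm, axis, nrow(M)))
}

#' Nipple angle in the axial plane
#'
#' The acute angle between the anterior-posterior direction and the
#' breast-orientation vector — the in-plane line from the centre of the
#' breast (the in-plane centroid of the whole-breast mask) to the nipple
#' — measured in the axial plane. Rotating the volume by this angle
#' about the same centroid ([rotate_about_si()]) brings the nipple onto
#' the anterior axis. The sign encodes the rotation direction: positive
#' when the nipple is displaced towards increasing left-right index.
#'
#' @param vol a `labeled_volume`; its `nipple` landmark is used if
#'   present, otherwise [detect_nipple()] is called when
#'   `auto_detect = TRUE`.
#' @param auto_detect fall back to surface-based nipple detection.
#' @return angle in degrees, in (-90, 90].
#' @export
nipple_angle <- function(vol, auto_detect = FALSE) {
  stopifnot(inherits(vol, "labeled_volume"))
  nip <- vol$nipple
  if (is.null(nip)) {
    if (!auto_detect)
      stop("no nipple landmark present; supply one or set auto_detect = TRUE")
    nip <- detect_nipple(vol)
  }
  sp <- vol$spacing
  w <- which(vol$breast_mask > 0, arr.ind = TRUE)
  if (nrow(w) == 0) stop("breast mask is empty")
  d_ant <- (mean(w[, 2]) - nip[2]) * sp[2]
  d_lr <- (nip[3] - mean(w[, 3])) * sp[3]
  ang <- atan2(d_lr, d_ant) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Detect the nipple on the breast surface
#'
#' When no landmark is available: the chest-wall plane is estimated as
#' the least-squares plane through the posterior boundary of the breast
#' mask (the most posterior breast voxel of each superior-inferior /
#' left-right column), and the nipple is the breast voxel with maximal
#' perpendicular distance from that plane.
#'
#' @param vol a `labeled_volume` with a non-empty breast mask.
#' @return integer length-3 voxel coordinate.
#' @export
detect_nipple <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  sp <- vol$spacing
  dm <- dim(vol$breast_mask)
  # posterior boundary: max AP index per (SI, LR) column
  has <- apply(vol$breast_mask, c(1, 3), function(col) {
    w <- which(col > 0)
    if (length(w)) max(w) else NA_integer_
  })
  b <- which(!is.na(has), arr.ind = TRUE)
  if (nrow(b) == 0) stop("breast mask is empty")
  x1 <- b[, 1] * sp[1]; x3 <- b[, 2] * sp[3]; y <- has[b] * sp[2]
  # boundary columns that end on the breast dome rather than the chest
  # wall contaminate the plane fit; trim anterior outliers and refit
  keep <- rep(TRUE, length(y))
  cf <- c(mean(y), 0, 0)
  for (it in 1:3) {
    if (sum(keep) >= 3) {
      fit <- stats::lm(y ~ x1 + x3, subset = keep)
      cf <- stats::coef(fit)
      cf[is.na(cf)] <- 0
      res <- y - (cf[1] + cf[2] * x1 + cf[3] * x3)
      keep <- res > -3 * max(sp)       # keep points near or behind the plane
    }
  }
  nrm <- sqrt(1 + cf[2]^2 + cf[3]^2)
  v <- which(vol$breast_mask > 0, arr.ind = TRUE)
  dist <- (cf[1] + cf[2] * v[, 1] * sp[1] + cf[3] * v[, 3] * sp[3] -
             v[, 2] * sp[2]) / nrm
  # the dome is locally flat, so voxels tie at the maximum to within the
  # grid resolution; their centroid is the apex
  near <- dist >= max(dist) - max(sp)
  as.integer(round(colMeans(v[near, , drop = FALSE])))
}

#' Rotate a volume about the superior-inferior axis
#'
#' Applies one global in-plane rotation to every axial plane, about the
#' in-plane centroid of the whole breast mask, using bilinear
#' interpolation (out-of-grid samples read as background). Rotating by
#' the volume's nipple angle brings the nipple onto the anterior axis
#' through the centroid. Masks are re-binarized at 0.5 and the FT mask
#' intersected with the breast mask.
#'
#' @param vol a 1 mm isotropic `labeled_volume` (see
#'   [resample_isotropic()]).
#' @param angle_deg rotation angle in degrees, normally the value
#'   returned by [nipple_angle()].
#' @return an `oriented_breast`: masks, optional intensities, the applied
#'   `rotation_angle_deg`, the transformed nipple voxel, and
#'   `coronal_axis = 2` (coronal slices are indexed along grid axis 2).
#' @export
rotate_about_si <- function(vol, angle_deg) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!all(vol$spacing == 1))
    stop("rotate_about_si expects a 1 mm isotropic volume")
  dm <- dim(vol$breast_mask)
  w <- which(vol$breast_mask > 0, arr.ind = TRUE)
  if (nrow(w) == 0) stop("breast mask is empty")
  c2 <- mean(w[, 2]); c3 <- mean(w[, 3])
  th <- angle_deg * pi / 180

  # inverse map: for each target in-plane position, the source position
  jk <- expand.grid(j = seq_len(dm[2]), k = seq_len(dm[3]))
  dj <- jk$j - c2; dk <- jk$k - c3
  sj <- c2 + cos(th) * dj + sin(th) * dk
  sk <- c3 - sin(th) * dj + cos(th) * dk
  g <- bilinear_gather(sj, sk, dm[2], dm[3])

  rot1 <- function(a, mask) {
    if (is.null(a)) return(NULL)
    out <- array(0, dm)
    for (i in seq_len(dm[1])) {
      s <- as.double(a[i, , ])
      out[i, , ] <- g$w00 * s[g$i00] + g$w01 * s[g$i01] +
                    g$w10 * s[g$i10] + g$w11 * s[g$i11]
    }
    if (mask) {
      m <- array(0L, dm); m[out >= 0.5] <- 1L; m
    } else out
  }
  breast <- rot1(vol$breast_mask, TRUE)
  ft <- rot1(vol$ft_mask, TRUE)
  if (!is.null(ft)) ft <- ft * breast

  nip <- vol$nipple
  if (!is.null(nip)) {
    n2 <- c2 + cos(th) * (nip[2] - c2) - sin(th) * (nip[3] - c3)
    n3 <- c3 + sin(th) * (nip[2] - c2) + cos(th) * (nip[3] - c3)
    nip <- as.integer(round(c(nip[1], n2, n3)))
    nip <- pmin(pmax(nip, 1L), dm)
  }
  structure(list(breast_mask = breast, ft_mask = ft,
                 intensities = rot1(vol$intensities, FALSE),
                 rotation_angle_deg = angle_deg, coronal_axis = 2L,
                 nipple = nip, spacing = c(1, 1, 1)),
            class = "oriented_breast")
}

# Precompute bilinear gather indices/weights for positions (sj, sk) on an
# n2 x n3 grid; samples falling outside the grid get zero weight.
bilinear_gather <- function(sj, sk, n2, n3) {
  j0 <- floor(sj); k0 <- floor(sk)
  fj <- sj - j0; fk <- sk - k0
  ok <- function(j, k) j >= 1 & j <= n2 & k >= 1 & k <= n3
  idx <- function(j, k, valid) ifelse(valid, (k - 1) * n2 + j, 1L)
  v00 <- ok(j0, k0); v01 <- ok(j0, k0 + 1)
  v10 <- ok(j0 + 1, k0); v11 <- ok(j0 + 1, k0 + 1)
  list(i00 = idx(j0, k0, v00), w00 = (1 - fj) * (1 - fk) * v00,
       i01 = idx(j0, k0 + 1, v01), w01 = (1 - fj) * fk * v01,
       i10 = idx(j0 + 1, k0, v10), w10 = fj * (1 - fk) * v10,
       i11 = idx(j0 + 1, k0 + 1, v11), w11 = fj * fk * v11)
}

#' @export
print.oriented_breast <- function(x, ...) {
  cat("<oriented_breast> ", paste(dim(x$breast_mask), collapse = " x "),
      " voxels @ 1 mm, rotated ", sprintf("%.2f", x$rotation_angle_deg),
      " deg\n", sep = "")
  invisible(x)
}

#' Extract coronal slices from an oriented breast
#'
#' Returns the non-empty coronal planes as 2D (breast, FT) mask pairs,
#' ordered from the chest wall (posterior, first element) to the nipple
#' (anterior, last element); empty leading and trailing planes are
#' trimmed.
#'
#' @param ob an `oriented_breast`.
#' @return a list of `list(breast =, ft =)` 2D matrices
#'   (superior-inferior by left-right).
#' @export
coronal_slices <- function(ob) {
  stopifnot(inherits(ob, "oriented_breast"))
  counts <- apply(ob$breast_mask, 2, sum)
  nz <- which(counts > 0)
  if (length(nz) == 0) stop("breast mask is empty")
  js <- seq(max(nz), min(nz))           # posterior -> anterior
  lapply(js, function(j)
    list(breast = ob$breast_mask[, j, ],
         ft = if (is.null(ob$ft_mask)) NULL else ob$ft_mask[, j, ]))
}

#' Full geometric preprocessing
#'
#' Convenience wrapper: resample to 1 mm cubic voxels, measure the nipple
#' angle, and rotate the volume so the breast axis is aligned with the
#' anterior direction.
#'
#' @inheritParams nipple_angle
#' @return an `oriented_breast`.
#' @export
preprocess_volume <- function(vol, auto_detect = FALSE) {
  iso <- resample_isotropic(vol)
  rotate_about_si(iso, nipple_angle(iso, auto_detect = auto_detect))
}
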