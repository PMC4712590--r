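#' Specification of a synthetic breast phantom
#'
#' Describes a half-ellipsoid breast attached to a flat chest-wall plane,
#' plus the spatial pattern of its fibroglandular tissue. The breast
#' occupies the anterior half of an ellipsoid whose axis is tilted
#' in-plane by `nipple_offset_deg` about the superior-inferior axis; the
#' nipple is the most distal point of that axis and is stored as a
#' landmark on the generated volume.
#'
#' FT pattern modes:
#' \describe{
#'   \item{nonsparse}{centrally condensed FT: voxels are ranked by a
#'     radially decaying weight `exp(-d / decay_scale)` (`d` = in-plane
#'     distance from the coronal slice centroid, mm) plus Gaussian jitter,
#'     and the top `ft_fraction` of breast voxels become FT. The radial
#'     profile decays from centre to periphery.}
#'   \item{sparse}{scattered FT: spherical clusters of radius
#'     `cluster_radius_mm` are dropped at uniformly random positions in
#'     the breast until the FT fraction reaches `ft_fraction`, giving a
#'     near-flat radial profile.}
#'   \item{uniform}{independent Bernoulli(`ft_fraction`) voxels.}
#'   \item{annulus}{FT exactly where relative radius lies within
#'     `annulus_bounds` (a structured test pattern).}
#'   \item{full, empty}{FT equals the breast mask / is empty.}
#' }
#'
#' @param shape integer length-3 grid dimensions (superior-inferior,
#'   anterior-posterior, left-right).
#' @param voxel_spacing_mm numeric length-3, strictly positive.
#' @param breast_halfaxes_mm numeric length-3 ellipsoid half-axes, mm:
#'   along the superior-inferior axis, along the (tilted) breast axis,
#'   and along the in-plane direction perpendicular to it.
#' @param nipple_offset_deg in-plane angle (degrees) between the breast
#'   axis and the anterior direction.
#' @param ft_mode one of `"nonsparse"`, `"sparse"`, `"uniform"`,
#'   `"annulus"`, `"empty"`, `"full"`.
#' @param ft_fraction target fibroglandular composition, in \[0, 1\].
#' @param cluster_radius_mm sphere radius for sparse mode, mm.
#' @param decay_scale radial decay length for non-sparse mode, mm.
#' @param annulus_bounds length-2 relative-radius bounds for annulus mode.
#' @param seed integer; all randomness in [generate_phantom()] derives
#'   from it.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 88L, 112L),
                         voxel_spacing_mm = c(1, 1, 1),
                         breast_halfaxes_mm = c(40, 60, 45),
                         nipple_offset_deg = 0,
                         ft_mode = c("nonsparse", "sparse", "uniform",
                                     "annulus", "empty", "full"),
                         ft_fraction = 0.25,
                         cluster_radius_mm = 5,
                         decay_scale = 15,
                         annulus_bounds = c(0.3, 0.6),
                         seed = 1L) {
  ft_mode <- match.arg(ft_mode)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0),
            length(breast_halfaxes_mm) == 3L, all(breast_halfaxes_mm > 0),
            length(ft_fraction) == 1L, ft_fraction >= 0, ft_fraction <= 1,
            cluster_radius_mm > 0, decay_scale > 0,
            length(annulus_bounds) == 2L,
            all(annulus_bounds >= 0), all(annulus_bounds <= 1),
            annulus_bounds[1] <= annulus_bounds[2])
  structure(list(shape = shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 breast_halfaxes_mm = as.numeric(breast_halfaxes_mm),
                 nipple_offset_deg = as.numeric(nipple_offset_deg),
                 ft_mode = ft_mode, ft_fraction = as.numeric(ft_fraction),
                 cluster_radius_mm = as.numeric(cluster_radius_mm),
                 decay_scale = as.numeric(decay_scale),
                 annulus_bounds = as.numeric(annulus_bounds),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic breast volume
#'
#' Realizes a [phantom_spec()] as a [labeled_volume()]: builds the
#' half-ellipsoid breast mask, fills in the FT mask according to the
#' requested pattern mode, and stores the nipple landmark (the most
#' distal point of the breast axis). Deterministic given `spec$seed`.
#'
#' For the `nonsparse`, `sparse` and `uniform` modes the realized
#' fibroglandular composition lands within 0.05 of `ft_fraction`.
#'
#' @param spec a `phantom_spec`.
#' @return a `labeled_volume` with breast mask, FT mask and nipple set.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$shape
  sp <- spec$voxel_spacing_mm
  ax <- spec$breast_halfaxes_mm
  theta <- spec$nipple_offset_deg * pi / 180

  # world coordinates of voxel centres: (index - 1) * spacing
  si <- (seq_len(dm[1]) - 1) * sp[1]
  ap <- (seq_len(dm[2]) - 1) * sp[2]
  lr <- (seq_len(dm[3]) - 1) * sp[3]

  # chest-wall plane tilts rigidly with the breast axis; keep its most
  # posterior reach 4 mm inside the grid
  centre <- c(mean(range(si)),
              max(ap) - 4 - ax[3] * abs(sin(theta)),
              mean(range(lr)))
  if (centre[2] < 0)
    stop("grid too shallow in the anterior-posterior direction")

  # breast axis u (into the breast, anterior = decreasing AP) tilted by
  # theta; v is its in-plane perpendicular
  u <- c(-cos(theta), sin(theta))      # (AP, LR) components
  v <- c(sin(theta), cos(theta))

  dsi <- si - centre[1]
  dap <- ap - centre[2]
  dlr <- lr - centre[3]
  # ellipsoid-frame squared coordinates, broadcast over the grid
  p1 <- (dsi / ax[1])^2
  A2 <- outer(dap * u[1], dlr * u[2], "+") / ax[2]   # AP x LR
  A3 <- outer(dap * v[1], dlr * v[2], "+") / ax[3]
  q <- A2^2 + A3^2                                   # AP x LR
  to3d <- function(m) aperm(array(m, c(dm[2], dm[3], dm[1])), c(3, 1, 2))
  # anterior half of the ellipsoid in its own (tilted) frame, so the
  # shape is the upright half-ellipsoid rigidly rotated by theta
  breast <- array(0L, dm)
  breast[sweep(to3d(q), 1, p1, "+") <= 1 & to3d(A2 >= 0)] <- 1L
  if (sum(breast) == 0)
    stop("breast ellipsoid produced an empty mask")

  # the half-ellipsoid must lie fully inside the grid
  if (any(breast[1, , ] > 0) || any(breast[dm[1], , ] > 0) ||
      any(breast[, 1, ] > 0) || any(breast[, dm[2], ] > 0) ||
      any(breast[, , 1] > 0) || any(breast[, , dm[3]] > 0))
    stop("breast ellipsoid exceeds the grid bounds; enlarge `shape` or ",
         "shrink `breast_halfaxes_mm`")

  nipple_world <- c(centre[1], centre[2] + ax[2] * u[1],
                    centre[3] + ax[2] * u[2])
  nipple <- as.integer(round(nipple_world / sp)) + 1L

  # breast-frame coordinates of every breast voxel: q1 along the
  # superior-inferior axis, q2 along the breast axis (0 at the chest
  # wall, ax[2] at the nipple), q3 along the in-plane perpendicular.
  # All FT patterns are defined in this frame, so a tilted phantom
  # carries the rigidly rotated pattern of its untilted counterpart and
  # the downstream geometry pipeline can be validated against rotation.
  idx <- which(breast > 0)
  ai <- arrayInd(idx, dm)
  dap_v <- (ai[, 2] - 1) * sp[2] - centre[2]
  dlr_v <- (ai[, 3] - 1) * sp[3] - centre[3]
  frame <- list(idx = idx, dm = dm, sp = sp, centre = centre,
                halfaxes = ax, u = u, v = v, breast = breast,
                q1 = (ai[, 1] - 1) * sp[1] - centre[1],
                q2 = dap_v * u[1] + dlr_v * u[2],
                q3 = dap_v * v[1] + dlr_v * v[2])

  ft <- switch(spec$ft_mode,
    full = breast,
    empty = array(0L, dm),
    uniform = ft_uniform(frame, spec$ft_fraction),
    nonsparse = ft_nonsparse(frame, spec$ft_fraction, spec$decay_scale),
    sparse = ft_sparse(frame, spec$ft_fraction, spec$cluster_radius_mm),
    annulus = ft_annulus(frame, spec$annulus_bounds))

  labeled_volume(breast, ft, spacing = sp, nipple = nipple)
}

# Smooth isotropic random field evaluated at breast-frame coordinates: a
# sum of random cosine waves with mm-scale wavelengths. Because it is a
# function of the frame coordinates, the field co-rotates rigidly with a
# tilted breast.
cosine_field <- function(Q, n_waves = 48L, wavelength_mm = c(6, 12)) {
  dirs <- matrix(stats::rnorm(3L * n_waves), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  kmag <- 2 * pi / stats::runif(n_waves, wavelength_mm[1], wavelength_mm[2])
  K <- dirs * kmag
  phase <- stats::runif(n_waves, 0, 2 * pi)
  amp <- stats::rnorm(n_waves)
  drop(cos(sweep(Q %*% t(K), 2, phase, "+")) %*% amp) / sqrt(n_waves)
}

ft_from_score <- function(frame, frac, score) {
  ft <- array(0L, frame$dm)
  k <- round(frac * length(frame$idx))
  if (k > 0)
    ft[frame$idx[order(score, decreasing = TRUE)[seq_len(k)]]] <- 1L
  ft
}

# Spatially flat FT: the thresholded random field gives mm-scale tissue
# blobs (voxel speckle would be eroded by interpolation) at exactly the
# target fraction.
ft_uniform <- function(frame, frac) {
  ft_from_score(frame, frac,
                cosine_field(cbind(frame$q1, frame$q2, frame$q3)))
}

# Centrally condensed FT: weight decays with the distance from the
# breast axis; the random-field jitter roughens the boundary.
ft_nonsparse <- function(frame, frac, decay_scale) {
  d_axis <- sqrt(frame$q1^2 + frame$q3^2)
  jitter <- cosine_field(cbind(frame$q1, frame$q2, frame$q3))
  ft_from_score(frame, frac, exp(-d_axis / decay_scale) + 0.05 * jitter)
}

# Scattered FT: spherical clusters at uniformly random breast-frame
# positions, added until the target fraction is reached (the last
# cluster may overshoot by at most its own volume).
ft_sparse <- function(frame, frac, radius) {
  dm <- frame$dm; sp <- frame$sp; ax <- frame$halfaxes
  ft <- array(0L, dm)
  target <- round(frac * length(frame$idx))
  if (target == 0) return(ft)
  rr <- ceiling(radius / sp)            # bounding half-widths in voxels
  n_ft <- 0L
  for (iter in seq_len(200000L)) {
    if (n_ft >= target) break
    q <- c(stats::runif(1, -ax[1], ax[1]), stats::runif(1, 0, ax[2]),
           stats::runif(1, -ax[3], ax[3]))
    if (sum((q / ax)^2) > 1) next       # rejection-sample the half-ellipsoid
    w <- c(frame$centre[1] + q[1],
           frame$centre[2] + q[2] * frame$u[1] + q[3] * frame$v[1],
           frame$centre[3] + q[2] * frame$u[2] + q[3] * frame$v[2])
    cc <- round(w / sp) + 1
    lo <- pmax(cc - rr, 1); hi <- pmin(cc + rr, dm)
    if (any(lo > hi)) next
    i1 <- lo[1]:hi[1]; i2 <- lo[2]:hi[2]; i3 <- lo[3]:hi[3]
    dx <- (i1 - 1) * sp[1] - w[1]; dy <- (i2 - 1) * sp[2] - w[2]
    dz <- (i3 - 1) * sp[3] - w[3]
    d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    sub <- ft[i1, i2, i3, drop = FALSE]
    sub[d2 <= radius^2 & frame$breast[i1, i2, i3, drop = FALSE] > 0] <- 1L
    ft[i1, i2, i3] <- sub
    n_ft <- sum(ft)
  }
  if (n_ft < target)
    stop("ft_fraction ", frac, " unreachable for this geometry")
  ft
}

# FT exactly where the normalized elliptical radius of the breast
# cross-section lies within the bounds.
ft_annulus <- function(frame, bounds) {
  ax <- frame$halfaxes
  s <- sqrt(pmax(1 - (frame$q2 / ax[2])^2, 0))
  rho <- sqrt((frame$q1 / (ax[1] * s))^2 + (frame$q3 / (ax[3] * s))^2)
  ft <- array(0L, frame$dm)
  sel <- is.finite(rho) & rho >= bounds[1] & rho <= bounds[2]
  ft[frame$idx[sel]] <- 1L
  ft
}

#' Render a two-level intensity volume for a phantom
#'
#' Fills fat and fibroglandular voxels with fixed attenuation values
#' (roughly CT numbers) plus optional Gaussian noise, so the intensity
#' segmentation adapter can be exercised on phantoms. Voxels outside the
#' breast are set to an air-like value.
#'
#' @param vol a `labeled_volume` with breast and FT masks.
#' @param fat_hu,ft_hu intensity levels for fat and FT (defaults -100, 40).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed for the noise.
#' @return the volume with `intensities` populated.
#' @export
render_intensities <- function(vol, fat_hu = -100, ft_hu = 40,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(vol, "labeled_volume"), !is.null(vol$ft_mask))
  set.seed(seed)
  img <- array(-1000, dim(vol$breast_mask))
  img[vol$breast_mask > 0] <- fat_hu
  img[vol$ft_mask > 0] <- ft_hu
  if (noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  vol$intensities <- img
  vol
}

#' Generate a labelled phantom cohort
#'
#' Produces `n_nonsparse` phantoms in non-sparse mode and `n_sparse` in
#' sparse mode, each with random per-subject jitter of the breast
#' half-axes (±10 %), the FT fraction (±0.05, identically distributed in
#' both groups so that fibroglandular composition does not separate the
#' classes), the nipple offset (±20°), and the mode-specific pattern
#' parameter (±20 %). All randomness derives from `seed`: subject seeds
#' are drawn once up front, so the cohort is reproducible and each
#' subject's volume depends only on `seed` and its position.
#'
#' @param n_nonsparse,n_sparse group sizes (the study default is 15 and 8).
#' @param base_spec the `phantom_spec` jittered per subject; its `ft_mode`
#'   is overridden per group.
#' @param seed integer master seed.
#' @return a list with one element per subject: `id`, `group`
#'   (`"nonsparse"` or `"sparse"`), and `volume` (a `labeled_volume`).
#' @export
generate_cohort <- function(n_nonsparse = 15L, n_sparse = 8L,
                            base_spec = phantom_spec(), seed = 1L) {
  stopifnot(n_nonsparse >= 1L, n_sparse >= 1L,
            inherits(base_spec, "phantom_spec"))
  n <- n_nonsparse + n_sparse
  groups <- rep(c("nonsparse", "sparse"), c(n_nonsparse, n_sparse))
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  jit <- list(
    halfaxes = matrix(stats::runif(3 * n, 0.9, 1.1), nrow = n),
    frac     = stats::runif(n, -0.05, 0.05),
    angle    = stats::runif(n, -20, 20),
    scale    = stats::runif(n, 0.8, 1.2))

  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$breast_halfaxes_mm <- sp$breast_halfaxes_mm * jit$halfaxes[i, ]
    sp$ft_fraction <- min(max(sp$ft_fraction + jit$frac[i], 0.02), 0.98)
    sp$nipple_offset_deg <- sp$nipple_offset_deg + jit$angle[i]
    sp$ft_mode <- groups[i]
    if (groups[i] == "nonsparse") {
      sp$decay_scale <- sp$decay_scale * jit$scale[i]
    } else {
      sp$cluster_radius_mm <- sp$cluster_radius_mm * jit$scale[i]
    }
    sp$seed <- subject_seeds[i]
    list(id = sprintf("S%02d", i), group = groups[i],
         volume = generate_phantom(sp))
  })
}
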