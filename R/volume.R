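#' Labeled breast CT volume
#'
#' The shared in-memory container of the pipeline: a 3D grid carrying an
#' optional intensity volume, a whole-breast binary mask, an optional
#' fibroglandular-tissue (FT) binary mask, voxel spacing, and an optional
#' nipple landmark (voxel coordinate, 1-based).
#'
#' The canonical grid axis order is fixed throughout the package:
#' axis 1 runs superior to inferior, axis 2 anterior to posterior, and
#' axis 3 left to right. Axial planes are therefore `vol[i, , ]`
#' (fixed superior-inferior position) and coronal planes `vol[, j, ]`
#' (fixed anterior-posterior position); the chest wall lies at high
#' axis-2 index, the nipple at low axis-2 index.
#'
#' @param breast_mask 3D array (logical or 0/1) — whole-breast mask.
#' @param ft_mask optional 3D array — FT mask, a subset of the breast mask.
#' @param intensities optional 3D numeric array (e.g. HU values).
#' @param spacing numeric length-3, voxel spacing in mm along the three
#'   canonical axes; strictly positive.
#' @param nipple optional integer length-3, 1-based voxel coordinate of
#'   the nipple landmark.
#'
#' @return An object of class `labeled_volume`: a list with elements
#'   `breast_mask`, `ft_mask`, `intensities`, `spacing`, `nipple`.
#' @export
labeled_volume <- function(breast_mask, ft_mask = NULL, intensities = NULL,
                           spacing = c(1, 1, 1), nipple = NULL) {
  breast_mask <- as_mask_array(breast_mask, "breast_mask")
  dm <- dim(breast_mask)
  if (!is.null(ft_mask)) {
    ft_mask <- as_mask_array(ft_mask, "ft_mask")
    if (!identical(dim(ft_mask), dm))
      stop("ft_mask dimensions ", paste(dim(ft_mask), collapse = "x"),
           " do not match breast_mask dimensions ",
           paste(dm, collapse = "x"))
    if (any(ft_mask & !breast_mask))
      stop("ft_mask contains voxels outside the breast mask")
  }
  if (!is.null(intensities)) {
    intensities <- as.array(intensities)
    if (!identical(dim(intensities), dm))
      stop("intensity volume dimensions do not match breast_mask")
    storage.mode(intensities) <- "double"
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (!is.null(nipple)) {
    nipple <- as.integer(round(nipple))
    if (length(nipple) != 3L || any(nipple < 1L) || any(nipple > dm))
      stop("nipple landmark must be a 1-based voxel coordinate inside the grid")
  }
  structure(list(breast_mask = breast_mask, ft_mask = ft_mask,
                 intensities = intensities, spacing = spacing,
                 nipple = nipple),
            class = "labeled_volume")
}

# Coerce to a 0/1 integer array, binarizing at strictly > 0 so that
# 0/1/255 label encodings are all accepted.
as_mask_array <- function(x, what) {
  x <- as.array(x)
  if (length(dim(x)) != 3L)
    stop(what, " must be a 3D array")
  m <- array(0L, dim = dim(x))
  m[x > 0] <- 1L
  m
}

#' @export
print.labeled_volume <- function(x, ...) {
  dm <- dim(x$breast_mask)
  cat("<labeled_volume> ", paste(dm, collapse = " x "),
      " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm\n",
      sep = "")
  cat("  breast voxels: ", sum(x$breast_mask), sep = "")
  if (!is.null(x$ft_mask))
    cat("; FT voxels: ", sum(x$ft_mask),
        sprintf(" (FC = %.3f)", fibroglandular_composition(x)), sep = "")
  cat("\n")
  if (!is.null(x$nipple))
    cat("  nipple voxel: [", paste(x$nipple, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Fibroglandular composition of a volume
#'
#' FC is the fraction of breast voxels that are fibroglandular — a bulk
#' quantity, distinct from the spatial distribution of FT.
#'
#' @param vol a `labeled_volume` (or `oriented_breast`) with both masks.
#' @return numeric in \[0, 1\].
#' @export
fibroglandular_composition <- function(vol) {
  if (is.null(vol$ft_mask))
    stop("volume has no FT mask")
  nb <- sum(vol$breast_mask)
  if (nb == 0) stop("breast mask is empty")
  sum(vol$ft_mask) / nb
}

#' Reorder a volume's grid axes to the canonical anatomical order
#'
#' Maps arbitrary axis labelling onto the package's canonical order
#' (superior-inferior, anterior-posterior, left-right). `axes` names, for
#' each grid axis of the input, the anatomical direction of increasing
#' index: `"SI"` superior to inferior, `"IS"` its reverse, `"AP"`/`"PA"`,
#' `"LR"`/`"RL"`. Reversed axes are flipped. Applying the function to an
#' already-canonical volume is the identity, so the operation is a single
#' idempotent pass.
#'
#' @param vol a `labeled_volume`.
#' @param axes character length-3, one label per grid axis.
#' @return a `labeled_volume` in canonical axis order.
#' @export
canonicalize_axes <- function(vol, axes = c("SI", "AP", "LR")) {
  axes <- toupper(axes)
  valid <- c(SI = 1L, IS = 1L, AP = 2L, PA = 2L, LR = 3L, RL = 3L)
  if (length(axes) != 3L || !all(axes %in% names(valid)))
    stop("axes must be three of SI/IS, AP/PA, LR/RL; missing orientation ",
         "metadata must be supplied explicitly")
  target <- valid[axes]
  if (anyDuplicated(target))
    stop("axes must name three distinct anatomical directions")
  perm <- order(target)                  # input axis that becomes canonical k
  flip <- axes[perm] %in% c("IS", "PA", "RL")

  reorder1 <- function(a) {
    if (is.null(a)) return(NULL)
    a <- aperm(a, perm)
    idx <- lapply(seq_len(3L), function(k) {
      n <- dim(a)[k]
      if (flip[k]) rev(seq_len(n)) else seq_len(n)
    })
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  nip <- vol$nipple
  if (!is.null(nip)) {
    nip <- nip[perm]
    dm <- dim(vol$breast_mask)[perm]
    nip <- ifelse(flip, dm - nip + 1L, nip)
  }
  labeled_volume(reorder1(vol$breast_mask), reorder1(vol$ft_mask),
                 reorder1(vol$intensities), vol$spacing[perm], nip)
}
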