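#' Read a breast volume with its masks
#'
#' Reads NIfTI volumes, validates that every file shares the grid and
#' spacing of the breast mask, binarizes masks at strictly greater than
#' zero (so 0/1/255 label encodings all work), and maps the grid axes to
#' the package's canonical anatomical order via [canonicalize_axes()].
#' Spacing is taken from the NIfTI `pixdim`. An optional JSON sidecar
#' supplies the nipple landmark as `{"nipple_voxel": [i, j, k]}`
#' (1-based, in the file's axis order).
#'
#' @param breast_mask_path NIfTI file with the whole-breast mask.
#' @param ft_mask_path optional NIfTI file with the FT mask.
#' @param intensity_path optional NIfTI file with the intensity volume.
#' @param landmark_path optional JSON sidecar with the nipple voxel.
#' @param axes anatomical direction of increasing index for each file
#'   grid axis (see [canonicalize_axes()]).
#' @return a `labeled_volume` in canonical axis order.
#' @export
read_volume <- function(breast_mask_path, ft_mask_path = NULL,
                        intensity_path = NULL, landmark_path = NULL,
                        axes = c("SI", "AP", "LR")) {
  ref <- RNifti::readNifti(breast_mask_path)
  ref_dim <- dim(ref)
  ref_sp <- RNifti::pixdim(ref)
  if (length(ref_dim) != 3L)
    stop("expected a 3D volume in ", breast_mask_path)
  if (any(!is.finite(ref_sp)) || any(ref_sp <= 0))
    stop("missing or degenerate voxel spacing in ", breast_mask_path)

  read_matched <- function(path) {
    img <- RNifti::readNifti(path)
    if (!identical(dim(img), ref_dim))
      stop("dimensions of ", path, " (", paste(dim(img), collapse = "x"),
           ") do not match the breast mask (",
           paste(ref_dim, collapse = "x"), ")")
    if (max(abs(RNifti::pixdim(img) - ref_sp)) > 1e-4)
      stop("voxel spacing of ", path, " does not match the breast mask")
    array(as.numeric(img), ref_dim)
  }

  ft <- if (!is.null(ft_mask_path)) read_matched(ft_mask_path)
  img <- if (!is.null(intensity_path)) read_matched(intensity_path)
  nip <- NULL
  if (!is.null(landmark_path)) {
    side <- jsonlite::read_json(landmark_path, simplifyVector = TRUE)
    if (is.null(side$nipple_voxel) || length(side$nipple_voxel) != 3L)
      stop("landmark sidecar ", landmark_path,
           " must contain a 3-element nipple_voxel")
    nip <- as.integer(side$nipple_voxel)
  }
  vol <- labeled_volume(array(as.numeric(ref), ref_dim), ft, img,
                        spacing = ref_sp, nipple = nip)
  canonicalize_axes(vol, axes)
}

#' Write a labeled volume as NIfTI files plus a JSON sidecar
#'
#' Writes `<prefix>_breast.nii.gz`, and when present
#' `<prefix>_ft.nii.gz` and `<prefix>_intensity.nii.gz`, each with the
#' voxel spacing in the header, plus `<prefix>.json` carrying the nipple
#' landmark and any extra metadata (e.g. a group label).
#'
#' @param vol a `labeled_volume`.
#' @param prefix output path prefix.
#' @param metadata named list merged into the JSON sidecar.
#' @return invisibly, the named vector of files written.
#' @export
write_volume <- function(vol, prefix, metadata = list()) {
  stopifnot(inherits(vol, "labeled_volume"))
  write1 <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
    path
  }
  files <- c(breast = write1(vol$breast_mask,
                             paste0(prefix, "_breast.nii.gz")))
  if (!is.null(vol$ft_mask))
    files["ft"] <- write1(vol$ft_mask, paste0(prefix, "_ft.nii.gz"))
  if (!is.null(vol$intensities))
    files["intensity"] <- write1(vol$intensities,
                                 paste0(prefix, "_intensity.nii.gz"))
  side <- c(list(nipple_voxel = vol$nipple), metadata)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  files["sidecar"] <- paste0(prefix, ".json")
  invisible(files)
}

#' Write a cohort feature table as CSV
#'
#' Fixed column order: `subject`, `region`, `f1`..`f13`, `fc`, `label`;
#' full double precision so a re-read reproduces the values.
#'
#' @param table cohort feature table (see [cohort_features()]).
#' @param path output CSV path.
#' @export
write_features <- function(table, path) {
  check_cohort_table(table)
  cols <- c("subject", "region", paste0("f", 1:13), "fc", "label")
  utils::write.csv(format(table[, cols], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return the cohort feature table.
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (k in c(paste0("f", 1:13), "fc")) tab[[k]] <- as.numeric(tab[[k]])
  check_cohort_table(tab)
  tab
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
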