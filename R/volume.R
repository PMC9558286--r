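#' Volumetric image container
#'
#' A `Volume` is the package's universal image currency: a 3D scalar grid with
#' voxel spacing (mm), a 4x4 voxel-to-world affine, and an optional binary
#' brain mask on the same grid.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis (positive).
#' @param affine 4x4 voxel-to-world matrix (last row `c(0,0,0,1)`).
#' @param mask optional 3D array in `{0,1}` with the same dimensions as `data`.
#' @return An object of class `ms_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL, mask = NULL) {
  data <- as_array3(data, "data")
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing, 3)
  }
  v <- structure(list(data = data, spacing = as.numeric(spacing),
                      affine = affine, mask = mask), class = "ms_volume")
  validate_volume(v)
  v
}

as_array3 <- function(x, what) {
  x <- unclass(x)
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("expected 3D volume for '", what, "', got dims: ",
         paste(dim(x) %||% length(x), collapse = "x"))
  storage.mode(x) <- "double"
  x
}

validate_volume <- function(v) {
  stopifnot(inherits(v, "ms_volume"))
  if (length(dim(v$data)) != 3L) stop("expected 3D volume")
  if (length(v$spacing) != 3L || any(v$spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  if (!all(dim(v$affine) == c(4L, 4L)) ||
      !isTRUE(all.equal(v$affine[4, ], c(0, 0, 0, 1))))
    stop("affine must be 4x4 with last row (0,0,0,1)")
  if (!is.null(v$mask)) {
    if (!identical(dim(v$mask), dim(v$data)))
      stop("mask and data dimensions differ")
    if (!all(v$mask %in% c(0, 1))) stop("mask must be binary")
  }
  invisible(v)
}

#' @export
print.ms_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<Volume %dx%dx%d, spacing %s mm%s>\n", d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = "x"),
              if (!is.null(x$mask)) sprintf(", mask %d vox", sum(x$mask)) else ""))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.ms_volume <- function(x) dim(x$data)

#' Read a NIfTI-1 volume
#'
#' Volumes are reoriented to the closest-to-RAS axis order on load so all
#' voxel-space operations share one convention. Masks are stored in separate
#' files (suffix `_mask`) and are not attached by the reader.
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3D volume, got ", length(dim(img)), "D in ", path)
  RNifti::orientation(img) <- "RAS"
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr)) # drop RNifti pointer attributes
  volume(arr,
         spacing = RNifti::pixdim(img)[1:3],
         affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Write a volume as NIfTI-1
#'
#' The file carries the volume's affine and spacing; the mask, when present,
#' is not serialized with the intensity file (write it separately).
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  validate_volume(vol)
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  mat <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- mat
  RNifti::qform(img) <- mat
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Longitudinal case container
#'
#' Bundles baseline and follow-up volumes per modality plus the optional
#' new-lesion ground-truth mask (a binary volume in follow-up space).
#'
#' @param case_id character identifier.
#' @param baseline,followup named lists of [volume()]s; names from
#'   `FLAIR`, `T1`, `T1S`.
#' @param new_lesion_mask optional binary [volume()] on the follow-up grid.
#' @return An object of class `ms_case`.
#' @export
longitudinal_case <- function(case_id, baseline, followup, new_lesion_mask = NULL) {
  ok <- c("FLAIR", "T1", "T1S")
  if (!all(names(baseline) %in% ok) || !all(names(followup) %in% ok))
    stop("modality names must be drawn from {FLAIR, T1, T1S}")
  if (!is.null(new_lesion_mask)) {
    ref <- followup[[1]]
    if (!identical(dim(new_lesion_mask$data), dim(ref$data)))
      stop("new_lesion_mask must share the follow-up grid")
  }
  structure(list(case_id = case_id, baseline = baseline, followup = followup,
                 new_lesion_mask = new_lesion_mask), class = "ms_case")
}

#' @export
print.ms_case <- function(x, ...) {
  nles <- if (is.null(x$new_lesion_mask)) NA_integer_ else {
    lab <- cpp_label_components(x$new_lesion_mask$data, 26L)
    attr(lab, "n_components")
  }
  cat(sprintf("<LongitudinalCase %s: baseline {%s}, follow-up {%s}, new lesions: %s>\n",
              x$case_id, paste(names(x$baseline), collapse = ","),
              paste(names(x$followup), collapse = ","),
              ifelse(is.na(nles), "unknown", nles)))
  invisible(x)
}
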