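#' CT volume in Hounsfield units
#'
#' A `ct_volume` wraps a 3D array of HU values together with its physical
#' voxel spacing and origin. Arrays are indexed `[i, j, k]` along the first
#' three axes of the NIfTI affine (x, y, z); this convention is fixed and
#' used by every function in the package.
#'
#' @param data 3D numeric array of HU values; must be finite.
#' @param spacing Numeric length-3 voxel spacing `(sx, sy, sz)` in mm,
#'   strictly positive.
#' @param origin Physical coordinate (mm) of voxel `(1, 1, 1)`.
#'
#' @details HU values outside the plausible CT range `[-1100, 3100]` trigger
#'   a warning but are kept: phantom and clinical exports clip differently.
#'
#' @return An object of class `ct_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
#' @examples
#' vol <- ct_volume(array(0, c(16, 16, 16)), spacing = c(1, 1, 1.5))
#' dim(vol$data)
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) {
    abort_cs("`data` must be a 3D array", "dimensionality_error")
  }
  if (!all(is.finite(data))) {
    abort_validation("CT data contains non-finite values (NaN/Inf)")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort_validation("`spacing` must be 3 strictly positive values (mm)")
  }
  rng <- range(data)
  if (rng[1] < -1100 || rng[2] > 3100) {
    warning("HU values outside the plausible CT range [-1100, 3100]",
            call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

#' Default structure legend for label masks
#'
#' @return Named integer vector mapping structure names to label values:
#'   background = 0, liver = 1, tumor = 2, cyst = 3.
#' @export
default_legend <- function() {
  c(background = 0L, liver = 1L, tumor = 2L, cyst = 3L)
}

#' Integer label mask aligned to a CT volume
#'
#' @param data 3D array of small non-negative integers (values within 1e-6
#'   of an integer are accepted and cast).
#' @param spacing,origin As in [ct_volume()].
#' @param legend Named integer vector mapping structure names to label
#'   values; every value present in `data` must appear in the legend.
#'
#' @return An object of class `label_mask` with fields `data` (integer
#'   array), `spacing`, `origin`, `legend`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       legend = default_legend()) {
  if (length(dim(data)) != 3L) {
    abort_cs("`data` must be a 3D array", "dimensionality_error")
  }
  if (is.double(data)) {
    rounded <- round(data)
    if (max(abs(data - rounded)) > 1e-6) {
      abort_cs("mask voxel values are not integral (tolerance 1e-6)",
               "format_error")
    }
    data <- array(as.integer(rounded), dim(data))
  }
  storage.mode(data) <- "integer"
  present <- unique(as.vector(data))
  bad <- setdiff(present, as.integer(legend))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "mask contains labels not in the legend: %s",
      paste(bad, collapse = ", ")
    ))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort_validation("`spacing` must be 3 strictly positive values (mm)")
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         legend = legend),
    class = "label_mask"
  )
}

nifti_geometry <- function(img) {
  pd <- RNifti::pixdim(img)[1:3]
  orig <- tryCatch(
    as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img)),
    error = function(e) c(0, 0, 0)
  )
  list(spacing = abs(pd), origin = orig)
}

#' Read a CT volume from a NIfTI file
#'
#' Spacing is taken from the header `pixdim`; integer-stored HU are rescaled
#' through the header slope/intercept where present (handled by RNifti).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    abort_cs(sprintf("expected a 3D image, got %dD", length(dim(img))),
             "dimensionality_error")
  }
  geo <- nifti_geometry(img)
  dat <- array(as.numeric(img), dim(img))
  ct_volume(dat, spacing = geo$spacing, origin = geo$origin)
}

#' Read a label mask from a NIfTI file
#'
#' @inheritParams read_ct_volume
#' @param legend Structure legend, as in [label_mask()].
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, legend = default_legend()) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    abort_cs(sprintf("expected a 3D image, got %dD", length(dim(img))),
             "dimensionality_error")
  }
  geo <- nifti_geometry(img)
  dat <- array(as.numeric(img), dim(img))
  label_mask(dat, spacing = geo$spacing, origin = geo$origin, legend = legend)
}

#' Write a CT volume or label mask to NIfTI
#'
#' HU volumes are stored as float32, masks as int16; spacing goes into the
#' header `pixdim`.
#'
#' @param x A [ct_volume()] or [label_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    dtype <- "float"
  } else if (inherits(x, "label_mask")) {
    dtype <- "int16"
  } else {
    abort_argument("`x` must be a ct_volume or label_mask")
  }
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Check that a CT volume and a mask share a voxel grid
#'
#' Passes silently when shapes are equal and spacing agrees within 1e-4 mm;
#' otherwise raises a geometry error. All cross-volume operations in the
#' package call this before indexing.
#'
#' @param ct A [ct_volume()] (or `label_mask`).
#' @param mask A [label_mask()] (or `ct_volume`).
#' @param tol Spacing tolerance in mm.
#' @return Invisibly `TRUE` on success.
#' @export
check_aligned <- function(ct, mask, tol = 1e-4) {
  if (!identical(dim(ct$data), dim(mask$data))) {
    abort_geometry(sprintf(
      "shape mismatch: (%s) vs (%s)",
      paste(dim(ct$data), collapse = ","), paste(dim(mask$data), collapse = ",")
    ))
  }
  if (any(abs(ct$spacing - mask$spacing) > tol)) {
    abort_geometry(sprintf(
      "spacing mismatch beyond %g mm: (%s) vs (%s)", tol,
      paste(ct$spacing, collapse = ","), paste(mask$spacing, collapse = ",")
    ))
  }
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = "x"),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$data, levels = x$legend,
                      labels = names(x$legend)))
  cat(sprintf(
    "<label_mask> %s voxels, spacing %s mm\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = "x")
  ))
  print(tab)
  invisible(x)
}
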