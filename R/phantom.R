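#' HU presets for phantom lesions
#'
#' Per-lesion Gaussian HU parameters used by default when a [lesion_spec()]
#' does not override them: mean 91, sd 23 HU for tumors and mean 17, sd 22
#' HU for cysts. These match fitted per-case values reported for clinical
#' liver CT and put the two lesion classes on either side of the 45 HU
#' decision cutoff.
#'
#' @return Named list with elements `tumor` and `cyst`, each
#'   `c(hu_mean, hu_sd)`.
#' @export
#' @examples
#' lesion_presets()$cyst
lesion_presets <- function() {
  list(tumor = c(hu_mean = 91, hu_sd = 23),
       cyst  = c(hu_mean = 17, hu_sd = 22))
}

#' Specify a spherical phantom lesion
#'
#' @param center Voxel coordinates (length 3) of the sphere center.
#' @param radius Sphere radius in mm, > 0.
#' @param kind `"tumor"` or `"cyst"`; selects the default HU preset.
#' @param hu_mean,hu_sd Optional overrides of the preset Gaussian HU
#'   parameters (mm and HU).
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, radius, kind = c("tumor", "cyst"),
                        hu_mean = NULL, hu_sd = NULL) {
  kind <- match.arg(kind)
  if (radius <= 0) abort_validation("lesion `radius` must be > 0 mm")
  preset <- lesion_presets()[[kind]]
  hu_mean <- hu_mean %||% unname(preset["hu_mean"])
  hu_sd <- hu_sd %||% unname(preset["hu_sd"])
  if (hu_sd < 0) abort_validation("lesion `hu_sd` must be >= 0")
  structure(
    list(center = as.numeric(center), radius = radius, kind = kind,
         hu_mean = hu_mean, hu_sd = hu_sd),
    class = "lesion_spec"
  )
}

#' Specify a synthetic CT phantom
#'
#' The phantom is an ellipsoidal "liver" of noisy parenchyma inside a uniform
#' background, carrying spherical tumor and cyst lesions whose HU values are
#' drawn i.i.d. per voxel from per-lesion Gaussians. It provides ground truth
#' for validating intensity-based post-processing; it makes no attempt at CT
#' physics (no partial volume, beam hardening or contrast phases).
#'
#' @param shape Voxel dimensions, each >= 16.
#' @param spacing Voxel spacing in mm; default `c(1, 1, 1.5)` mirrors 1.5 mm
#'   reconstruction slices with ~1 mm in-plane resolution.
#' @param liver List with `center` (voxel coords), `semi_axes` (mm),
#'   `hu_mean`, `hu_sd`. Parenchyma defaults to 60 +/- 10 HU, separable from
#'   both lesion presets.
#' @param background_hu Uniform HU outside the liver (default -1000, air).
#' @param lesions List of [lesion_spec()]s; pairwise non-overlapping, each
#'   sphere inside the liver ellipsoid.
#' @param noise_sd Additive Gaussian noise (HU) applied outside lesions only,
#'   so lesion HU variance is governed solely by the lesion parameters.
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 44),
                         spacing = c(1, 1, 1.5),
                         liver = list(center = NULL, semi_axes = c(26, 24, 26),
                                      hu_mean = 60, hu_sd = 10),
                         background_hu = -1000,
                         lesions = list(),
                         noise_sd = 5,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    abort_validation("`shape` must be 3 dimensions, each >= 16")
  }
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) abort_validation("`spacing` must be positive")
  liver$center <- liver$center %||% (shape + 1) / 2
  liver$semi_axes <- liver$semi_axes %||% c(26, 24, 26)
  liver$hu_mean <- liver$hu_mean %||% 60
  liver$hu_sd <- liver$hu_sd %||% 10
  if (any(liver$semi_axes <= 0)) abort_validation("liver semi-axes must be > 0")
  if (noise_sd < 0) abort_validation("`noise_sd` must be >= 0")

  spec <- structure(
    list(shape = shape, spacing = spacing, liver = liver,
         background_hu = background_hu, lesions = lesions,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_lesions(spec)
  spec
}

validate_lesions <- function(spec) {
  les <- spec$lesions
  if (length(les) == 0) return(invisible(TRUE))
  mm_center <- function(v) (v - 1) * spec$spacing
  lc <- mm_center(spec$liver$center)
  for (i in seq_along(les)) {
    l <- les[[i]]
    c_mm <- mm_center(l$center)
    # sphere fits inside the ellipsoid shrunk by the radius (conservative)
    shrunk <- spec$liver$semi_axes - l$radius
    if (any(shrunk <= 0) ||
        sum(((c_mm - lc) / shrunk)^2) > 1) {
      abort_validation(sprintf(
        "lesion %d (radius %.1f mm) does not fit inside the liver ellipsoid",
        i, l$radius
      ))
    }
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        d <- sqrt(sum((c_mm - mm_center(les[[j]]$center))^2))
        if (d <= l$radius + les[[j]]$radius) {
          abort_validation(sprintf("lesions %d and %d overlap", j, i))
        }
      }
    }
  }
  invisible(TRUE)
}

#' Build a synthetic CT phantom with ground-truth labels
#'
#' Voxel membership is decided by the physical (mm) distance from the voxel
#' center, so anisotropic spacing is handled correctly. Sampling order is
#' fixed (parenchyma, then lesions in list order, then background noise), so
#' the same spec and seed reproduce the phantom bit for bit.
#'
#' @param spec A [phantom_spec()].
#' @return List with `ct` (a [ct_volume()]) and `truth` (a [label_mask()]
#'   with liver = 1, tumor = 2, cyst = 3).
#' @export
#' @examples
#' spec <- phantom_spec(lesions = list(
#'   lesion_spec(c(26, 32, 22), radius = 8, kind = "tumor"),
#'   lesion_spec(c(44, 32, 22), radius = 6, kind = "cyst")
#' ))
#' ph <- build_phantom(spec)
#' table(ph$truth$data)
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_lesions(spec)
  d <- spec$shape
  sp <- spec$spacing
  # physical coordinates of voxel centers, origin at voxel (1,1,1)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  lc <- (spec$liver$center - 1) * sp
  ax <- spec$liver$semi_axes
  ex <- ((xs - lc[1]) / ax[1])^2
  ey <- ((ys - lc[2]) / ax[2])^2
  ez <- ((zs - lc[3]) / ax[3])^2
  liver_in <- outer(outer(ex, ey, `+`), ez, `+`) <= 1

  hu <- array(spec$background_hu, d)
  labels <- array(0L, d)
  labels[liver_in] <- 1L

  withr::with_seed(spec$seed, {
    n_liver <- sum(liver_in)
    hu[liver_in] <- stats::rnorm(n_liver, spec$liver$hu_mean,
                                 spec$liver$hu_sd)
    lesion_any <- array(FALSE, d)
    for (l in spec$lesions) {
      cm <- (l$center - 1) * sp
      dx2 <- (xs - cm[1])^2
      dy2 <- (ys - cm[2])^2
      dz2 <- (zs - cm[3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= l$radius^2
      labels[inside] <- if (l$kind == "tumor") 2L else 3L
      hu[inside] <- stats::rnorm(sum(inside), l$hu_mean, l$hu_sd)
      lesion_any <- lesion_any | inside
    }
    if (spec$noise_sd > 0) {
      outside <- !lesion_any
      hu[outside] <- hu[outside] +
        stats::rnorm(sum(outside), 0, spec$noise_sd)
    }
  })

  list(
    ct = ct_volume(hu, spacing = sp),
    truth = label_mask(labels, spacing = sp)
  )
}

#' Simulate a network prediction that confuses cysts with tumors
#'
#' Emulates the characteristic failure of intensity-driven segmentation
#' models on clinical liver CT: cyst voxels are absorbed into the predicted
#' tumor mask. The output mask contains only background and the tumor label.
#'
#' @param truth Ground-truth [label_mask()] with tumor and cyst labels in
#'   its legend.
#' @param mode `"merge_cysts"` merges truth cysts into the tumor label;
#'   `"merge_plus_jitter"` additionally dilates or erodes each merged
#'   component independently by a random physical radius up to
#'   `jitter_radius`.
#' @param jitter_radius Maximum boundary perturbation in mm.
#' @param seed Seed for the jitter draws.
#' @return A [label_mask()] with values in `{0, tumor}`.
#' @export
simulate_prediction <- function(truth,
                                mode = c("merge_cysts", "merge_plus_jitter"),
                                jitter_radius = 0, seed = 1L) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) abort_argument(
                     "`mode` must be 'merge_cysts' or 'merge_plus_jitter'"))
  legend <- truth$legend
  if (!all(c("tumor", "cyst") %in% names(legend))) {
    abort_validation("truth legend must contain 'tumor' and 'cyst' labels")
  }
  tumor_lab <- legend[["tumor"]]
  cyst_lab <- legend[["cyst"]]
  pred <- array(0L, dim(truth$data))
  pred[truth$data == tumor_lab | truth$data == cyst_lab] <- tumor_lab

  if (mode == "merge_plus_jitter" && jitter_radius > 0) {
    pm <- label_mask(pred, spacing = truth$spacing, origin = truth$origin,
                     legend = legend)
    regions <- connected_components(pm, label = tumor_lab)
    out <- array(0L, dim(pred))
    withr::with_seed(seed, {
      for (reg in regions) {
        r <- stats::runif(1, 0, jitter_radius)
        grow <- stats::runif(1) < 0.5
        bin <- array(FALSE, dim(pred))
        bin[voxel_to_linear(reg$voxel_indices, dim(pred))] <- TRUE
        adj <- morph_binary(bin, if (grow) r else -r, truth$spacing)
        out[adj] <- tumor_lab
      }
    })
    pred <- out
  }
  label_mask(pred, spacing = truth$spacing, origin = truth$origin,
             legend = legend)
}

# Binary dilation (radius > 0) or erosion (radius < 0) by a physical ball.
morph_binary <- function(bin, radius_mm, spacing) {
  if (radius_mm == 0) return(bin)
  offs <- ball_offsets(radius_mm, spacing)
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (nrow(offs) == 0) return(bin)
  if (radius_mm > 0) {
    out <- bin
    for (i in seq_len(nrow(offs))) out <- out | shift_logical(bin, offs[i, ])
  } else {
    out <- bin
    for (i in seq_len(nrow(offs))) out <- out & shift_logical(bin, offs[i, ])
  }
  out
}
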