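# Shared fixtures: small masks built in code and seeded random phantom
# layouts used by the filter and acceptance tests.

mask_from_array <- function(arr, spacing = c(1, 1, 1),
                            legend = default_legend()) {
  label_mask(arr, spacing = spacing, legend = legend)
}

# A solid axis-aligned box of `label` in an otherwise empty volume.
box_mask <- function(dims, from, to, label = 2L, spacing = c(1, 1, 1)) {
  arr <- array(0L, dims)
  arr[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- as.integer(label)
  mask_from_array(arr, spacing = spacing)
}

# Random phantom layout: n_tumor tumors and n_cyst cysts at seeded random
# non-overlapping positions inside the default liver ellipsoid, default HU
# presets. Rejection sampling; deterministic given `seed`.
random_phantom_spec <- function(seed, n_tumor = 2, n_cyst = 2,
                                shape = c(64, 64, 44),
                                spacing = c(1, 1, 1.5)) {
  withr::with_seed(seed, {
    liver_center <- (shape + 1) / 2
    semi <- c(26, 24, 26)
    radii <- c(runif(n_tumor, 5.5, 8), runif(n_cyst, 4.5, 6.5))
    kinds <- c(rep("tumor", n_tumor), rep("cyst", n_cyst))
    placed <- list()
    for (i in seq_along(radii)) {
      for (try in 1:200) {
        u <- runif(3, -1, 1)
        cand_mm <- (liver_center - 1) * spacing + u * (semi - radii[i] - 1)
        inside <- sum((cand_mm - (liver_center - 1) * spacing)^2 /
                        (semi - radii[i])^2) <= 1
        clear <- TRUE
        # 4 mm clearance: closer surfaces can fuse into one 26-connected
        # region after voxelization (voxel diagonal ~2.06 mm at 1.5 mm
        # slices), and the screen models one lesion per region
        for (p in placed) {
          d <- sqrt(sum((cand_mm - p$mm)^2))
          if (d <= radii[i] + p$radius + 4) clear <- FALSE
        }
        if (inside && clear) {
          placed[[length(placed) + 1]] <- list(
            mm = cand_mm, radius = radii[i], kind = kinds[i]
          )
          break
        }
      }
    }
    stopifnot(length(placed) == length(radii))
    lesions <- lapply(placed, function(p) {
      lesion_spec(center = p$mm / spacing + 1, radius = p$radius,
                  kind = p$kind)
    })
    phantom_spec(shape = shape, spacing = spacing, lesions = lesions,
                 seed = seed)
  })
}
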