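test_that("the 45 HU rule is strict-below", {
  expect_equal(classify_region(17), "cyst")
  expect_equal(classify_region(91), "tumor")
  expect_equal(classify_region(45), "tumor")
  expect_equal(classify_region(44.999), "cyst")
  expect_error(classify_region(NaN), class = "cystscreen_argument_error")
})

test_that("filter removes exactly the cyst regions of merged predictions", {
  for (seed in 41:45) {
    spec <- random_phantom_spec(seed, n_tumor = 2, n_cyst = 2)
    ph <- build_phantom(spec)
    pred <- simulate_prediction(ph$truth, "merge_cysts")
    res <- filter_mask(ph$ct, pred)

    expect_equal(attr(res$report, "n_removed"), 2L)
    expect_equal(attr(res$report, "n_kept"), 2L)
    # verdicts agree with the generator's ground-truth kinds per voxel
    for (i in seq_len(nrow(res$report))) {
      reg <- connected_components(pred, 2)[[i]]
      truth_labels <- ph$truth$data[
        cbind(reg$voxel_indices[, 1], reg$voxel_indices[, 2],
              reg$voxel_indices[, 3])
      ]
      true_kind <- if (any(truth_labels == 3L)) "cyst" else "tumor"
      expect_equal(res$report$verdict[i], true_kind)
    }
    # removed cyst voxels are relabeled, not erased, by default
    expect_true(all(res$mask$data[pred$data == 2L] %in% c(2L, 3L)))
  }
})

test_that("a prediction without cysts passes through unchanged", {
  spec <- random_phantom_spec(51, n_tumor = 2, n_cyst = 0)
  ph <- build_phantom(spec)
  pred <- simulate_prediction(ph$truth, "merge_cysts")
  res <- filter_mask(ph$ct, pred)
  expect_identical(res$mask$data, pred$data)
  expect_equal(attr(res$report, "n_removed"), 0L)
})

test_that("tiny regions fall back to the empirical mean", {
  arr_ct <- array(60, c(16, 16, 16))
  arr_m <- array(0L, c(16, 16, 16))
  arr_m[3:4, 3:4, 3:4] <- 2L # 8 voxels < min_fit_samples
  arr_ct[3:4, 3:4, 3:4] <- 10
  res <- filter_mask(ct_volume(arr_ct), mask_from_array(arr_m))
  expect_equal(nrow(res$report), 1L)
  expect_true(res$report$fallback[1])
  expect_equal(res$report$verdict[1], "cyst")
  expect_equal(res$report$decided_mean[1], 10.5) # bin center of [10, 11)
  expect_false(any(res$mask$data == 2L))
})

test_that("filtering is monotone, idempotent and erase mode works", {
  spec <- random_phantom_spec(61)
  ph <- build_phantom(spec)
  pred <- simulate_prediction(ph$truth, "merge_plus_jitter",
                              jitter_radius = 1.5, seed = 2L)
  res <- filter_mask(ph$ct, pred)
  # never adds voxels
  expect_true(all(res$mask$data[pred$data != 2L] != 2L))
  # the report accounts exactly for the removed voxels
  expect_equal(sum(pred$data == 2L) - sum(res$mask$data == 2L),
               attr(res$report, "voxels_removed"))
  # idempotence
  res2 <- filter_mask(ph$ct, res$mask)
  expect_identical(res2$mask$data, res$mask$data)
  expect_equal(attr(res2$report, "n_removed"), 0L)

  erased <- filter_mask(ph$ct, pred,
                        config = filter_config(erase_cysts = TRUE))
  expect_false(any(erased$mask$data == 3L))
})

test_that("threshold extremes remove all or no regions", {
  spec <- random_phantom_spec(71)
  ph <- build_phantom(spec)
  pred <- simulate_prediction(ph$truth, "merge_cysts")
  all_gone <- filter_mask(ph$ct, pred,
                          config = filter_config(threshold = 120))
  expect_equal(attr(all_gone$report, "n_kept"), 0L)
  none_gone <- filter_mask(ph$ct, pred,
                           config = filter_config(threshold = -50))
  expect_equal(attr(none_gone$report, "n_removed"), 0L)
})

test_that("empty predictions yield an identity output and empty report", {
  ct <- ct_volume(array(0, c(16, 16, 16)))
  empty <- mask_from_array(array(0L, c(16, 16, 16)))
  res <- filter_mask(ct, empty)
  expect_identical(res$mask$data, empty$data)
  expect_equal(nrow(res$report), 0L)
})

test_that("morphology adjustment behaves like ball dilation/erosion", {
  spec <- phantom_spec(
    shape = c(40, 40, 40), spacing = c(1, 1, 1),
    liver = list(semi_axes = c(17, 17, 17)),
    lesions = list(lesion_spec(c(20.5, 20.5, 20.5), 8, "tumor")),
    seed = 2L
  )
  ph <- build_phantom(spec)

  expect_identical(morphology_adjust(ph$truth, 2L, 0)$data, ph$truth$data)

  # opening (erode then dilate) recovers a large sphere within a 1-voxel shell
  er <- morphology_adjust(ph$truth, 2L, -2)
  op <- morphology_adjust(er, 2L, 2)
  diff_vox <- which(xor(op$data == 2L, ph$truth$data == 2L))
  if (length(diff_vox) > 0) {
    # every differing voxel must touch the original sphere surface
    d2 <- cystscreen:::edt_squared(
      cystscreen:::surface_voxels(ph$truth$data == 2L), c(1, 1, 1)
    )
    expect_lte(max(sqrt(d2[diff_vox])), sqrt(3) + 1e-9)
  }

  # dilation agrees exactly with a brute-force nearest-source oracle
  axs <- (1:22 - 11.5)^2
  d2s <- outer(outer(axs, axs, `+`), axs, `+`)
  small <- mask_from_array(array(2L * (d2s <= 25), c(22, 22, 22)))
  dis <- morphology_adjust(small, 2L, 2)
  src <- which(small$data == 2L, arr.ind = TRUE)
  all_vox <- which(array(TRUE, c(22, 22, 22)), arr.ind = TRUE)
  mind <- apply(all_vox, 1, function(v) {
    sqrt(min((src[, 1] - v[1])^2 + (src[, 2] - v[2])^2 +
               (src[, 3] - v[3])^2))
  })
  expect_identical(dis$data == 2L,
                   array(mind <= 2 + 1e-9, c(22, 22, 22)))

  # dilating a free-standing 8 mm sphere by 2 mm approximates a 10 mm
  # sphere volume; the discrete 2 mm ball reaches at most sqrt(3) mm along
  # diagonals, so the exact operation undershoots the continuum volume by
  # several percent
  ax <- (1:32 - 16.5)^2
  dist2 <- outer(outer(ax, ax, `+`), ax, `+`)
  sphere <- mask_from_array(array(2L * (dist2 <= 64), c(32, 32, 32)))
  di <- morphology_adjust(sphere, 2L, 2)
  n <- sum(di$data == 2L)
  expect_lt(abs(n - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.10)

  # dilation never overwrites other foreground structures
  blocked <- sphere$data
  blocked[26:32, , ] <- 1L
  blocked <- mask_from_array(blocked)
  dib <- morphology_adjust(blocked, 2L, 2)
  expect_true(all(dib$data[blocked$data == 1L] == 1L))
  expect_error(morphology_adjust(sphere, 2L, 100),
               class = "cystscreen_argument_error")
})
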