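# one-hot target array with class channel last
one_hot <- function(labels, n_classes) {
  d <- dim(labels)
  y <- array(0, c(d, n_classes))
  m <- matrix(y, ncol = n_classes)
  m[cbind(seq_along(labels), as.vector(labels) + 1L)] <- 1
  array(m, c(d, n_classes))
}

test_that("dice loss matches closed forms", {
  withr::with_seed(1, labs <- array(sample(0:2, 64, TRUE), c(4, 4, 4)))
  y <- one_hot(labs, 3)
  expect_lt(dice_loss(y, y), 1e-4)

  # total miss on a 2-class toy
  y2 <- one_hot(array(rep(0:1, each = 4), c(2, 2, 2)), 2)
  expect_equal(dice_loss(y2, 1 - y2), 1, tolerance = 1e-4)

  # C = 2, channel sums (10, 90), p = 0.5 everywhere on 100 voxels:
  # dice_c = 2*(0.5*n_c)/(n_c + 50); loss = 1 - (1/6 + 9/14)/2 = 25/42
  labs3 <- array(as.integer(seq_len(100) <= 10), c(10, 10, 1))
  y3 <- one_hot(labs3, 2) # channel sums (90, 10)
  p3 <- array(0.5, dim(y3))
  expect_equal(dice_loss(y3, p3), 25 / 42, tolerance = 1e-4)

  expect_error(dice_loss(y2, array(0.5, c(2, 2, 2, 3))),
               class = "cystscreen_argument_error")
})

test_that("cross-entropy matches analytic values", {
  labs <- array(sample(0:2, 27, TRUE), c(3, 3, 3))
  y <- one_hot(labs, 3)
  expect_lt(cross_entropy_loss(y, y), 1e-5)

  # uniform softmax over C = 3 costs ln 3 per voxel
  p_unif <- array(1 / 3, dim(y))
  expect_equal(cross_entropy_loss(y, p_unif), log(3), tolerance = 1e-9)

  # hand-computed 2-voxel case: true-class probabilities 0.8 and 0.5
  y2 <- one_hot(array(c(0L, 1L), c(2, 1, 1)), 2)
  p2 <- array(c(0.8, 0.5, 0.2, 0.5), c(2, 1, 1, 2))
  expect_equal(cross_entropy_loss(y2, p2), -(log(0.8) + log(0.5)) / 2)
})

test_that("sigmoid mode scores channels as independent binaries", {
  y <- array(c(1, 1, 1, 0), c(1, 1, 2, 2)) # overlapping liver/tumor targets
  p <- y * 0.9 + (1 - y) * 0.1
  bce <- cross_entropy_loss(y, p, activation = "sigmoid")
  expect_equal(bce, -log(0.9), tolerance = 1e-12)
})

test_that("scale loss composes its two terms", {
  withr::with_seed(2, {
    labs <- array(sample(0:2, 27, TRUE), c(3, 3, 3))
    y <- one_hot(labs, 3)
    p <- activate(array(rnorm(27 * 3), c(3, 3, 3, 3)), "softmax")
  })
  expect_equal(scale_loss(y, p),
               0.5 * cross_entropy_loss(y, p) + 0.5 * dice_loss(y, p))
  cfg_ce <- loss_config(term_weights = c(ce = 1, dice = 0))
  expect_equal(scale_loss(y, p, cfg_ce), cross_entropy_loss(y, p, cfg_ce))
  expect_lt(scale_loss(y, y * (1 - 2e-7) + 1e-7), 1e-5)
})

test_that("total loss weights the scale pyramid", {
  withr::with_seed(3, {
    labs1 <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
    labs2 <- array(sample(0:1, 8, TRUE), c(2, 2, 2))
    y1 <- one_hot(labs1, 2); y2 <- one_hot(labs2, 2)
    p1 <- activate(array(rnorm(128), c(4, 4, 4, 2)), "softmax")
    p2 <- activate(array(rnorm(16), c(2, 2, 2, 2)), "softmax")
  })
  cfg1 <- loss_config(n_classes = 2, n_scales = 1)
  expect_equal(total_loss(list(y1), list(p1), cfg1), scale_loss(y1, p1, cfg1))

  cfg2 <- loss_config(n_classes = 2, n_scales = 2)
  expect_equal(
    total_loss(list(y1, y2), list(p1, p2), cfg2),
    0.5 * scale_loss(y1, p1, cfg2) + 0.5 * scale_loss(y2, p2, cfg2)
  )

  # K = 4 perfect pyramid is (clip-limited) zero; every class is present
  # at every scale (the denominator-only epsilon leaves the empty-class
  # dice at 0 by design, so an absent class would contribute loss)
  cfg4 <- loss_config(n_classes = 2, n_scales = 4)
  ys <- list(y1, y2, one_hot(array(c(0L, 1L, 1L, 0L), c(2, 2, 1)), 2),
             one_hot(array(c(0L, 1L), c(2, 1, 1)), 2))
  ps <- lapply(ys, function(y) y * (1 - 2e-7) + 1e-7)
  expect_lt(total_loss(ys, ps, cfg4), 1e-5)

  expect_error(total_loss(list(y1), list(p1), cfg2),
               class = "cystscreen_argument_error")
  expect_error(total_loss(list(y2, y1), list(p2, p1), cfg2),
               class = "cystscreen_argument_error")
})

test_that("activation contract distinguishes softmax from sigmoid", {
  z <- array(0, c(2, 2, 1, 3))
  expect_equal(unique(as.vector(activate(z, "softmax"))), 1 / 3)
  expect_equal(unique(as.vector(activate(z, "sigmoid"))), 0.5)
  # sigmoid permits overlapping structures: both channels can exceed 0.5
  z2 <- array(2, c(1, 1, 1, 2))
  p2 <- activate(z2, "sigmoid")
  expect_true(all(p2 > 0.8))
  expect_error(activate(array(Inf, c(1, 1, 1, 2))),
               class = "cystscreen_argument_error")
})

test_that("losses are non-negative and channel-permutation symmetric", {
  withr::with_seed(5, {
    labs <- array(sample(0:2, 27, TRUE), c(3, 3, 3))
    y <- one_hot(labs, 3)
    p <- activate(array(rnorm(81), c(3, 3, 3, 3)), "softmax")
  })
  expect_gte(dice_loss(y, p), 0)
  expect_gte(cross_entropy_loss(y, p), 0)
  expect_lte(dice_loss(y, p), 1 + 1e-6)

  perm <- c(3, 1, 2)
  expect_equal(dice_loss(y[, , , perm], p[, , , perm]), dice_loss(y, p))
  expect_equal(cross_entropy_loss(y[, , , perm], p[, , , perm]),
               cross_entropy_loss(y, p))
})

test_that("analytic gradient matches central finite differences", {
  for (act in c("softmax", "sigmoid")) {
    withr::with_seed(6, {
      labs <- array(sample(0:1, 27, TRUE), c(3, 3, 3))
      y <- one_hot(labs, 2)
      p <- array(runif(54, 0.2, 0.8), c(3, 3, 3, 2))
    })
    cfg <- loss_config(n_classes = 2)
    g <- scale_loss_grad(y, p, cfg, activation = act)
    h <- 1e-5
    idx <- cbind(c(1, 2, 3, 1), c(2, 3, 1, 1), c(3, 1, 2, 1), c(1, 1, 2, 2))
    for (r in seq_len(nrow(idx))) {
      pp <- p; pp[matrix(idx[r, ], 1)] <- p[matrix(idx[r, ], 1)] + h
      pm <- p; pm[matrix(idx[r, ], 1)] <- p[matrix(idx[r, ], 1)] - h
      fd <- (scale_loss(y, pp, cfg, activation = act) -
               scale_loss(y, pm, cfg, activation = act)) / (2 * h)
      expect_lt(abs(fd - g[matrix(idx[r, ], 1)]), 1e-4)
    }
  }
})

test_that("target downsampling votes per block with deterministic ties", {
  uni <- mask_from_array(array(1L, c(8, 8, 8)))
  expect_true(all(downsample_target(uni, 2)$data == 1L))
  expect_equal(dim(downsample_target(uni, 2)$data), c(4, 4, 4))
  expect_equal(downsample_target(uni, 2)$spacing, c(2, 2, 2))

  # factor equal to the full extent: single voxel, global majority
  maj <- array(0L, c(4, 4, 4)); maj[1:40] <- 2L
  expect_equal(as.vector(downsample_target(mask_from_array(maj), 4)$data), 2L)

  # 5 tumor / 3 background per 2^3 cell: tumor wins each cell
  cell <- array(0L, c(2, 2, 2)); cell[1:5] <- 2L
  big <- array(0L, c(4, 4, 4))
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    big[1:2 + 2 * i, 1:2 + 2 * j, 1:2 + 2 * k] <- cell
  }
  expect_true(all(downsample_target(mask_from_array(big), 2)$data == 2L))

  # exact tie 4/4 goes to the smaller label
  tie <- array(c(rep(0L, 4), rep(2L, 4)), c(2, 2, 2))
  expect_equal(as.vector(downsample_target(mask_from_array(tie), 2)$data), 0L)

  # non-divisible dims are padded by edge replication
  odd <- mask_from_array(array(1L, c(5, 4, 4)))
  expect_equal(dim(downsample_target(odd, 2)$data), c(3, 2, 2))
})
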