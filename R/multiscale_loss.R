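# Deep-supervision composite loss: per scale 0.5*cross-entropy + 0.5*Dice,
# summed over K scales with 1/K weights. Pure array functions so any
# training framework can wrap them; the class channel is the LAST array
# dimension throughout.

#' Configuration of the multi-scale segmentation loss
#'
#' @param n_classes Number of classes `C` (default 3: background, liver,
#'   tumor).
#' @param n_scales Number of supervision scales `K` (default 4).
#' @param scale_weights Per-scale weights, non-negative and summing to 1;
#'   default uniform `1/K`.
#' @param term_weights Weights of the cross-entropy and Dice terms within
#'   one scale, default `c(ce = 0.5, dice = 0.5)`.
#' @param epsilon Smoothing added to the soft-Dice denominator only, so the
#'   empty-class case is defined (default 1e-5).
#' @return A `loss_config` list.
#' @export
loss_config <- function(n_classes = 3L, n_scales = 4L,
                        scale_weights = NULL,
                        term_weights = c(ce = 0.5, dice = 0.5),
                        epsilon = 1e-5) {
  n_scales <- as.integer(n_scales)
  scale_weights <- scale_weights %||% rep(1 / n_scales, n_scales)
  if (length(scale_weights) != n_scales || any(scale_weights < 0)) {
    abort_argument("`scale_weights` must be K non-negative values")
  }
  if (abs(sum(scale_weights) - 1) > 1e-8) {
    abort_argument("`scale_weights` must sum to 1")
  }
  if (length(term_weights) != 2 || any(term_weights < 0)) {
    abort_argument("`term_weights` must be 2 non-negative values")
  }
  structure(
    list(n_classes = as.integer(n_classes), n_scales = n_scales,
         scale_weights = scale_weights, term_weights = term_weights,
         epsilon = epsilon),
    class = "loss_config"
  )
}

#' Turn logits into per-class probabilities
#'
#' Softmax normalizes across the class channel, forcing per-voxel class
#' probabilities to sum to 1 — which cannot represent a tumor voxel that is
#' also a liver voxel. Sigmoid maps each channel independently, so
#' overlapping structures (tumor inside liver) can both be near 1 at the
#' same voxel; this is the activation used for the dual liver/tumor output.
#'
#' @param logits Array whose last dimension is the class channel.
#' @param mode `"softmax"` or `"sigmoid"`.
#' @return Probability array of the same shape, with the activation stored
#'   in the `"activation"` attribute (consumed by [cross_entropy_loss()]).
#' @export
#' @examples
#' p <- activate(array(0, c(2, 2, 2, 3)), "softmax")
#' p[1, 1, 1, ]
activate <- function(logits, mode = c("softmax", "sigmoid")) {
  mode <- match.arg(mode)
  if (any(!is.finite(logits))) abort_argument("`logits` must be finite")
  d <- dim(logits)
  if (mode == "sigmoid") {
    p <- 1 / (1 + exp(-logits))
  } else {
    nc <- d[length(d)]
    m <- matrix(logits, ncol = nc)
    m <- m - apply(m, 1, max)
    e <- exp(m)
    p <- array(e / rowSums(e), d)
  }
  attr(p, "activation") <- mode
  p
}

check_loss_shapes <- function(y, p) {
  if (!identical(dim(y), dim(p))) {
    abort_argument("`y` and `p` must have identical shapes")
  }
}

# number of classes = extent of the last dimension
n_channels <- function(x) dim(x)[length(dim(x))]

channel_matrix <- function(x) matrix(x, ncol = n_channels(x))

#' Soft Dice loss
#'
#' `1 - (1/C) * sum_c 2|y_c ∩ p_c| / (|y_c| + |p_c|)` with the standard
#' soft relaxation `|y_c ∩ p_c| = sum(y_c * p_c)` and `epsilon` added to
#' the denominator only.
#'
#' @param y Ground-truth indicator array (class channel last). In sigmoid
#'   mode the liver and tumor channels may both be 1 at a voxel.
#' @param p Probability array of the same shape.
#' @param cfg A [loss_config()].
#' @return Scalar loss in `[0, 1]` (up to epsilon slack).
#' @export
dice_loss <- function(y, p, cfg = loss_config()) {
  check_loss_shapes(y, p)
  ym <- channel_matrix(y)
  pm <- channel_matrix(p)
  inter <- colSums(ym * pm)
  denom <- colSums(ym) + colSums(pm) + cfg$epsilon
  1 - mean(2 * inter / denom)
}

#' Cross-entropy loss
#'
#' Softmax form: per-voxel `-sum_c y_c log p_c`, averaged over voxels (the
#' per-voxel mean keeps the loss comparable across pyramid scales of
#' different sizes). When `p` carries a `"sigmoid"` activation attribute
#' (or `activation = "sigmoid"`), each channel is scored as independent
#' binary cross-entropy, averaged over voxels and channels. Probabilities
#' are clipped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @inheritParams dice_loss
#' @param activation Overrides the activation attribute of `p`.
#' @return Scalar loss >= 0.
#' @export
cross_entropy_loss <- function(y, p, cfg = loss_config(),
                               activation = NULL) {
  check_loss_shapes(y, p)
  act <- activation %||% attr(p, "activation") %||% "softmax"
  pm <- pmin(pmax(channel_matrix(p), 1e-7), 1 - 1e-7)
  ym <- channel_matrix(y)
  if (act == "sigmoid") {
    -mean(ym * log(pm) + (1 - ym) * log(1 - pm))
  } else {
    mean(-rowSums(ym * log(pm)))
  }
}

#' Single-scale composite loss
#'
#' `w_ce * cross_entropy + w_dice * dice` with weights from the config
#' (default 0.5 each).
#'
#' @inheritParams cross_entropy_loss
#' @return Scalar loss.
#' @export
scale_loss <- function(y, p, cfg = loss_config(), activation = NULL) {
  w <- cfg$term_weights
  unname(w[1]) * cross_entropy_loss(y, p, cfg, activation = activation) +
    unname(w[2]) * dice_loss(y, p, cfg)
}

#' Analytic gradient of the single-scale loss with respect to p
#'
#' The loss feeds backpropagation, so its gradient in the probabilities is
#' part of the contract; tests check it against central finite differences.
#' Valid away from the probability clipping boundary.
#'
#' @inheritParams scale_loss
#' @return Array of the same shape as `p`.
#' @export
scale_loss_grad <- function(y, p, cfg = loss_config(), activation = NULL) {
  check_loss_shapes(y, p)
  act <- activation %||% attr(p, "activation") %||% "softmax"
  ym <- channel_matrix(y)
  pm <- channel_matrix(p)
  nvox <- nrow(ym)
  nc <- ncol(ym)
  if (act == "sigmoid") {
    g_ce <- -(ym / pm - (1 - ym) / (1 - pm)) / (nvox * nc)
  } else {
    g_ce <- -(ym / pm) / nvox
  }
  inter <- colSums(ym * pm)
  denom <- colSums(ym) + colSums(pm) + cfg$epsilon
  g_dice <- -sweep(
    sweep(2 * ym, 2, denom, `/`),
    2, 2 * inter / denom^2, `-`
  ) / nc
  w <- cfg$term_weights
  array(unname(w[1]) * g_ce + unname(w[2]) * g_dice, dim(p))
}

#' Total deep-supervision loss over a resolution pyramid
#'
#' `sum_k scale_weights[k] * scale_loss(y_k, p_k)` over K scales of
#' strictly decreasing resolution.
#'
#' @param y_pyramid,p_pyramid Lists of K target/probability arrays, finest
#'   scale first.
#' @param cfg A [loss_config()] with matching `n_scales`.
#' @param activation Overrides the per-scale activation attributes.
#' @return Scalar loss.
#' @export
total_loss <- function(y_pyramid, p_pyramid, cfg = loss_config(),
                       activation = NULL) {
  K <- cfg$n_scales
  if (length(y_pyramid) != K || length(p_pyramid) != K) {
    abort_argument(sprintf("pyramids must have length K = %d", K))
  }
  sizes <- vapply(p_pyramid, function(x) prod(utils::head(dim(x), -1)),
                  numeric(1))
  if (K > 1 && any(diff(sizes) >= 0)) {
    abort_argument("pyramid resolutions must be strictly decreasing")
  }
  total <- 0
  for (k in seq_len(K)) {
    total <- total + cfg$scale_weights[k] *
      scale_loss(y_pyramid[[k]], p_pyramid[[k]], cfg, activation = activation)
  }
  total
}

#' Downsample a label mask by per-block majority vote
#'
#' Builds the ground truth for coarser supervision scales: each
#' `factor^3` block collapses to its most frequent label, ties broken by
#' the smallest label id (deterministic and independent of label order).
#' Dimensions not divisible by `factor` are padded by replicating the last
#' slice before voting.
#'
#' @param mask A [label_mask()].
#' @param factor Integer >= 2.
#' @return A [label_mask()] with `factor`-times coarser grid and spacing.
#' @export
downsample_target <- function(mask, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 2L) abort_argument("`factor` must be >= 2")
  dat <- mask$data
  d <- dim(dat)
  pad <- (factor - d %% factor) %% factor
  if (any(pad > 0)) {
    nd <- d + pad
    padded <- array(0L, nd)
    padded[1:d[1], 1:d[2], 1:d[3]] <- dat
    if (pad[1] > 0) padded[(d[1] + 1):nd[1], , ] <-
      padded[rep(d[1], pad[1]), , ]
    if (pad[2] > 0) padded[, (d[2] + 1):nd[2], ] <-
      padded[, rep(d[2], pad[2]), ]
    if (pad[3] > 0) padded[, , (d[3] + 1):nd[3]] <-
      padded[, , rep(d[3], pad[3])]
    dat <- padded
    d <- nd
  }
  out_d <- d %/% factor
  labels <- sort(unique(as.vector(dat)))
  best_count <- array(-1L, out_d)
  best_label <- array(labels[1], out_d)
  for (l in labels) {
    cnt <- block_sum(dat == l, factor)
    win <- cnt > best_count # strict: earlier (smaller) label wins ties
    best_label[win] <- l
    best_count[win] <- cnt[win]
  }
  label_mask(best_label, spacing = mask$spacing * factor,
             origin = mask$origin, legend = mask$legend)
}

# Sum of a logical/numeric 3D array over factor^3 blocks.
block_sum <- function(x, f) {
  d <- dim(x)
  out_d <- d %/% f
  dim(x) <- c(f, out_d[1], f, out_d[2], f, out_d[3])
  apply(x, c(2, 4, 6), sum)
}
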