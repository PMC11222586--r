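# Internal helpers: classed conditions, voxel neighbourhood geometry, logical
# array shifts and the separable squared Euclidean distance transform.

abort_cs <- function(msg, class) {
  rlang::abort(msg, class = c(paste0("cystscreen_", class), "cystscreen_error"))
}

abort_validation <- function(msg) abort_cs(msg, "validation_error")
abort_geometry   <- function(msg) abort_cs(msg, "geometry_error")
abort_io         <- function(msg) abort_cs(msg, "io_error")
abort_argument   <- function(msg) abort_cs(msg, "argument_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
connectivity_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort_argument("`connectivity` must be one of 6, 18 or 26")
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g)) # number of axes the offset moves along
  keep <- switch(as.character(connectivity),
    "6"  = ord == 1,
    "18" = ord >= 1 & ord <= 2,
    "26" = ord >= 1
  )
  unname(g[keep, , drop = FALSE])
}

# Half of the offset set (lexicographically positive) so each undirected
# voxel adjacency is enumerated once.
half_offsets <- function(connectivity) {
  g <- connectivity_offsets(connectivity)
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[keep, , drop = FALSE]
}

# Voxel offsets whose physical length is <= radius_mm under `spacing`.
ball_offsets <- function(radius_mm, spacing) {
  r <- abs(radius_mm)
  nmax <- pmax(0L, as.integer(floor(r / spacing)))
  g <- as.matrix(expand.grid(
    dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2], dz = -nmax[3]:nmax[3]
  ))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  unname(g[d2 <= r^2 + 1e-9, , drop = FALSE])
}

# Shift a 3D logical array by an integer voxel offset; voxels shifted in from
# outside the image are FALSE.
shift_logical <- function(x, offset) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      dst[[a]] <- (1 + o):d[a]
      src[[a]] <- 1:(d[a] - o)
    } else {
      dst[[a]] <- 1:(d[a] + o)
      src[[a]] <- (1 - o):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# 1D squared distance transform (lower envelope of parabolas) on a sampled
# line with squared sample spacing w2. `f` holds squared distances.
dt1d <- function(f, w2) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + w2 * q * q) - (f[vk] + w2 * vk * vk)) / (2 * w2 * (q - vk))
      if (s > z[k]) break
      k <- k - 1L
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    vk <- v[k]
    d[q] <- w2 * (q - vk)^2 + f[vk]
  }
  d
}

# Exact squared Euclidean distance (mm^2) from every voxel to the nearest
# TRUE voxel, honouring anisotropic spacing. Felzenszwalb-Huttenlocher
# separable transform; LARGE stands in for +Inf to keep the envelope
# arithmetic finite.
edt_squared <- function(mask, spacing) {
  LARGE <- 1e30
  d <- dim(mask)
  f <- array(LARGE, d)
  f[mask] <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    f[, j, k] <- dt1d(f[, j, k], spacing[1]^2)
  }
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) {
    f[i, , k] <- dt1d(f[i, , k], spacing[2]^2)
  }
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    f[i, j, ] <- dt1d(f[i, j, ], spacing[3]^2)
  }
  f
}

# Voxel indices (n x 3 integer matrix) -> linear indices for dims d.
voxel_to_linear <- function(idx, d) {
  as.integer(idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2])
}

linear_to_voxel <- function(lin, d) {
  lin0 <- lin - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i + 1L, j + 1L, k + 1L)
}
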