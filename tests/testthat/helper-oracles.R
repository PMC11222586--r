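# Independent brute-force oracles: these deliberately reimplement the
# checked operations in the most literal way possible (explicit loops, no
# shared helpers with the package), so that agreement is meaningful.

# Flood-fill connected components by breadth-first search over explicit
# neighbor triples. Returns an integer membership array (0 = background).
oracle_flood_fill <- function(arr, connectivity) {
  d <- dim(arr)
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    moved <- abs(dx) + abs(dy) + abs(dz)
    use <- if (connectivity == 6) moved == 1
           else if (connectivity == 18) moved %in% c(1, 2)
           else moved >= 1
    if (use) offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  comp <- array(0L, d)
  ncomp <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!arr[i, j, k] || comp[i, j, k] > 0L) next
    ncomp <- ncomp + 1L
    queue <- list(c(i, j, k))
    comp[i, j, k] <- ncomp
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (o in offs) {
        n <- v + o
        if (any(n < 1) || n[1] > d[1] || n[2] > d[2] || n[3] > d[3]) next
        if (arr[n[1], n[2], n[3]] && comp[n[1], n[2], n[3]] == 0L) {
          comp[n[1], n[2], n[3]] <- ncomp
          queue[[length(queue) + 1]] <- n
        }
      }
    }
  }
  comp
}

# Check that the package's region decomposition induces the same partition
# as the flood-fill oracle.
expect_same_partition <- function(regions, oracle_comp) {
  expect_equal(length(regions), max(oracle_comp))
  seen <- integer(0)
  for (reg in regions) {
    idx <- reg$voxel_indices
    labs <- oracle_comp[cbind(idx[, 1], idx[, 2], idx[, 3])]
    expect_length(unique(labs), 1L)
    expect_false(labs[1] %in% seen)
    expect_equal(reg$voxel_count, sum(oracle_comp == labs[1]))
    seen <- c(seen, labs[1])
  }
}

# Surface voxels of a binary array by literal 6-neighborhood inspection.
oracle_surface <- function(arr) {
  d <- dim(arr)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!arr[i, j, k]) next
    boundary <- FALSE
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      n <- c(i, j, k) + o
      if (any(n < 1) || n[1] > d[1] || n[2] > d[2] || n[3] > d[3] ||
          !arr[n[1], n[2], n[3]]) {
        boundary <- TRUE
        break
      }
    }
    if (boundary) out <- rbind(out, c(i, j, k))
  }
  out
}

# Directed distances by all-pairs search, then the symmetrized 95th
# percentile with explicit linear interpolation between order statistics.
oracle_hd95 <- function(binA, binB, spacing, prob = 0.95) {
  ptsA <- sweep(oracle_surface(binA) - 1, 2, spacing, `*`)
  ptsB <- sweep(oracle_surface(binB) - 1, 2, spacing, `*`)
  directed <- function(P, Q) {
    apply(P, 1, function(p) {
      sqrt(min((Q[, 1] - p[1])^2 + (Q[, 2] - p[2])^2 + (Q[, 3] - p[3])^2))
    })
  }
  pctl <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    if (n == 1) return(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  dAB <- directed(ptsA, ptsB)
  dBA <- directed(ptsB, ptsA)
  list(
    hd = max(max(dAB), max(dBA)),
    hd95 = max(pctl(dAB, prob), pctl(dBA, prob))
  )
}
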