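#' Dice similarity coefficient between two labeled structures
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)` over voxel sets, in `[0, 1]` with
#' 1 for perfect agreement. Conventions for degenerate cases: both
#' structures empty gives 1.0; one empty and one not gives 0.0.
#'
#' @param a,b [label_mask()]s on the same voxel grid.
#' @param label Structure label in `a` (default: legend's `tumor`).
#' @param label_b Structure label in `b` (default: `label`).
#' @return DSC as a single number.
#' @export
#' @examples
#' m <- array(0L, c(8, 8, 8)); m[2:5, 2:5, 2:5] <- 2L
#' dsc(label_mask(m), label_mask(m), label = 2)
dsc <- function(a, b, label = NULL, label_b = label) {
  check_aligned(a, b)
  label <- label %||% a$legend[["tumor"]]
  label_b <- label_b %||% label
  va <- a$data == as.integer(label)
  vb <- b$data == as.integer(label_b)
  na <- sum(va); nb <- sum(vb)
  if (na == 0 && nb == 0) return(1.0)
  2 * sum(va & vb) / (na + nb)
}

#' Extract the boundary surface of a structure as physical points
#'
#' A voxel belongs to the surface when it carries the label and its
#' 6-neighbourhood contains at least one non-label voxel (image borders
#' count as background). Voxel indices are mapped to mm using the spacing,
#' so distances between surfaces are physical.
#'
#' @param mask A [label_mask()].
#' @param label Structure label.
#' @return An n x 3 matrix of mm coordinates with attributes `spacing` and
#'   `voxel_indices`; raises an empty-structure error for an empty label.
#' @export
extract_surface <- function(mask, label = NULL) {
  label <- label %||% mask$legend[["tumor"]]
  bin <- mask$data == as.integer(label)
  if (!any(bin)) abort_cs("structure is empty", "empty_structure")
  surf <- surface_voxels(bin)
  idx <- linear_to_voxel(which(surf), dim(bin))
  pts <- sweep(idx - 1, 2, mask$spacing, `*`)
  attr(pts, "spacing") <- mask$spacing
  attr(pts, "voxel_indices") <- idx
  pts
}

surface_voxels <- function(bin) {
  interior <- bin
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    interior <- interior & shift_logical(bin, o)
  }
  bin & !interior
}

# Directed surface distances d(A -> B): for every A-surface voxel the
# Euclidean mm distance to the nearest B-surface voxel, computed from the
# separable distance transform of B's surface over the joint bounding box.
directed_surface_distances <- function(surfA, surfB, d, spacing) {
  idxA <- attr(surfA, "voxel_indices")
  idxB <- attr(surfB, "voxel_indices")
  all_idx <- rbind(idxA, idxB)
  lo <- pmax(apply(all_idx, 2, min) - 1L, 1L)
  hi <- apply(all_idx, 2, max)
  sub_dim <- hi - lo + 1L
  binB <- array(FALSE, sub_dim)
  shiftedB <- sweep(idxB, 2, lo - 1L, `-`)
  binB[voxel_to_linear(shiftedB, sub_dim)] <- TRUE
  d2 <- edt_squared(binB, spacing)
  shiftedA <- sweep(idxA, 2, lo - 1L, `-`)
  sqrt(d2[voxel_to_linear(shiftedA, sub_dim)])
}

#' Hausdorff distances between two structures
#'
#' Computes the directed surface-to-surface distances in both directions
#' and returns the exact Hausdorff distance
#' `HD = max(h(A,B), h(B,A))` with `h(A,B)` the greatest distance from a
#' surface point of one set to the closest surface point of the other, and
#' the 95th-percentile variant `HD95`, the largest separation among the
#' closest 95% of surface points. By default HD95 symmetrizes like HD
#' (maximum of the two directed 95th percentiles, linear-interpolation
#' percentile); `method = "pooled"` instead takes the 95th percentile of
#' the pooled directed distances.
#'
#' @param a,b Aligned [label_mask()]s; both structures must be non-empty.
#' @param label,label_b Structure labels, as in [dsc()].
#' @param method Symmetrization of the 95th percentile.
#' @return Named numeric vector `c(hd, hd95)` in mm.
#' @export
hausdorff <- function(a, b, label = NULL, label_b = label,
                      method = c("max_directed", "pooled")) {
  method <- match.arg(method)
  check_aligned(a, b)
  label <- label %||% a$legend[["tumor"]]
  label_b <- label_b %||% label
  sa <- extract_surface(a, label)
  sb <- extract_surface(b, label_b)
  d_ab <- directed_surface_distances(sa, sb, dim(a$data), a$spacing)
  d_ba <- directed_surface_distances(sb, sa, dim(a$data), a$spacing)
  hd <- max(max(d_ab), max(d_ba))
  hd95 <- if (method == "max_directed") {
    max(stats::quantile(d_ab, 0.95, names = FALSE),
        stats::quantile(d_ba, 0.95, names = FALSE))
  } else {
    stats::quantile(c(d_ab, d_ba), 0.95, names = FALSE)
  }
  c(hd = hd, hd95 = hd95)
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' @inheritParams hausdorff
#' @return HD95 in mm.
#' @seealso [hausdorff()] for the exact HD and symmetrization options.
#' @export
hd95 <- function(a, b, label = NULL, label_b = label,
                 method = c("max_directed", "pooled")) {
  unname(hausdorff(a, b, label = label, label_b = label_b,
                   method = method)["hd95"])
}

#' Compare two segmentation variants across cases
#'
#' For each case, computes DSC and HD95 of two variants against the truth
#' and runs a two-sided paired t-test on the per-case differences — the
#' standard per-case comparison table for a post-processing step.
#'
#' @param cases List of cases, each a list with elements `truth`, `a`, `b`
#'   ([label_mask()]s on a shared grid).
#' @param label Structure label to evaluate.
#' @return A `case_comparison` tibble with columns `case`, `dsc_a`,
#'   `hd95_a`, `dsc_b`, `hd95_b`. Attributes: `summary` (mean, sd, min,
#'   median, max per metric) and `tests` (paired t statistic and two-sided
#'   P for the DSC and HD95 differences; identical variants give P = 1 by
#'   convention).
#' @export
compare_cases <- function(cases, label = 2L) {
  if (length(cases) < 2) abort_argument("need at least 2 cases")
  ok <- vapply(cases, function(cs) {
    all(c("truth", "a", "b") %in% names(cs))
  }, logical(1))
  if (!all(ok)) abort_argument("each case needs `truth`, `a` and `b` masks")

  rows <- purrr::imap(cases, function(cs, i) {
    tibble::tibble(
      case = as.integer(i),
      dsc_a = dsc(cs$a, cs$truth, label = label),
      hd95_a = hd95(cs$a, cs$truth, label = label),
      dsc_b = dsc(cs$b, cs$truth, label = label),
      hd95_b = hd95(cs$b, cs$truth, label = label)
    )
  })
  tab <- dplyr::bind_rows(rows)

  summarize_col <- function(v) {
    tibble::tibble(mean = mean(v), sd = stats::sd(v), min = min(v),
                   median = stats::median(v), max = max(v))
  }
  summ <- dplyr::bind_rows(
    lapply(tab[c("dsc_a", "hd95_a", "dsc_b", "hd95_b")], summarize_col),
    .id = "metric"
  )

  paired_p <- function(x, y) {
    dd <- x - y
    if (all(dd == 0)) {
      return(tibble::tibble(statistic = 0, p_value = 1, significant = FALSE))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    tibble::tibble(statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   significant = tt$p.value < 0.05)
  }
  tests <- dplyr::bind_rows(
    dsc = paired_p(tab$dsc_a, tab$dsc_b),
    hd95 = paired_p(tab$hd95_a, tab$hd95_b),
    .id = "metric"
  )

  attr(tab, "summary") <- summ
  attr(tab, "tests") <- tests
  class(tab) <- c("case_comparison", class(tab))
  tab
}

#' @export
print.case_comparison <- function(x, ...) {
  cat(sprintf("<case_comparison> %d cases\n", nrow(x)))
  print(tibble::as_tibble(x))
  cat("\nAggregates:\n")
  print(attr(x, "summary"))
  cat("\nPaired t-tests (a vs b):\n")
  print(attr(x, "tests"))
  invisible(x)
}
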