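#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Gaussian HU fit
#'
#' @param x A `gaussian_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`A`, `M`, `S`).
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "M", "S"),
    estimate = c(x$A, x$M, x$S)
  )
}

#' One-row summary of a Gaussian HU fit
#'
#' @inheritParams tidy.gaussian_fit
#' @return A tibble with `r_squared`, `n_samples`, `converged`.
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    n_samples = x$n_samples,
    converged = x$converged
  )
}

#' Tidy an HU histogram
#'
#' @param x An `hu_histogram`.
#' @param ... Unused.
#' @return A tibble of `(bin_center, count)`.
#' @export
tidy.hu_histogram <- function(x, ...) {
  tibble::tibble(bin_center = bin_centers(x), count = x$counts)
}

#' Plot a region histogram with its fitted Gaussian
#'
#' Reproduces the standard per-region diagnostic: the (smoothed) HU counts
#' with the fitted curve overlaid.
#'
#' @param object A `gaussian_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaussian_fit <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_center)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count),
                      width = diff(dat$bin_center[1:2]),
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                       color = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "HU", y = "count",
      title = sprintf("Gaussian fit: M = %.1f HU, S = %.1f HU (R² = %.2f)",
                      object$M, object$S, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-region filter decisions
#'
#' Decided mean HU per region, colored by verdict, with the decision
#' threshold drawn as a horizontal line.
#'
#' @param object A `filter_report` from [filter_mask()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.filter_report <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$region_id), y = .data$decided_mean,
    fill = .data$verdict
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "region", y = "decided mean (HU)",
                  fill = "verdict") +
    ggplot2::theme_minimal()
}

#' Glance at a case comparison
#'
#' @param x A `case_comparison` from [compare_cases()].
#' @param ... Unused.
#' @return The paired-test tibble (metric, t statistic, two-sided P).
#' @export
glance.case_comparison <- function(x, ...) {
  attr(x, "tests")
}
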