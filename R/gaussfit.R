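#' Gaussian model for an HU histogram
#'
#' Evaluates `f(HU) = A / sqrt(2*pi*S^2) * exp(-(HU - M)^2 / (2*S^2))`, the
#' count-scale Gaussian fitted to region histograms: `M` is the mean HU,
#' `S` the standard deviation and `A` the amplitude (the integral of the
#' curve over HU, i.e. roughly the voxel count times the bin width).
#'
#' @param hu HU values at which to evaluate.
#' @param A,M,S Amplitude, mean (HU) and standard deviation (HU).
#' @return Numeric vector of expected counts.
#' @export
gauss_curve <- function(hu, A, M, S) {
  A / sqrt(2 * pi * S^2) * exp(-(hu - M)^2 / (2 * S^2))
}

#' Count-weighted moments of an HU histogram
#'
#' Fallback estimator used when a region is too small or too degenerate to
#' support a curve fit: the mean and (population) standard deviation of the
#' bin centers weighted by counts.
#'
#' @param h An `hu_histogram` with at least one sample.
#' @return Named numeric vector `c(mean, sd)` in HU.
#' @export
empirical_moments <- function(h) {
  if (!inherits(h, "hu_histogram")) abort_argument("`h` must be an hu_histogram")
  total <- sum(h$counts)
  if (total <= 0) abort_argument("histogram is empty")
  x <- bin_centers(h)
  m <- sum(h$counts * x) / total
  v <- sum(h$counts * (x - m)^2) / total
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Fit the Gaussian HU model to a histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [gauss_curve()] against
#' bin centers vs counts. Counts, not normalized frequencies, are fitted:
#' the amplitude then reflects region size, and only the fitted mean enters
#' the downstream decision rule, so the bin-width dependence of `A` is
#' harmless. Initialization uses the histogram moments
#' (`M0` = mean, `S0` = sd, `A0 = max(count) * sqrt(2*pi) * S0`) with bounds
#' `S` in (0.1, 500) HU and `M` inside the histogram range. Optimizer
#' failure is a reportable state, not an exception: the fit falls back to
#' the empirical moments with `converged = FALSE`.
#'
#' @param h An `hu_histogram` (smoothed or not) with at least 3 nonzero
#'   bins; fewer raise a degenerate-fit error so the caller can fall back
#'   to [empirical_moments()].
#' @return A `gaussian_fit` with fields `A`, `M`, `S`, `r_squared` (in
#'   `[0, 1]`), `n_samples`, `converged`, and a `data` tibble of
#'   `(bin_center, count, fitted)`.
#' @export
#' @examples
#' set.seed(7)
#' h <- hu_histogram(rnorm(20000, 91, 23))
#' fit <- fit_gaussian(smooth_histogram(h))
#' round(c(fit$M, fit$S), 1)
fit_gaussian <- function(h) {
  if (!inherits(h, "hu_histogram")) abort_argument("`h` must be an hu_histogram")
  x <- bin_centers(h)
  y <- h$counts
  if (sum(y > 0) < 3) {
    abort_cs("fewer than 3 nonzero bins: histogram cannot support a fit",
             "degenerate_fit")
  }
  emp <- empirical_moments(h)
  M0 <- unname(emp["mean"])
  S0 <- max(unname(emp["sd"]), 0.5)
  A0 <- max(y) * sqrt(2 * pi) * S0
  lo <- min(h$bin_edges); hi <- max(h$bin_edges)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A / sqrt(2 * pi * S^2) * exp(-(x - M)^2 / (2 * S^2)),
      start = list(A = A0, M = M0, S = S0),
      lower = c(A = 0, M = lo, S = 0.1),
      upper = c(A = Inf, M = hi, S = 500),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-8, ptol = 1e-8, maxfev = 10000, maxiter = 1024
      )
    ),
    error = function(e) NULL,
    warning = function(w) NULL
  )

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    A <- unname(cf["A"]); M <- unname(cf["M"]); S <- unname(cf["S"])
    converged <- is.finite(A) && is.finite(M) && S > 0
  } else {
    # fall back to empirical moments; A from total mass
    bw <- diff(h$bin_edges[1:2])
    A <- sum(y) * bw
    M <- M0
    S <- max(unname(emp["sd"]), 1e-8)
    converged <- FALSE
  }
  fitted <- gauss_curve(x, A, M, S)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(
    list(A = A, M = M, S = S,
         r_squared = min(max(r2, 0), 1),
         n_samples = h$n_samples, converged = converged,
         data = tibble::tibble(bin_center = x, count = y, fitted = fitted)),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_fit> A = %.1f, M = %.2f HU, S = %.2f HU (R2 = %.3f, n = %d%s)\n",
    x$A, x$M, x$S, x$r_squared, x$n_samples,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}
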