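#' Hypothesis on a contrast of GLM coefficients
#'
#' One-sided hypotheses test `H0: cB = theta0` against
#' `Ha: cB >= theta1` (`theta1 > theta0`); two-sided hypotheses test
#' `H0: |cB - theta0| = 0` against `Ha: |cB - theta0| >= delta`
#' (`delta > 0`).
#'
#' @param c Contrast vector over the design-matrix columns (including the
#'   intercept).
#' @param theta0 Null value of the contrast (default 0).
#' @param theta1 One-sided alternative value (`> theta0`); supply exactly
#'   one of `theta1` / `delta`.
#' @param delta Two-sided practically important difference (`> 0`).
#' @param label Optional name used in reports.
#' @return An object of class `sprt_hypothesis` with `sidedness`
#'   `"one"` or `"two"`.
#' @examples
#' hypothesis(c(0, 1, 0), theta1 = 1, label = "taskA")
#' hypothesis(c(0, 1, -1), delta = 1, label = "A-minus-B")
#' @export
hypothesis <- function(c, theta0 = 0, theta1 = NULL, delta = NULL,
                       label = NULL) {
  if (is.null(theta1) == is.null(delta))
    stop("supply exactly one of 'theta1' (one-sided) or 'delta' (two-sided)")
  if (!is.null(theta1)) {
    if (theta1 <= theta0) stop("'theta1' must exceed 'theta0'")
    sidedness <- "one"
  } else {
    if (delta <= 0) stop("'delta' must be > 0")
    sidedness <- "two"
  }
  structure(list(c = as.numeric(c), theta0 = theta0, theta1 = theta1,
                 delta = delta, sidedness = sidedness,
                 label = if (is.null(label)) "contrast" else label),
            class = "sprt_hypothesis")
}

#' SPRT stopping boundaries
#'
#' Wald's boundaries `A = log((1 - beta_n)/alpha_n)` and
#' `B = log(beta_n/(1 - alpha_n))` with Bonferroni-adjusted error rates
#' `alpha_n = alpha/N`, `beta_n = beta/N` for `N` simultaneous tests, plus
#' a truncation bound `T` (maximum number of volumes) at which the test
#' decides by the sign of the statistic.
#'
#' @param alpha Type I error rate in (0, 1).
#' @param beta Type II error rate in (0, 1).
#' @param n_tests Bonferroni count `N` (>= 1), typically the number of
#'   voxels times the number of hypotheses per voxel.
#' @param truncation Truncation bound `T` in volumes (default `Inf`).
#' @return Object of class `sprt_boundaries` with elements `A`, `B`,
#'   `alpha`, `beta`, `alpha_n`, `beta_n`, `n_tests`, `truncation`.
#' @examples
#' compute_boundaries(0.01, 0.1)            # A = log 90, B = log(0.1/0.99)
#' compute_boundaries(0.01, 0.1, n_tests = 2304, truncation = 360)
#' @export
compute_boundaries <- function(alpha, beta, n_tests = 1,
                               truncation = Inf) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1")
  if (!is.numeric(beta) || beta <= 0 || beta >= 1)
    stop("'beta' must lie strictly between 0 and 1")
  if (n_tests < 1) stop("'n_tests' must be >= 1")
  if (truncation < 1) stop("'truncation' must be >= 1")
  alpha_n <- alpha / n_tests
  beta_n <- beta / n_tests
  structure(list(A = log((1 - beta_n) / alpha_n),
                 B = log(beta_n / (1 - alpha_n)),
                 alpha = alpha, beta = beta,
                 alpha_n = alpha_n, beta_n = beta_n,
                 n_tests = n_tests, truncation = truncation),
            class = "sprt_boundaries")
}

#' @export
print.sprt_boundaries <- function(x, ...) {
  cat("SPRT boundaries: A = ", signif(x$A, 6), ", B = ", signif(x$B, 6),
      " (alpha = ", x$alpha, ", beta = ", x$beta, ", N = ", x$n_tests,
      ", T = ", x$truncation, ")\n", sep = "")
  invisible(x)
}

#' Sequential log likelihood ratios for a Gaussian contrast estimate
#'
#' `lambda_one_sided()` is the plug-in Wald statistic for
#' `H0: cB = theta0` vs `Ha: cB = theta1`,
#' `((cb - theta0)^2 - (cb - theta1)^2) / (2 v)`; `lambda_two_sided()`
#' weights the two alternatives `theta0 +/- delta` equally and is computed
#' in log-sum-exp form for numerical stability. Both accept vector
#' `cb_hat` / `var_hat` (recycled) and return `NA` where `var_hat` is not
#' positive (the voxel is not yet estimable and remains in the continue
#' state).
#'
#' @param cb_hat Contrast estimate(s).
#' @param var_hat Plug-in variance(s) of the contrast estimate.
#' @param theta0 Null value.
#' @param theta1 One-sided alternative value.
#' @param delta Two-sided practically important difference.
#' @return Numeric vector of log likelihood ratios.
#' @export
lambda_one_sided <- function(cb_hat, var_hat, theta0 = 0, theta1) {
  if (theta1 <= theta0) stop("'theta1' must exceed 'theta0'")
  out <- 0.5 * ((cb_hat - theta0)^2 - (cb_hat - theta1)^2) / var_hat
  out[!is.finite(var_hat) | var_hat <= 0] <- NA_real_
  out
}

#' @rdname lambda_one_sided
#' @export
lambda_two_sided <- function(cb_hat, var_hat, theta0 = 0, delta) {
  if (delta <= 0) stop("'delta' must be > 0")
  z <- cb_hat - theta0
  # log(1/2 (exp(-(z-delta)^2/2v) + exp(-(z+delta)^2/2v))) + z^2/2v
  a <- -(z - delta)^2 / (2 * var_hat)
  b <- -(z + delta)^2 / (2 * var_hat)
  m <- pmax(a, b)
  out <- log(0.5) + m + log(exp(a - m) + exp(b - m)) + z^2 / (2 * var_hat)
  out[!is.finite(var_hat) | var_hat <= 0] <- NA_real_
  out
}

#' Voxel-level SPRT decision rule
#'
#' Before truncation, sampling continues while `B < lambda < A`; crossing
#' a boundary (attainment included) stops the voxel's test. At the
#' truncation bound `t = T` the test stops and accepts `Ha` when
#' `lambda > 0`, `H0` otherwise. `NA` statistics (below burn-in) always
#' continue.
#'
#' @param lambda_t Log likelihood ratio(s) at volume `t`.
#' @param bounds An [compute_boundaries()] object.
#' @param t Current volume index (>= 1).
#' @return Character vector over `lambda_t`:
#'   `"continue"`, `"accept_H0"` or `"accept_Ha"`.
#' @export
decide <- function(lambda_t, bounds, t) {
  stopifnot(inherits(bounds, "sprt_boundaries"), t >= 1)
  out <- rep("continue", length(lambda_t))
  if (t >= bounds$truncation) {
    out[!is.na(lambda_t) & lambda_t > 0] <- "accept_Ha"
    out[is.na(lambda_t) | lambda_t <= 0] <- "accept_H0"
  } else {
    out[!is.na(lambda_t) & lambda_t >= bounds$A] <- "accept_Ha"
    out[!is.na(lambda_t) & lambda_t <= bounds$B] <- "accept_H0"
  }
  out
}

#' Global stopping rule over an ROI
#'
#' Scanning stops once at least `g_percent` percent of the in-mask voxels
#' have reached a non-continue verdict for all of their hypotheses.
#'
#' @param verdicts Character vector (or matrix, voxels x hypotheses) of
#'   verdicts as returned by [decide()].
#' @param g_percent Target percentage `G` in (0, 100].
#' @param mask_size Number of in-mask voxels; defaults to the number of
#'   rows of `verdicts`.
#' @return `TRUE` when the rule is satisfied.
#' @export
global_stop <- function(verdicts, g_percent, mask_size = NULL) {
  if (g_percent <= 0 || g_percent > 100)
    stop("'g_percent' must lie in (0, 100]")
  v <- as.matrix(verdicts)
  if (nrow(v) == 0) stop("empty mask")
  if (is.null(mask_size)) mask_size <- nrow(v)
  decided <- rowSums(v == "continue") == 0
  100 * sum(decided) / mask_size >= g_percent
}

#' Final activation classification at the stopping time
#'
#' Voxels whose SPRT never crossed a boundary are classified by the sign
#' of the final statistic: `Ha` when `lambda_T > 0`, `H0` otherwise --
#' equivalently, by the hypothesized parameter value with the larger
#' likelihood. Undefined statistics (never past burn-in) classify as `H0`.
#'
#' @param lambda_T Final log likelihood ratio(s).
#' @return Character vector `"H0"` / `"Ha"`.
#' @export
final_classify <- function(lambda_T) {
  ifelse(!is.na(lambda_T) & lambda_T > 0, "Ha", "H0")
}
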