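#' Fixed-design GLM contrast t-test
#'
#' Conventional batch GLM inference for one voxel: the contrast t
#' statistic `c B_hat / sqrt(s2 c (X'V^-1 X)^-1 c')` with the unbiased
#' variance estimator (divisor `t - P - 1`) and a p-value from the t
#' distribution with `t - P - 1` degrees of freedom.
#'
#' @param X Design matrix.
#' @param y Response series.
#' @param c Contrast vector.
#' @param cov [temporal_covariance()] (default identity).
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return List with `statistic`, `p_value`, `estimate`, `df`.
#' @export
glm_ttest <- function(X, y, c, cov = temporal_covariance("identity"),
                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more volumes than coefficients")
  fit <- gls_fit(X, y, cov)
  est <- sum(c * fit$beta_hat)
  se <- sqrt(contrast_variance(c, X, cov, fit$sigma2_unbiased))
  stat <- est / se
  if (se == 0)  # exact fit: +/-Inf for a real effect, 0 for roundoff
    stat <- if (abs(est) <= max(abs(y)) * 1e-10) 0 else sign(est) * Inf
  df <- nrow(X) - ncol(X)
  p <- if (alternative == "greater") stats::pt(stat, df, lower.tail = FALSE)
       else 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  list(statistic = stat, p_value = p, estimate = est, df = df)
}

#' Benjamini-Hochberg FDR rejection set
#'
#' Step-up false discovery rate control at level `q`: reject all
#' hypotheses up to the largest `i` with `p_(i) <= q i / m`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q Target FDR level.
#' @return Integer vector of rejected indices (into `pvalues`), possibly
#'   empty.
#' @export
fdr_bh <- function(pvalues, q) {
  if (length(pvalues) == 0) return(integer(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  which(stats::p.adjust(pvalues, method = "BH") <= q)
}

#' Fixed-design benchmark analysis of a dataset
#'
#' The conventional comparison arm: after the full scan, run a voxel-wise
#' GLM contrast t-test over the mask and control the false discovery rate
#' by Benjamini-Hochberg at level `q`. Preprocessing mirrors the
#' sequential pipeline (smoothing, drift correction).
#'
#' @param data 3-D array (rows x cols x volumes) or `sim_dataset`.
#' @param paradigm The run's [paradigm].
#' @param contrasts A list of contrast vectors (or a single vector), or a
#'   list of [hypothesis()] objects whose contrasts and sidedness are
#'   used.
#' @param mask Logical matrix (default all voxels).
#' @param q FDR level (default 0.01).
#' @param cov [temporal_covariance()].
#' @param hrf HRF kernel (default canonical double gamma).
#' @param smooth,fwhm,kernel_extent,drift,drift_lambda Preprocessing
#'   controls as in [run_sequential()].
#' @return Object of class `fixed_run`: `active` (voxels x contrasts
#'   logical), `p_values`, `statistics`, `class_map` (coded as in
#'   [run_sequential()]), `mask_index`, `q`.
#' @export
run_fixed <- function(data, paradigm, contrasts, mask = NULL, q = 0.01,
                      cov = temporal_covariance("identity"), hrf = NULL,
                      smooth = TRUE, fwhm = 6, kernel_extent = 3,
                      drift = TRUE, drift_lambda = 0.1) {
  if (inherits(data, "sim_dataset")) data <- data$data
  if (is.null(dim(data))) data <- array(data, c(1, 1, length(data)))
  d <- dim(data)
  nt <- d[length(d)]
  shape <- d[-length(d)]
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = paradigm$tr)
  X <- build_design_matrix(paradigm, hrf)[seq_len(nt), , drop = FALSE]
  if (inherits(contrasts, "sprt_hypothesis")) contrasts <- list(contrasts)
  if (is.numeric(contrasts)) contrasts <- list(contrasts)
  clist <- lapply(contrasts, function(ct)
    if (inherits(ct, "sprt_hypothesis")) ct$c else as.numeric(ct))
  sides <- vapply(contrasts, function(ct)
    if (inherits(ct, "sprt_hypothesis") && ct$sidedness == "two")
      "two.sided" else "greater", character(1))
  labels <- vapply(seq_along(contrasts), function(i) {
    ct <- contrasts[[i]]
    if (inherits(ct, "sprt_hypothesis")) ct$label else paste0("c", i)
  }, character(1))

  if (is.null(mask)) mask <- array(TRUE, shape)
  midx <- which(mask)
  nvox <- length(midx)

  # preprocess volume by volume, as in the sequential arm
  dstate <- NULL
  fm <- matrix(data, ncol = nt)
  flat <- matrix(0, nvox, nt)
  for (t in seq_len(nt)) {
    vol <- array(fm[, t], shape)
    if (smooth) vol <- gaussian_smooth(vol, fwhm, kernel_extent)
    if (drift) {
      dc <- drift_correct(dstate, vol, t, drift_lambda)
      vol <- dc$volume
      dstate <- dc$state
    }
    flat[, t] <- as.numeric(vol)[midx]
  }

  Xw <- whiten(X, cov)
  Yw <- t(whiten(t(flat), cov))
  xtx <- crossprod(Xw)
  check_design_rank(xtx, colnames(X))
  xtx_inv <- solve(xtx)
  beta <- xtx_inv %*% crossprod(Xw, t(Yw))        # k x nvox
  rss <- pmax(rowSums(Yw^2) - colSums(beta * crossprod(Xw, t(Yw))), 0)
  df <- nt - ncol(X)
  s2 <- rss / df

  H <- length(clist)
  pvals <- stats <- matrix(NA_real_, nvox, H,
                           dimnames = list(NULL, labels))
  active <- matrix(FALSE, nvox, H, dimnames = list(NULL, labels))
  for (h in seq_len(H)) {
    cv <- clist[[h]]
    se <- sqrt(s2 * drop(crossprod(cv, xtx_inv %*% cv)))
    stat <- drop(crossprod(cv, beta)) / se
    p <- if (sides[h] == "greater")
      stats::pt(stat, df, lower.tail = FALSE)
    else 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    stats[, h] <- stat
    pvals[, h] <- p
    active[fdr_bh(p, q), h] <- TRUE
  }

  code <- integer(nvox)
  for (h in seq_len(H)) code <- code + as.integer(active[, h]) * 2L^(h - 1L)
  class_map <- array(NA_integer_, shape)
  class_map[midx] <- code

  structure(list(active = active, p_values = pvals, statistics = stats,
                 class_map = class_map, mask = mask, mask_index = midx,
                 q = q, n_volumes = nt),
            class = "fixed_run")
}

#' @export
print.fixed_run <- function(x, ...) {
  cat("fixed-design GLM run: ", x$n_volumes, " volumes, FDR q = ", x$q,
      "\n  active voxels per contrast: ",
      paste(colnames(x$active), colSums(x$active), sep = ":",
            collapse = "  "), "\n", sep = "")
  invisible(x)
}
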