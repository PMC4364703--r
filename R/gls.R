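#' Generalized least squares fit of a voxel GLM
#'
#' Fits `y = X B + E`, `E ~ N(0, sigma^2 V_t)`, by GLS:
#' `B_hat = (X' V^-1 X)^-1 X' V^-1 y`. The error variance is estimated by
#' its maximum-likelihood estimator `rss / t` (the divisor convention used
#' by the sequential tests); the unbiased estimator `rss / (t - P - 1)`
#' is also returned for fixed-design t-tests.
#'
#' @param X Design matrix (`t x (P + 1)`), see [build_design_matrix()].
#' @param y Numeric response vector of length `nrow(X)`.
#' @param cov A [temporal_covariance()]; default identity.
#' @return An object of class `voxel_state`: a list with elements `t`,
#'   `beta_hat`, `rss` (generalized residual sum of squares),
#'   `sigma2_hat` (MLE), `sigma2_unbiased`, and `estimable`.
#' @export
gls_fit <- function(X, y, cov = temporal_covariance("identity")) {
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)")
  Xw <- whiten(X, cov)
  yw <- whiten(matrix(y, ncol = 1), cov)
  xtx <- crossprod(Xw)
  check_design_rank(xtx, colnames(X))
  beta <- drop(solve(xtx, crossprod(Xw, yw)))
  names(beta) <- colnames(X)
  rss <- drop(crossprod(yw)) - sum(beta * crossprod(Xw, yw))
  rss <- max(rss, 0)
  t <- nrow(X)
  new_voxel_state(t = t, beta_hat = beta, rss = rss,
                  df = t - ncol(X), estimable = TRUE)
}

new_voxel_state <- function(t, beta_hat, rss, df, estimable,
                            acc = NULL) {
  structure(list(t = t, beta_hat = beta_hat, rss = rss,
                 sigma2_hat = if (t > 0) rss / t else NA_real_,
                 sigma2_unbiased = if (!is.null(df) && df > 0)
                   rss / df else NA_real_,
                 estimable = estimable, acc = acc),
            class = "voxel_state")
}

#' @export
print.voxel_state <- function(x, ...) {
  cat("voxel state at t = ", x$t,
      if (!x$estimable) " (below burn-in)", "\n", sep = "")
  if (x$estimable) {
    cat("  beta_hat: ", paste(signif(x$beta_hat, 5), collapse = " "),
        "\n  sigma2_hat (MLE): ", signif(x$sigma2_hat, 5), "\n", sep = "")
  }
  invisible(x)
}

check_design_rank <- function(xtx, labels = NULL) {
  ev <- eigen(xtx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10) {
    qrd <- qr(xtx)
    bad <- setdiff(seq_len(ncol(xtx)), qrd$pivot[seq_len(qrd$rank)])
    lab <- if (!is.null(labels)) paste(labels[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("singular design: offending columns ", lab)
  }
  invisible(TRUE)
}

# Burn-in rule: estimation (and SPRT evaluation) starts once
# t >= ncol(X) + 2 and every task column varies over the observed window,
# so that the design carries energy for every coefficient.
past_burn_in <- function(X, t) {
  k <- ncol(X)
  if (t < k + 2) return(FALSE)
  if (k > 1) {
    sub <- X[seq_len(t), -1, drop = FALSE]
    v <- apply(sub, 2, stats::var)
    if (any(v <= max(sub^2) * 1e-12)) return(FALSE)
  }
  TRUE
}

#' Streaming (per-volume) update of a voxel GLM fit
#'
#' Maintains the sufficient statistics of a GLS fit so that after each new
#' volume the returned state equals a fresh batch [gls_fit()] on all
#' volumes observed so far (to numerical tolerance). The whitened
#' cross-products `X'V^-1 X` and `X'V^-1 y` are accumulated causally; for
#' AR(1) covariances the update uses the exact innovation transform, so no
#' matrix of order `t` is ever formed.
#'
#' @param state A `voxel_state` from a previous update, or `NULL` to start
#'   a stream.
#' @param X Design matrix holding at least the first `t + 1` rows.
#' @param y_new Observed BOLD value of the new volume.
#' @param cov A [temporal_covariance()].
#' @return Updated `voxel_state`. Before burn-in (fewer than `P + 3`
#'   volumes, or a task regressor still constant) the state is flagged
#'   `estimable = FALSE` and carries no estimates.
#' @examples
#' X <- cbind(1, stats::rnorm(20))
#' s <- NULL
#' y <- stats::rnorm(20)
#' for (t in 1:20) s <- update_voxel_state(s, X[1:t, , drop = FALSE], y[t])
#' all.equal(s$beta_hat, gls_fit(X, y)$beta_hat, check.attributes = FALSE)
#' @export
update_voxel_state <- function(state, X, y_new,
                               cov = temporal_covariance("identity")) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (is.null(state)) {
    acc <- list(xtx = matrix(0, k, k), xty = numeric(k), yty = 0,
                prev_x = NULL, prev_y = NULL)
    t <- 0L
  } else {
    acc <- state$acc
    t <- state$t
  }
  if (nrow(X) < t + 1)
    stop("'X' must be extended to at least t + 1 rows")
  x_new <- X[t + 1L, ]
  if (cov$kind == "ar1" && t >= 1L) {
    s <- sqrt(1 - cov$rho^2)
    xw <- (x_new - cov$rho * acc$prev_x) / s
    yw <- (y_new - cov$rho * acc$prev_y) / s
  } else {
    xw <- x_new
    yw <- y_new
  }
  acc$xtx <- acc$xtx + tcrossprod(xw)
  acc$xty <- acc$xty + xw * yw
  acc$yty <- acc$yty + yw^2
  acc$prev_x <- x_new
  acc$prev_y <- y_new
  t <- t + 1L
  if (!past_burn_in(X, t))
    return(new_voxel_state(t, beta_hat = NULL, rss = NA_real_, df = NULL,
                           estimable = FALSE, acc = acc))
  beta <- drop(solve(acc$xtx, acc$xty))
  names(beta) <- colnames(X)
  rss <- max(acc$yty - sum(beta * acc$xty), 0)
  new_voxel_state(t, beta_hat = beta, rss = rss, df = t - k,
                  estimable = TRUE, acc = acc)
}

#' Variance of a contrast estimate
#'
#' Returns `Var(c B_hat) = sigma2_hat * c' (X' V^-1 X)^-1 c`, the plug-in
#' variance used inside the sequential likelihood ratios.
#'
#' @param c Contrast vector of length `ncol(X)`.
#' @param X Design matrix.
#' @param cov A [temporal_covariance()].
#' @param sigma2_hat Error-variance estimate (>= 0).
#' @return The contrast variance (scalar).
#' @export
contrast_variance <- function(c, X, cov = temporal_covariance("identity"),
                              sigma2_hat = 1) {
  X <- as.matrix(X)
  if (length(c) != ncol(X))
    stop("length(c) must equal ncol(X)")
  if (sigma2_hat < 0) stop("'sigma2_hat' must be >= 0")
  xtx <- crossprod(whiten(X, cov))
  check_design_rank(xtx, colnames(X))
  drop(sigma2_hat * crossprod(c, solve(xtx, c)))
}

#' Signal-to-noise ratio of a task effect
#'
#' SNR is the task regression coefficient divided by the within-voxel
#' error standard deviation.
#'
#' @param beta Task amplitude (regression coefficient).
#' @param sigma Error standard deviation (> 0).
#' @return `beta / sigma`.
#' @export
snr <- function(beta, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  beta / sigma
}
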