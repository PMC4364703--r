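#' Temporal covariance model
#'
#' Describes the within-voxel temporal correlation of the GLM errors,
#' either white (`identity`) or first-order autoregressive (`ar1`) with
#' known coefficient `rho`, for which entry (i, j) of the implied
#' correlation matrix is `rho^|i-j|`.
#'
#' The AR(1) structure admits an exact causal whitening transform
#' (`z_1 = y_1`, `z_t = (y_t - rho * y_{t-1}) / sqrt(1 - rho^2)`), which is
#' how all generalized least squares computations are carried out; the
#' full correlation matrix is only materialized on request.
#'
#' @param kind `"identity"` or `"ar1"`.
#' @param rho AR(1) coefficient in (-1, 1); ignored for `identity`.
#' @return An object of class `temporal_cov`.
#' @export
temporal_covariance <- function(kind = c("identity", "ar1"), rho = 0) {
  kind <- match.arg(kind)
  if (kind == "ar1") {
    if (!is.numeric(rho) || abs(rho) >= 1)
      stop("'rho' must lie in (-1, 1)")
  } else rho <- 0
  structure(list(kind = kind, rho = rho), class = "temporal_cov")
}

#' @rdname temporal_covariance
#' @param cov A `temporal_cov`.
#' @param t Number of time points.
#' @return `cov_matrix()` returns the t x t correlation matrix `V_t`.
#' @export
cov_matrix <- function(cov, t) {
  stopifnot(inherits(cov, "temporal_cov"))
  if (cov$kind == "identity") return(diag(t))
  cov$rho^abs(outer(seq_len(t), seq_len(t), "-"))
}

# Causal whitening of the rows of a matrix (time on rows) under an AR(1)
# correlation; identity passes through. Whitened GLS == OLS.
whiten <- function(m, cov) {
  if (cov$kind == "identity") return(m)
  m <- as.matrix(m)
  rho <- cov$rho
  t <- nrow(m)
  if (t == 1L) return(m)
  out <- m
  out[2:t, ] <- (m[2:t, , drop = FALSE] -
                   rho * m[1:(t - 1), , drop = FALSE]) / sqrt(1 - rho^2)
  out
}

#' Build a GLM design matrix from a paradigm
#'
#' Each condition's regressor is the discrete convolution of its boxcar
#' indicator -- sampled on the TR grid as the fraction of each acquisition
#' interval covered by the condition's events -- with the HRF kernel,
#' truncated to the scan length. A leading intercept column of ones is
#' prepended. Task columns are ordered by first occurrence in the event
#' table.
#'
#' @param paradigm A [paradigm].
#' @param hrf HRF kernel sampled at the paradigm's TR, e.g.
#'   [double_gamma_hrf()].
#' @return A numeric matrix of size `n_volumes x (P + 1)` with
#'   `colnames` `c("intercept", <conditions>)`, of class `design_matrix`.
#' @examples
#' p <- make_block_paradigm(c("A", "B"), 4, 20, tr = 2, n_volumes = 360)
#' X <- build_design_matrix(p, double_gamma_hrf(tr = 2))
#' dim(X)  # 360 x 3
#' @export
build_design_matrix <- function(paradigm, hrf) {
  stopifnot(inherits(paradigm, "paradigm"))
  if (!is.numeric(hrf) || length(hrf) == 0)
    stop("'hrf' must be a nonempty numeric vector")
  n <- paradigm$n_volumes
  tr <- paradigm$tr
  ev <- paradigm$events
  conds <- unique(ev$condition[order(ev$onset)])
  X <- matrix(1, nrow = n, ncol = 1L + length(conds))
  colnames(X) <- c("intercept", conds)
  vol_start <- (seq_len(n) - 1L) * tr
  for (j in seq_along(conds)) {
    rows <- ev[ev$condition == conds[j], , drop = FALSE]
    u <- numeric(n)
    for (k in seq_len(nrow(rows))) {
      # fraction of each TR interval [start, start + tr) covered
      overlap <- pmin(vol_start + tr, rows$onset[k] + rows$duration[k]) -
        pmax(vol_start, rows$onset[k])
      u <- u + pmax(overlap, 0) / tr
    }
    # direct causal convolution (exact zeros before the first event)
    r <- numeric(n)
    for (k in seq_along(hrf)) {
      idx <- seq_len(n - k + 1L)
      if (length(idx)) r[idx + k - 1L] <- r[idx + k - 1L] + hrf[k] * u[idx]
    }
    X[, j + 1L] <- r
  }
  class(X) <- c("design_matrix", class(X))
  X
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design matrix: ", nrow(x), " volumes x ", ncol(x),
      " columns (", paste(colnames(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write a design matrix to TSV
#'
#' @param X A design matrix.
#' @param path Output path.
#' @export
write_design_matrix <- function(X, path) {
  utils::write.table(as.data.frame(unclass(X)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
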