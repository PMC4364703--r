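#' Spatial Gaussian smoothing with edge renormalization
#'
#' Convolves an image with a truncated Gaussian kernel
#' (`sigma = fwhm / 2.3548`) supported on `kernel_extent` voxels per
#' dimension. Weights are renormalized to sum to one everywhere,
#' including at image edges, so a constant image is left unchanged. The
#' kernel is separable and the normalized convolution is applied
#' dimension by dimension; 2-D and 3-D images are supported.
#'
#' @param volume Numeric matrix or 3-D array (one volume).
#' @param fwhm Full width at half maximum of the Gaussian, in voxels.
#' @param kernel_extent Odd kernel support per dimension (default 3).
#' @return Smoothed image of the same dimensions.
#' @examples
#' img <- matrix(rnorm(48 * 48), 48, 48)
#' sm <- gaussian_smooth(img, fwhm = 6)
#' @export
gaussian_smooth <- function(volume, fwhm = 6, kernel_extent = 3) {
  if (fwhm <= 0) stop("'fwhm' must be > 0")
  if (kernel_extent %% 2 != 1) stop("'kernel_extent' must be odd")
  w <- gaussian_kernel_1d(fwhm, kernel_extent)
  d <- dim(volume)
  if (is.null(d)) stop("'volume' must be a matrix or array")
  out <- volume
  for (dd in seq_along(d)) out <- normalized_conv_dim(out, dd, w)
  out
}

gaussian_kernel_1d <- function(fwhm, extent) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  h <- (extent - 1) / 2
  w <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  w / sum(w)
}

# Normalized 1-D convolution along dimension `dd` of an array: the kernel
# is renormalized over the in-image support, so edges keep unit gain.
normalized_conv_dim <- function(arr, dd, w) {
  d <- dim(arr)
  n <- d[dd]
  h <- (length(w) - 1) / 2
  # move target dim first, flatten the rest
  perm <- c(dd, setdiff(seq_along(d), dd))
  m <- matrix(aperm(arr, perm), nrow = n)
  num <- matrix(0, nrow = n, ncol = ncol(m))
  den <- numeric(n)
  for (j in seq(-h, h)) {
    src <- seq_len(n) + j
    ok <- src >= 1 & src <= n
    wj <- w[j + h + 1]
    num[ok, ] <- num[ok, ] + wj * m[src[ok], , drop = FALSE]
    den[ok] <- den[ok] + wj
  }
  out <- num / den
  aperm(array(out, d[perm]), order(perm))
}

#' Causal running-baseline drift correction
#'
#' Maintains an exponentially weighted per-voxel baseline,
#' `baseline_t = (1 - lambda) baseline_{t-1} + lambda volume_t` (with
#' `baseline_1 = volume_1`), and returns
#' `volume_t - baseline_t + grand_baseline`, where the grand baseline is
#' the first volume. This removes slow scanner drift while preserving the
#' signal scale, and is strictly causal: the output at volume `t` depends
#' only on volumes `1..t`.
#'
#' @param state A `drift_state` returned by a previous call, or `NULL` at
#'   the first volume.
#' @param volume Numeric matrix/array (one volume).
#' @param t Volume index (must arrive in order: 1, 2, ...).
#' @param lambda Baseline smoothing factor in (0, 1] (default 0.1).
#' @return A list with `volume` (corrected image) and `state` (updated
#'   `drift_state` to pass to the next call).
#' @export
drift_correct <- function(state, volume, t, lambda = 0.1) {
  if (lambda <= 0 || lambda > 1) stop("'lambda' must lie in (0, 1]")
  if (is.null(state)) {
    if (t != 1L) stop("volumes must arrive in order starting at t = 1")
    state <- structure(list(baseline = volume, grand = volume, t = 1L,
                            lambda = lambda),
                       class = "drift_state")
    return(list(volume = volume, state = state))
  }
  stopifnot(inherits(state, "drift_state"))
  if (t != state$t + 1L)
    stop("out-of-order volume: expected t = ", state$t + 1L,
         ", got ", t)
  lambda <- state$lambda
  state$baseline <- (1 - lambda) * state$baseline + lambda * volume
  state$t <- t
  list(volume = volume - state$baseline + state$grand, state = state)
}
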