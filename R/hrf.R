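#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical double-gamma HRF on the acquisition grid. The
#' kernel is the difference of two gamma densities -- a positive response
#' peaking around 5--6 s and a late undershoot around 15--16 s -- and is
#' rescaled to unit peak so that a regression coefficient is expressed in
#' units of the peak response to a sustained stimulus sample.
#'
#' @param tr Sampling interval (repetition time) in seconds.
#' @param length Support of the kernel in seconds (default 32).
#' @param peak_delay Delay of the positive response peak, seconds.
#' @param undershoot_delay Delay of the undershoot peak, seconds.
#' @param peak_disp,undershoot_disp Dispersions (gamma scale), seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector of `floor(length / tr)` samples at times
#'   `0, tr, 2 tr, ...`, scaled so `max(hrf) == 1`.
#' @examples
#' h <- double_gamma_hrf(tr = 2)
#' which.max(h)   # peak near 6 s
#' @export
double_gamma_hrf <- function(tr, length = 32,
                             peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             ratio = 1 / 6) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a positive number")
  if (!is.numeric(length) || length <= 0)
    stop("'length' must be a positive number")
  t <- seq(0, length - tr / 2, by = tr)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                          scale = undershoot_disp)
  h / max(h)
}
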