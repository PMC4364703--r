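#' Replay a dataset volume by volume
#'
#' Wraps a 3-D array (rows x cols x volumes), a `sim_dataset`, or a plain
#' time-series vector as an ordered volume iterator, emulating real-time
#' acquisition: the consumer never observes volume `t + 1` before
#' deciding on volume `t`.
#'
#' @param data Array with time as the last dimension, a `sim_dataset`, or
#'   a numeric vector (single-series ROI data).
#' @param delay Optional wall-clock delay per volume in seconds (demo
#'   mode).
#' @return A function that returns the next volume (matrix) on each call
#'   and `NULL` once exhausted.
#' @export
stream_volumes <- function(data, delay = 0) {
  if (inherits(data, "sim_dataset")) data <- data$data
  if (is.null(dim(data))) data <- array(data, c(1, 1, length(data)))
  d <- dim(data)
  nt <- d[length(d)]
  flat <- matrix(data, ncol = nt)
  shape <- d[-length(d)]
  i <- 0L
  function() {
    if (i >= nt) return(NULL)
    i <<- i + 1L
    if (delay > 0) Sys.sleep(delay)
    array(flat[, i], shape)
  }
}

#' Run the voxel-wise sequential probability ratio test
#'
#' The real-time loop: per incoming volume, preprocess (spatial smoothing
#' then drift correction), update every in-mask voxel's streaming GLS
#' fit, recompute each hypothesis' log likelihood ratio from the current
#' full-data estimates, apply the truncated SPRT decision rule, and check
#' the global stopping rule. At the stop, every voxel is classified for
#' every hypothesis: voxels whose test crossed a boundary keep that
#' verdict; the rest are classified by the sign of their final statistic.
#'
#' A voxel counts as decided for the global rule only when all of its
#' hypotheses have non-continue verdicts. Voxels that never pass burn-in
#' are classified `H0` and flagged; they count as undecided.
#'
#' @param data A 3-D array (rows x cols x volumes), `sim_dataset`,
#'   numeric vector (single ROI series), or a volume stream from
#'   [stream_volumes()] (in which case `n_volumes` must be supplied).
#' @param paradigm The run's [paradigm].
#' @param hypotheses A single [hypothesis()] or a list of them, all
#'   sharing the paradigm's design matrix.
#' @param mask Logical matrix of in-mask voxels; default all.
#' @param bounds [compute_boundaries()] output. Default: alpha 0.01,
#'   beta 0.1, Bonferroni `N = mask voxels x hypotheses`, truncation at
#'   the planned scan length.
#' @param g_percent Global stopping percentage `G` in (0, 100].
#' @param cov Temporal covariance assumed in estimation (default
#'   identity).
#' @param hrf HRF kernel (default canonical double gamma).
#' @param smooth,fwhm,kernel_extent Spatial smoothing toggle and kernel.
#' @param drift,drift_lambda Drift-correction toggle and factor.
#' @param keep_lambda Keep per-volume statistic trajectories
#'   (voxels x volumes x hypotheses; memory heavy).
#' @param verbose Emit per-volume progress messages.
#' @param n_volumes Planned scan length; required when `data` is a bare
#'   stream function.
#' @return Object of class `sprt_run`: list with `stop_volume`,
#'   `verdicts` (voxels x hypotheses), `lambda` (final statistics),
#'   `decided_t`, `classification` (per-hypothesis `"H0"`/`"Ha"`),
#'   `class_map` (integer image: bit `h` set when hypothesis `h`
#'   accepted `Ha`; 0/1/2/3 for two hypotheses), `estimable`, `bounds`,
#'   `g_percent`, `mask`, and `hypotheses`.
#' @export
run_sequential <- function(data, paradigm, hypotheses, mask = NULL,
                           bounds = NULL, g_percent = 100,
                           cov = temporal_covariance("identity"),
                           hrf = NULL,
                           smooth = TRUE, fwhm = 6, kernel_extent = 3,
                           drift = TRUE, drift_lambda = 0.1,
                           keep_lambda = FALSE, verbose = FALSE,
                           n_volumes = NULL) {
  if (inherits(hypotheses, "sprt_hypothesis")) hypotheses <- list(hypotheses)
  stopifnot(length(hypotheses) >= 1,
            all(vapply(hypotheses, inherits, TRUE, "sprt_hypothesis")))
  if (is.function(data)) {
    stream <- data
    if (is.null(n_volumes)) stop("'n_volumes' is required for a stream")
  } else {
    stream <- stream_volumes(data)
    if (inherits(data, "sim_dataset")) data <- data$data
    if (is.null(dim(data))) n_volumes <- length(data)
    else n_volumes <- dim(data)[length(dim(data))]
  }
  stopifnot(inherits(paradigm, "paradigm"))
  if (paradigm$n_volumes < n_volumes)
    stop("paradigm covers fewer volumes than the data stream")
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = paradigm$tr)
  X <- build_design_matrix(paradigm, hrf)
  k <- ncol(X)
  H <- length(hypotheses)
  cmat <- vapply(hypotheses, `[[`, numeric(k), "c")  # k x H
  hyp_labels <- vapply(hypotheses, `[[`, character(1), "label")
  if (anyDuplicated(hyp_labels))
    hyp_labels <- make.unique(hyp_labels)

  first <- stream()
  if (is.null(first)) stop("empty volume stream")
  shape <- dim(first)
  if (is.null(shape)) shape <- c(length(first), 1L)
  if (is.null(mask)) mask <- array(TRUE, shape)
  if (!all(dim(mask) == shape))
    stop("geometry mismatch: mask is ", paste(dim(mask), collapse = "x"),
         ", data volumes are ", paste(shape, collapse = "x"))
  midx <- which(mask)
  nvox <- length(midx)
  if (nvox == 0) stop("empty mask")
  if (is.null(bounds))
    bounds <- compute_boundaries(0.01, 0.1, n_tests = nvox * H,
                                 truncation = n_volumes)
  trunc_T <- min(bounds$truncation, n_volumes)
  if (bounds$truncation > n_volumes)
    warning("stream shorter than the truncation bound; ",
            "truncating at volume ", n_volumes)

  # streaming accumulators shared across voxels
  xtx <- matrix(0, k, k)
  xty <- matrix(0, k, nvox)
  yty <- numeric(nvox)
  prev_x <- NULL
  prev_y <- NULL
  dstate <- NULL

  verdicts <- matrix("continue", nvox, H,
                     dimnames = list(NULL, hyp_labels))
  lambda <- matrix(NA_real_, nvox, H, dimnames = list(NULL, hyp_labels))
  decided_t <- matrix(NA_integer_, nvox, H)
  traj <- if (keep_lambda)
    array(NA_real_, c(nvox, trunc_T, H)) else NULL
  estimable <- FALSE
  stop_volume <- trunc_T
  t <- 0L
  vol <- first

  while (!is.null(vol) && t < trunc_T) {
    t <- t + 1L
    if (smooth) vol <- gaussian_smooth(vol, fwhm, kernel_extent)
    if (drift) {
      dc <- drift_correct(dstate, vol, t, drift_lambda)
      vol <- dc$volume
      dstate <- dc$state
    }
    y <- as.numeric(vol)[midx]
    x_new <- X[t, ]
    if (cov$kind == "ar1" && t > 1L) {
      s <- sqrt(1 - cov$rho^2)
      xw <- (x_new - cov$rho * prev_x) / s
      yw <- (y - cov$rho * prev_y) / s
    } else {
      xw <- x_new
      yw <- y
    }
    xtx <- xtx + tcrossprod(xw)
    xty <- xty + outer(xw, yw)
    yty <- yty + yw^2
    prev_x <- x_new
    prev_y <- y

    # stream exhausted before the truncation bound: apply the
    # truncation decision rule at this last volume
    nxt <- stream()
    last <- is.null(nxt) && t < trunc_T
    if (last) {
      warning("volume stream exhausted at t = ", t,
              " before truncation T = ", trunc_T,
              "; applying the truncation rule here")
      trunc_T <- t
    }

    estimable <- past_burn_in(X, t)
    if (estimable) {
      # an ill-conditioned early window counts as below burn-in
      xtx_inv <- tryCatch(solve(xtx), error = function(e) NULL)
      if (is.null(xtx_inv) || !all(is.finite(xtx_inv)))
        estimable <- FALSE
    }
    if (estimable) {
      beta <- xtx_inv %*% xty                      # k x nvox
      sigma2 <- pmax(yty - colSums(beta * xty), 0) / t
      for (h in seq_len(H)) {
        hyp <- hypotheses[[h]]
        cb <- drop(crossprod(cmat[, h], beta))
        varc <- sigma2 * drop(crossprod(cmat[, h],
                                        xtx_inv %*% cmat[, h]))
        lam <- sprt_lambda(hyp, cb, varc)
        if (keep_lambda) traj[, t, h] <- lam
        open <- verdicts[, h] == "continue"
        lambda[open, h] <- lam[open]
        v <- decide(lam[open], bounds_at(bounds, trunc_T), t)
        newly <- v != "continue"
        verdicts[which(open)[newly], h] <- v[newly]
        decided_t[which(open)[newly], h] <- t
      }
    }
    decided_frac <- sum(rowSums(verdicts == "continue") == 0) / nvox
    if (verbose)
      message(sprintf("volume %d: %.1f%% voxels decided", t,
                      100 * decided_frac))
    if (100 * decided_frac >= g_percent) {
      stop_volume <- t
      break
    }
    stop_volume <- t
    vol <- nxt
  }
  if (t < max(ncol(X) + 2, 1))
    stop("stream ended before the burn-in period (t = ", t, ")")

  classification <- matrix(final_classify(lambda), nvox, H,
                           dimnames = list(NULL, hyp_labels))
  crossed <- verdicts != "continue"
  classification[crossed] <-
    ifelse(verdicts[crossed] == "accept_Ha", "Ha", "H0")
  never_estimable <- rowSums(!is.na(lambda)) == 0

  code <- integer(nvox)
  for (h in seq_len(H))
    code <- code + as.integer(classification[, h] == "Ha") * 2L^(h - 1L)
  class_map <- array(NA_integer_, shape)
  class_map[midx] <- code

  structure(list(stop_volume = stop_volume, verdicts = verdicts,
                 lambda = lambda, decided_t = decided_t,
                 classification = classification, class_map = class_map,
                 estimable = !never_estimable, bounds = bounds,
                 g_percent = g_percent, mask = mask, mask_index = midx,
                 hypotheses = hypotheses, truncation = trunc_T),
            class = "sprt_run")
}

# Evaluate a hypothesis' statistic, including the zero-variance limit
# (noiseless data): the likelihood ratio degenerates to +/-Inf according
# to which hypothesized value the estimate is closer to.
sprt_lambda <- function(hyp, cb, varc) {
  zero <- !is.na(varc) & varc == 0
  lam <- if (hyp$sidedness == "one")
    lambda_one_sided(cb, varc, hyp$theta0, hyp$theta1)
  else
    lambda_two_sided(cb, varc, hyp$theta0, hyp$delta)
  if (any(zero)) {
    s <- if (hyp$sidedness == "one")
      (cb[zero] - hyp$theta0)^2 - (cb[zero] - hyp$theta1)^2
    else
      (cb[zero] - hyp$theta0)^2 -
        pmin((cb[zero] - hyp$theta0 - hyp$delta)^2,
             (cb[zero] - hyp$theta0 + hyp$delta)^2)
    lam[zero] <- sign(s) * Inf
  }
  lam
}

# boundaries with the effective truncation of this run
bounds_at <- function(bounds, trunc_T) {
  bounds$truncation <- trunc_T
  bounds
}

#' @export
print.sprt_run <- function(x, ...) {
  nvox <- nrow(x$verdicts)
  decided <- sum(rowSums(x$verdicts == "continue") == 0)
  cat("voxel-wise SPRT run: stopped at volume ", x$stop_volume,
      " (G = ", x$g_percent, "%)\n", sep = "")
  cat("  ", decided, " of ", nvox, " voxels decided at boundaries (",
      sprintf("%.1f%%", 100 * decided / nvox), ")\n", sep = "")
  tab <- table(factor(x$class_map[x$mask_index]))
  cat("  classification codes: ",
      paste(names(tab), tab, sep = ":", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Per-voxel statistics table of a sequential run
#'
#' @param run An `sprt_run`.
#' @return Data frame with one row per (in-mask voxel, hypothesis):
#'   0-based voxel index, hypothesis label, final statistic, verdict,
#'   decision volume and classification.
#' @export
run_stats_table <- function(run) {
  stopifnot(inherits(run, "sprt_run"))
  H <- ncol(run$verdicts)
  nvox <- nrow(run$verdicts)
  do.call(rbind, lapply(seq_len(H), function(h) {
    data.frame(voxel = run$mask_index - 1L,
               hypothesis = colnames(run$verdicts)[h],
               lambda = run$lambda[, h],
               verdict = run$verdicts[, h],
               decided_volume = run$decided_t[, h],
               classification = run$classification[, h])
  }))
}
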