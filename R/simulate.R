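#' Lattice disk of voxels
#'
#' All voxels whose Euclidean distance from `center` is at most `radius`,
#' clipped to the image. Radii 11 and 6 give 377 and 113 voxels, the two
#' activation-region sizes used by the simulation presets.
#'
#' @param center Integer vector `(row, col)`.
#' @param radius Disk radius in voxels (>= 0).
#' @param shape Image dimensions `(rows, cols)`; default 48 x 48.
#' @return Two-column integer matrix of `(row, col)` voxel coordinates.
#' @examples
#' nrow(disk_region(c(24, 24), 11))  # 377
#' @export
disk_region <- function(center, radius, shape = c(48, 48)) {
  if (radius < 0) stop("'radius' must be >= 0")
  if (center[1] < 1 || center[1] > shape[1] ||
      center[2] < 1 || center[2] > shape[2])
    stop("'center' lies outside the image")
  r <- ceiling(radius)
  rows <- max(1, center[1] - r):min(shape[1], center[1] + r)
  cols <- max(1, center[2] - r):min(shape[2], center[2] + r)
  g <- expand.grid(row = rows, col = cols)
  d2 <- (g$row - center[1])^2 + (g$col - center[2])^2
  as.matrix(g[d2 <= radius^2 + 1e-9, , drop = FALSE])
}

#' Activation region specification
#'
#' A disk-shaped activation region whose amplitude decays exponentially
#' from the peak at the center: at lattice distance `d` the amplitude is
#' `peak_amplitude * exp(-decay_rate * d)`.
#'
#' @param center `(row, col)` center voxel.
#' @param radius Disk radius in voxels.
#' @param peak_amplitude Peak task amplitude (b-value) at the center.
#' @param tasks Character vector of task labels activated by the region
#'   (subset of the paradigm's conditions, e.g. `"A"`, `c("A", "B")`).
#' @param decay_rate Exponential decay per voxel of distance. The default
#'   calibrates the high-amplitude core (amplitude >= 0.8 of peak) to
#'   lattice distance `sqrt(12)` for radius-11 disks (37 voxels) and
#'   `sqrt(2)` for radius-6 disks (9 voxels).
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(center, radius, peak_amplitude = 1,
                        tasks = "A", decay_rate = NULL) {
  if (radius < 0 || peak_amplitude < 0)
    stop("'radius' and 'peak_amplitude' must be >= 0")
  if (is.null(decay_rate)) {
    core <- if (radius >= 11) sqrt(12) else sqrt(2)
    decay_rate <- -log(0.8) / core
  }
  structure(list(center = center, radius = radius,
                 peak_amplitude = peak_amplitude, tasks = tasks,
                 decay_rate = decay_rate),
            class = "region_spec")
}

#' Ground-truth activation map
#'
#' Builds per-task amplitude images and a region-label image from a list
#' of non-overlapping [region_spec()]s.
#'
#' @param shape Image dimensions `(rows, cols)`.
#' @param regions List of [region_spec()].
#' @return Object of class `ground_truth`: list with `amplitude` (named
#'   list of task amplitude matrices), `labels` (integer matrix, 0 =
#'   outside all regions, i = region i), `regions` and `shape`.
#' @export
make_activation_map <- function(shape, regions) {
  labels <- matrix(0L, shape[1], shape[2])
  tasks <- unique(unlist(lapply(regions, `[[`, "tasks")))
  amplitude <- stats::setNames(
    replicate(length(tasks), matrix(0, shape[1], shape[2]),
              simplify = FALSE), tasks)
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    vox <- disk_region(rg$center, rg$radius, shape)
    if (any(labels[vox] != 0L))
      stop("activation regions overlap; the layout assumes disjoint disks")
    labels[vox] <- i
    d <- sqrt((vox[, 1] - rg$center[1])^2 + (vox[, 2] - rg$center[2])^2)
    amp <- rg$peak_amplitude * exp(-rg$decay_rate * d)
    for (task in rg$tasks) amplitude[[task]][vox] <- amp
  }
  structure(list(amplitude = amplitude, labels = labels,
                 regions = regions, shape = shape),
            class = "ground_truth")
}

#' The three-region activation layout of the simulation presets
#'
#' A 48 x 48 slice with three disk regions: region 1 (radius 11, 377
#' voxels, task A only), region 2 (radius 6, 113 voxels, task B only) and
#' region 3 (radius 11, 377 voxels, both tasks), all decaying
#' exponentially from `peak_b` at the center. The remaining 1437 voxels
#' are inactive.
#'
#' @param peak_b Peak amplitude of every region (1 for maximum SNR 0.1 at
#'   sigma 10, 3 for maximum SNR 0.3).
#' @return A `ground_truth`.
#' @export
preset_activation_map <- function(peak_b = 1) {
  make_activation_map(c(48, 48), list(
    region_spec(c(13, 13), 11, peak_b, "A"),
    region_spec(c(13, 36), 6, peak_b, "B"),
    region_spec(c(36, 25), 11, peak_b, c("A", "B"))))
}

#' Multi-component fMRI noise specification
#'
#' The noise model mixes five standardized components: white Gaussian
#' noise, low-frequency drift from a discrete-cosine basis, physiological
#' sinusoids (cardiac and respiratory, random phase per voxel), AR(1)
#' temporally correlated noise, and a spatially AR(1)-correlated field
#' (temporally white). Components are weighted and the sum is scaled so
#' the per-voxel standard deviation equals `sigma`.
#'
#' @param sigma Target per-voxel error standard deviation.
#' @param weights Named nonnegative weights summing to 1 over
#'   `c("white", "drift", "physio", "temporal", "spatial")`.
#' @param rho_temporal AR(1) coefficient of the temporal component.
#' @param rho_spatial AR(1) coefficient of the spatial component.
#' @param cardiac_hz,respiratory_hz Physiological frequencies in Hz.
#' @param drift_cutoff_s Longest drift period retained, seconds; the
#'   cosine basis holds all frequencies below `1/drift_cutoff_s`.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 10,
                       weights = c(white = 0.2, drift = 0.2,
                                   physio = 0.2, temporal = 0.2,
                                   spatial = 0.2),
                       rho_temporal = 0.3, rho_spatial = 0.7,
                       cardiac_hz = 1.17, respiratory_hz = 0.2,
                       drift_cutoff_s = 128) {
  comp <- c("white", "drift", "physio", "temporal", "spatial")
  if (!all(comp %in% names(weights)))
    stop("'weights' must be named over: ", paste(comp, collapse = ", "))
  weights <- weights[comp]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be nonnegative and sum to 1")
  if (rho_temporal < 0 || rho_temporal >= 1 ||
      rho_spatial < 0 || rho_spatial >= 1)
    stop("AR(1) coefficients must lie in [0, 1)")
  structure(list(sigma = sigma, weights = weights,
                 rho_temporal = rho_temporal, rho_spatial = rho_spatial,
                 cardiac_hz = cardiac_hz, respiratory_hz = respiratory_hz,
                 drift_cutoff_s = drift_cutoff_s),
            class = "noise_spec")
}

#' Generate multi-component fMRI noise
#'
#' @param shape Spatial dimensions `(rows, cols)`.
#' @param n_volumes Number of volumes.
#' @param spec A [noise_spec()].
#' @param tr Repetition time, seconds.
#' @param seed Optional integer; when supplied the generator is
#'   deterministic and leaves the caller's RNG state untouched.
#' @return Array `(rows, cols, n_volumes)` with per-voxel SD `spec$sigma`.
#' @export
generate_noise <- function(shape, n_volumes, spec = noise_spec(),
                           tr = 2, seed = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
    set.seed(seed)
  }
  nv <- prod(shape)
  t <- n_volumes
  w <- spec$weights
  total <- matrix(0, nv, t)

  if (w["white"] > 0)
    total <- total + w["white"] * matrix(stats::rnorm(nv * t), nv, t)

  if (w["drift"] > 0) {
    k <- max(1, floor(2 * t * tr / spec$drift_cutoff_s))
    grid <- (seq_len(t) - 0.5) / t
    basis <- sapply(seq_len(k), function(j) cos(pi * j * grid))
    basis <- scale(basis)  # unit temporal SD per basis function
    coef <- matrix(stats::rnorm(nv * k, sd = 1 / sqrt(k)), nv, k)
    total <- total + w["drift"] * tcrossprod(coef, basis)
  }

  if (w["physio"] > 0) {
    tt <- (seq_len(t) - 1) * tr
    ph1 <- stats::runif(nv, 0, 2 * pi)
    ph2 <- stats::runif(nv, 0, 2 * pi)
    physio <- sin(outer(ph1, 2 * pi * spec$cardiac_hz * tt, "+")) +
      sin(outer(ph2, 2 * pi * spec$respiratory_hz * tt, "+"))
    total <- total + w["physio"] * physio
  }

  if (w["temporal"] > 0) {
    rho <- spec$rho_temporal
    ar <- matrix(0, nv, t)
    ar[, 1] <- stats::rnorm(nv)
    if (t > 1) {
      innov_sd <- sqrt(1 - rho^2)
      for (i in 2:t)
        ar[, i] <- rho * ar[, i - 1] + stats::rnorm(nv, sd = innov_sd)
    }
    total <- total + w["temporal"] * ar
  }

  if (w["spatial"] > 0) {
    rho <- spec$rho_spatial
    field <- array(stats::rnorm(nv * t), c(shape, t))
    s <- sqrt(1 - rho^2)
    if (shape[1] > 1)
      for (i in 2:shape[1])
        field[i, , ] <- rho * field[i - 1, , ] + s * field[i, , ]
    if (shape[2] > 1)
      for (j in 2:shape[2])
        field[, j, ] <- rho * field[, j - 1, ] + s * field[, j, ]
    total <- total + w["spatial"] * matrix(field, nv, t)
  }

  total <- total * spec$sigma / sqrt(sum(w^2))
  array(total, c(shape, t))
}

#' Simulate a block-design fMRI dataset
#'
#' Forward model per voxel: `baseline + sum_p b_p x_p(t) + noise`, where
#' `x_p` are the HRF-convolved task regressors of the paradigm and `b_p`
#' the ground-truth amplitudes.
#'
#' @param truth A `ground_truth` from [make_activation_map()].
#' @param paradigm A [paradigm] whose conditions match the truth's tasks.
#' @param hrf HRF kernel (default canonical double gamma at the
#'   paradigm's TR).
#' @param noise A [noise_spec()], or `NULL` for noiseless data.
#' @param baseline Constant signal baseline (default 100).
#' @param seed Optional integer seed passed to [generate_noise()].
#' @return List of class `sim_dataset`: `data` (rows x cols x volumes
#'   array), `truth` (with a per-task `snr` image attached when noise is
#'   present), `paradigm`, `design` (the design matrix).
#' @export
simulate_dataset <- function(truth, paradigm, hrf = NULL, noise = NULL,
                             baseline = 100, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(paradigm, "paradigm"))
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = paradigm$tr)
  X <- build_design_matrix(paradigm, hrf)
  shape <- truth$shape
  t <- paradigm$n_volumes
  data <- array(baseline, c(shape, t))
  flat <- matrix(data, prod(shape), t)
  for (task in names(truth$amplitude)) {
    if (!task %in% colnames(X))
      stop("truth task '", task, "' absent from the paradigm")
    flat <- flat + outer(as.vector(truth$amplitude[[task]]), X[, task])
  }
  if (!is.null(noise)) {
    flat <- flat + matrix(generate_noise(shape, t, noise,
                                         tr = paradigm$tr, seed = seed),
                          prod(shape), t)
    truth$snr <- lapply(truth$amplitude, function(a) a / noise$sigma)
  }
  structure(list(data = array(flat, c(shape, t)), truth = truth,
                 paradigm = paradigm, design = X),
            class = "sim_dataset")
}

#' Simulation preset: the two-task activation experiment
#'
#' Generates the full synthetic experiment: 48 x 48 slice, three disk
#' regions with exponential decay from `peak_b`, alternating 4 s task /
#' 20 s rest blocks of tasks A and B at TR 2, and the five-component
#' noise model (sigma 10, temporal AR(1) rho 0.3, spatial AR(1) rho 0.7).
#' `peak_b = 1` gives maximum SNR 0.1; `peak_b = 3` gives 0.3.
#'
#' @param peak_b Peak activation amplitude.
#' @param n_volumes Number of volumes (default 360).
#' @param sigma Noise standard deviation (default 10).
#' @param seed Optional integer seed.
#' @return A `sim_dataset`.
#' @export
simulate_experiment <- function(peak_b = 1, n_volumes = 360, sigma = 10,
                                seed = NULL) {
  truth <- preset_activation_map(peak_b)
  par <- make_block_paradigm(c("A", "B"), task_s = 4, rest_s = 20,
                             tr = 2, n_volumes = n_volumes)
  simulate_dataset(truth, par, noise = noise_spec(sigma = sigma),
                   seed = seed)
}
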