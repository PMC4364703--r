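test_that("lattice disks reproduce the region voxel counts", {
  # brute-force lattice enumeration over the full plane (oracle)
  brute <- function(r) sum(outer((-20:20)^2, (-20:20)^2, "+") <= r^2)
  expect_equal(nrow(disk_region(c(24, 24), 11)), brute(11))
  expect_equal(nrow(disk_region(c(24, 24), 11)), 377)
  expect_equal(nrow(disk_region(c(24, 24), 6)), brute(6))
  expect_equal(nrow(disk_region(c(24, 24), 6)), 113)
  expect_equal(nrow(disk_region(c(24, 24), 0)), 1)
  # clipping at the image border
  expect_lt(nrow(disk_region(c(1, 1), 6)), 113)
  expect_error(disk_region(c(0, 5), 3), "outside")
})

test_that("region fractions of the 48 x 48 image match", {
  truth <- preset_activation_map(1)
  sizes <- table(truth$labels)
  expect_equal(round(100 * sizes[["1"]] / 2304, 2), 16.36)
  expect_equal(round(100 * sizes[["2"]] / 2304, 2), 4.90)
  expect_equal(round(100 * sizes[["3"]] / 2304, 2), 16.36)
  expect_equal(sizes[["0"]], 1437)
})

test_that("activation amplitudes decay from the peak and calibrate the core", {
  truth <- preset_activation_map(1)
  a <- truth$amplitude$A
  b <- truth$amplitude$B
  expect_equal(max(a), 1)
  expect_equal(a[13, 13], 1)          # region-1 center
  expect_equal(b[13, 36], 1)          # region-2 center
  expect_equal(a[36, 25], 1)          # region 3 activates for both
  expect_equal(b[36, 25], 1)
  expect_equal(a[1, 48], 0)           # outside all regions
  expect_equal(b[1, 48], 0)
  # high-amplitude cores: 37 / 9 / 37 voxels (brute-force count)
  expect_equal(sum(a[truth$labels == 1] >= 0.8), 37)
  expect_equal(sum(b[truth$labels == 2] >= 0.8), 9)
  expect_equal(sum(a[truth$labels == 3] >= 0.8 &
                     b[truth$labels == 3] >= 0.8), 37)
  # monotone decay with distance
  d <- sqrt(outer((1:48 - 13)^2, (1:48 - 13)^2 * 0, "+") +
              outer((1:48 - 13)^2 * 0, (1:48 - 13)^2, "+"))
  in1 <- truth$labels == 1
  expect_true(all(abs(a[in1] - exp(log(0.8) / sqrt(12) * d[in1])) < 1e-12))
})

test_that("overlapping regions are rejected", {
  expect_error(make_activation_map(c(48, 48), list(
    region_spec(c(20, 20), 8), region_spec(c(24, 24), 8))), "overlap")
})

test_that("noise components are calibrated and reproducible", {
  # all-white mixture hits the target SD
  spec_w <- noise_spec(sigma = 10, weights = c(white = 1, drift = 0,
                                               physio = 0, temporal = 0,
                                               spatial = 0))
  nz <- generate_noise(c(4, 4), 5000, spec_w, seed = 21)
  sds <- apply(matrix(nz, 16, 5000), 1, sd)
  expect_true(all(sds > 9 & sds < 11))
  # temporal component alone shows its AR(1) signature
  spec_t <- noise_spec(sigma = 1, weights = c(white = 0, drift = 0,
                                              physio = 0, temporal = 1,
                                              spatial = 0))
  nz <- generate_noise(c(2, 2), 5000, spec_t, seed = 22)
  l1 <- apply(matrix(nz, 4, 5000), 1, function(y)
    cor(y[-1], y[-length(y)]))
  expect_true(all(abs(l1 - 0.3) < 0.05))
  # spatial component: neighbours correlate at ~rho, variance stays unit
  spec_s <- noise_spec(sigma = 1, weights = c(white = 0, drift = 0,
                                              physio = 0, temporal = 0,
                                              spatial = 1))
  nz <- generate_noise(c(30, 30), 400, spec_s, seed = 23)
  mid <- nz[15, 15, ]
  expect_equal(cor(mid, nz[15, 16, ]), 0.7, tolerance = 0.1)
  expect_equal(cor(mid, nz[16, 15, ]), 0.7, tolerance = 0.1)
  expect_equal(sd(mid), 1, tolerance = 0.12)
  # the full mixture respects the target SD within 10%
  nz <- generate_noise(c(6, 6), 3000, noise_spec(sigma = 10), seed = 24)
  sds <- apply(matrix(nz, 36, 3000), 1, sd)
  expect_true(all(abs(sds - 10) / 10 < 0.1))
  # determinism
  n1 <- generate_noise(c(5, 5), 40, noise_spec(), seed = 9)
  n2 <- generate_noise(c(5, 5), 40, noise_spec(), seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1, generate_noise(c(5, 5), 40, noise_spec(),
                                            seed = 10)))
  expect_error(noise_spec(weights = c(white = 2, drift = 0, physio = 0,
                                      temporal = 0, spatial = 0)),
               "weights")
})

test_that("the forward model is exactly recoverable without noise", {
  truth <- preset_activation_map(1)
  par <- two_task_paradigm(120)
  ds <- simulate_dataset(truth, par, noise = NULL)
  expect_equal(dim(ds$data), c(48, 48, 120))
  # outside regions: flat baseline
  expect_true(all(ds$data[1, 48, ] == 100))
  # peak voxel of region 1: GLS recovers b exactly
  y <- ds$data[13, 13, ]
  fit <- gls_fit(ds$design, y)
  expect_equal(unname(fit$beta_hat), c(100, 1, 0), tolerance = 1e-8)
  # region 3 carries both tasks
  y3 <- ds$data[36, 25, ]
  fit3 <- gls_fit(ds$design, y3)
  expect_equal(unname(fit3$beta_hat), c(100, 1, 1), tolerance = 1e-8)
})

test_that("the preset experiment attains the configured maximum SNR", {
  ds <- simulate_experiment(peak_b = 1, n_volumes = 60, seed = 5)
  expect_equal(max(unlist(ds$truth$snr)), 0.1)
  ds3 <- simulate_experiment(peak_b = 3, n_volumes = 60, seed = 5)
  expect_equal(max(unlist(ds3$truth$snr)), 0.3)
  # seed determinism of the full dataset
  ds2 <- simulate_experiment(peak_b = 1, n_volumes = 60, seed = 5)
  expect_identical(ds$data, ds2$data)
})

test_that("peak b-value estimates are unbiased at SNR 0.3", {
  set.seed(41)
  truth <- preset_activation_map(3)
  par <- two_task_paradigm(360)
  peaks <- replicate(30, {
    ds <- simulate_dataset(truth, par, noise = noise_spec(sigma = 10),
                           seed = sample.int(1e6, 1))
    gls_fit(ds$design, ds$data[13, 13, ])$beta_hat[["A"]]
  })
  expect_lt(abs(mean(peaks) - 3), 3 * sd(peaks) / sqrt(30))
})
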