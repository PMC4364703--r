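test_that("volume streams replay data in order and stop on demand", {
  arr <- array(rnorm(4 * 4 * 10), c(4, 4, 10))
  s <- stream_volumes(arr)
  for (t in 1:10) expect_equal(s(), arr[, , t])
  expect_null(s())
  # a consumer stopping at t consumes exactly t volumes
  s2 <- stream_volumes(arr)
  for (t in 1:3) s2()
  expect_equal(s2(), arr[, , 4])
  # two replays give identical sequences
  sa <- stream_volumes(arr)
  sb <- stream_volumes(arr)
  for (t in 1:10) expect_identical(sa(), sb())
})

test_that("the engine matches a batch fit when forced to full length", {
  set.seed(51)
  truth <- preset_activation_map(1)
  par <- two_task_paradigm(80)
  ds <- simulate_dataset(truth, par, noise = noise_spec(sigma = 5),
                         seed = 52)
  hyp <- hypothesis(c(0, 1, 0), theta1 = 1, label = "A")
  b <- compute_boundaries(0.01, 0.1, truncation = 80)
  b$A <- Inf
  b$B <- -Inf   # never cross: run to truncation
  run <- run_sequential(ds, par, hyp, bounds = b, g_percent = 100,
                        smooth = FALSE, drift = FALSE)
  expect_equal(run$stop_volume, 80)
  # final statistic equals a batch computation at t = 80
  i <- 13 + (13 - 1) * 48   # peak voxel, column-major index
  y <- ds$data[13, 13, ]
  fit <- gls_fit(ds$design[1:80, ], y)
  v <- contrast_variance(c(0, 1, 0), ds$design[1:80, ],
                         sigma2_hat = fit$sigma2_hat)
  lam <- lambda_one_sided(fit$beta_hat[["A"]], v, 0, 1)
  expect_equal(unname(run$lambda[i, "A"]), lam, tolerance = 1e-10)
})

test_that("null data keep the voxel-wise false-positive rate controlled", {
  set.seed(53)
  n <- 250
  par <- two_task_paradigm(360)
  X <- build_design_matrix(par, double_gamma_hrf(2))
  arr <- array(100 + rnorm(n * 360, sd = 2), c(n, 1, 360))
  hyp <- hypothesis(c(0, 1, 0), theta1 = 1, label = "A")
  b <- compute_boundaries(0.01, 0.1, truncation = 360)
  run <- run_sequential(arr, par, hyp, bounds = b, g_percent = 100,
                        smooth = FALSE, drift = FALSE)
  # truncated SPRT: count boundary crossings of Ha among null voxels
  frac_ha <- mean(run$verdicts[, 1] == "accept_Ha" &
                    run$decided_t[, 1] < 360, na.rm = TRUE)
  expect_lte(frac_ha, 0.01 + 2 * sqrt(0.01 * 0.99 / n))
  # and the vast majority accept H0
  expect_gt(mean(run$classification[, 1] == "H0"), 0.95)
})

test_that("strong signals decide quickly and classify correctly", {
  set.seed(54)
  par <- two_task_paradigm(360)
  X <- build_design_matrix(par, double_gamma_hrf(2))
  n <- 60
  arr <- array(0, c(n, 1, 360))
  for (i in 1:n) arr[i, 1, ] <- 100 + 2 * X[, "A"] + rnorm(360, sd = 2)
  hyp <- hypothesis(c(0, 1, 0), theta1 = 1, label = "A")
  b <- compute_boundaries(0.01, 0.1, truncation = 360)
  run <- run_sequential(arr, par, hyp, bounds = b, g_percent = 100,
                        smooth = FALSE, drift = FALSE)
  expect_true(all(run$classification[, 1] == "Ha"))
  expect_lt(run$stop_volume, 200)
})

test_that("multi-hypothesis runs decide voxels conjunctively", {
  set.seed(55)
  par <- two_task_paradigm(200)
  X <- build_design_matrix(par, double_gamma_hrf(2))
  arr <- array(0, c(2, 1, 200))
  arr[1, 1, ] <- 100 + 3 * X[, "A"] + rnorm(200, sd = 1)
  arr[2, 1, ] <- 100 + 3 * X[, "A"] + 3 * X[, "B"] + rnorm(200, sd = 1)
  hyps <- list(hypothesis(c(0, 1, 0), theta1 = 1, label = "A"),
               hypothesis(c(0, 0, 1), theta1 = 1, label = "B"))
  b <- compute_boundaries(0.05, 0.1, truncation = 200)
  run <- run_sequential(arr, par, hyps, bounds = b, g_percent = 100,
                        smooth = FALSE, drift = FALSE)
  expect_equal(unname(run$classification[1, ]), c("Ha", "H0"))
  expect_equal(unname(run$classification[2, ]), c("Ha", "Ha"))
  expect_equal(run$class_map[1, 1], 1L)
  expect_equal(run$class_map[2, 1], 3L)
})

test_that("geometry and stream errors are reported", {
  arr <- array(rnorm(4 * 4 * 40), c(4, 4, 40))
  par <- two_task_paradigm(40)
  hyp <- hypothesis(c(0, 1, 0), theta1 = 1)
  expect_error(run_sequential(arr, par, hyp, mask = matrix(TRUE, 3, 3)),
               "geometry mismatch")
  expect_error(run_sequential(arr, par, hyp,
                              mask = matrix(FALSE, 4, 4)), "empty mask")
  # stream exhausted before the truncation bound: warn, then truncate
  b <- compute_boundaries(0.01, 0.1, truncation = 80)
  b$A <- Inf
  b$B <- -Inf   # keep every voxel open until the stream runs out
  expect_warning(run <- run_sequential(arr, par, hyp, bounds = b,
                                       g_percent = 100, smooth = FALSE,
                                       drift = FALSE),
                 "exhausted|truncat")
  expect_equal(run$stop_volume, 40)
  expect_true(all(run$verdicts != "continue"))
})

test_that("runs are deterministic replays of the same data", {
  set.seed(56)
  ds <- simulate_experiment(peak_b = 1, n_volumes = 60, seed = 57)
  hyp <- hypothesis(c(0, 1, 0), theta1 = 1, label = "A")
  b <- compute_boundaries(0.01, 0.1, n_tests = 2304, truncation = 60)
  r1 <- run_sequential(ds, ds$paradigm, hyp, bounds = b, g_percent = 30)
  r2 <- run_sequential(ds, ds$paradigm, hyp, bounds = b, g_percent = 30)
  expect_identical(r1$lambda, r2$lambda)
  expect_identical(r1$class_map, r2$class_map)
  expect_identical(r1$stop_volume, r2$stop_volume)
})
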