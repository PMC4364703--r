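test_that("stopping boundaries follow Wald's closed form", {
  b <- compute_boundaries(0.01, 0.1)
  expect_equal(b$A, log(0.9 / 0.01), tolerance = 1e-12)
  expect_equal(b$B, log(0.1 / 0.99), tolerance = 1e-12)
  expect_equal(b$A, 4.4998, tolerance = 1e-4)
  expect_equal(b$B, -2.2925, tolerance = 1e-4)
  # symmetry when alpha = beta
  bs <- compute_boundaries(0.05, 0.05)
  expect_equal(bs$A, -bs$B)
  # Bonferroni over the full 48 x 48 image widens both boundaries
  bb <- compute_boundaries(0.01, 0.1, n_tests = 2304)
  expect_equal(bb$A, log((1 - 0.1 / 2304) / (0.01 / 2304)),
               tolerance = 1e-12)
  expect_equal(bb$A, 12.348, tolerance = 1e-3)
  expect_equal(bb$B, -10.045, tolerance = 1e-3)
  expect_gt(bb$A, b$A)
  expect_lt(bb$B, b$B)
  expect_error(compute_boundaries(0, 0.1), "alpha")
  expect_error(compute_boundaries(0.01, 1), "beta")
})

test_that("tightening either error rate widens the continue region", {
  grid <- expand.grid(a = c(0.001, 0.01, 0.05), b = c(0.01, 0.1, 0.2))
  for (i in seq_len(nrow(grid))) {
    b0 <- compute_boundaries(grid$a[i], grid$b[i])
    expect_true(b0$B < 0 && 0 < b0$A)
    tighter <- compute_boundaries(grid$a[i] / 2, grid$b[i] / 2)
    expect_gt(tighter$A, b0$A)
    expect_lt(tighter$B, b0$B)
  }
})

test_that("one-sided statistic matches hand-evaluated likelihood ratios", {
  expect_equal(lambda_one_sided(1, 0.5, 0, 1), 1)
  expect_equal(lambda_one_sided(0, 1, 0, 1), -0.5)
  expect_equal(lambda_one_sided(0.5, 0.123, 0, 1), 0)  # midpoint
  # strictly increasing in the estimate
  cb <- seq(-2, 3, by = 0.1)
  expect_true(all(diff(lambda_one_sided(cb, 0.7, 0, 1)) > 0))
  expect_true(is.na(lambda_one_sided(1, -1, 0, 1)))
})

test_that("two-sided statistic is symmetric and hand-checked", {
  expect_equal(lambda_two_sided(0, 1, 0, 1), -0.5)
  expect_equal(lambda_two_sided(1, 1, 0, 1), log(0.5 * (1 + exp(-2))) + 0.5)
  expect_equal(lambda_two_sided(1, 1, 0, 1), -0.0662, tolerance = 1e-3)
  d <- seq(0.1, 2.5, by = 0.3)
  expect_equal(lambda_two_sided(d, 0.4, 0, 1),
               lambda_two_sided(-d, 0.4, 0, 1))
  # offset null
  expect_equal(lambda_two_sided(2 + d, 0.4, 2, 1),
               lambda_two_sided(2 - d, 0.4, 2, 1))
  # agrees with direct (unstable) evaluation at moderate values
  direct <- function(z, v, delta)
    log(0.5 * (exp(-(z - delta)^2 / (2 * v)) +
                 exp(-(z + delta)^2 / (2 * v)))) + z^2 / (2 * v)
  expect_equal(lambda_two_sided(1.3, 0.6, 0, 0.8), direct(1.3, 0.6, 0.8))
  # stable where direct evaluation overflows
  expect_true(is.finite(lambda_two_sided(40, 0.01, 0, 1)))
})

test_that("decision rules implement the truncated SPRT", {
  b <- compute_boundaries(0.01, 0.1, truncation = 100)
  expect_equal(decide(0, b, 50), "continue")
  expect_equal(decide(b$A, b, 50), "accept_Ha")    # closed boundary
  expect_equal(decide(b$B, b, 50), "accept_H0")
  expect_equal(decide(b$A + 1, b, 50), "accept_Ha")
  # at truncation the sign decides
  expect_equal(decide(0.1, b, 100), "accept_Ha")
  expect_equal(decide(-0.1, b, 100), "accept_H0")
  expect_equal(decide(0, b, 100), "accept_H0")
  expect_equal(decide(NA_real_, b, 50), "continue")
  expect_equal(decide(NA_real_, b, 100), "accept_H0")
})

test_that("global stopping rule counts fully decided voxels", {
  v <- rep("accept_Ha", 2304)
  v[1:(2304 - 692)] <- "continue"
  expect_true(global_stop(v, 30))            # 692/2304 = 30.03%
  v[2304] <- "continue"                      # 691 decided
  expect_false(global_stop(v, 30))
  expect_false(global_stop(c("continue", rep("accept_H0", 99)), 100))
  expect_true(global_stop(c("accept_H0", rep("continue", 99)), 1))
  # multi-hypothesis: all hypotheses must be decided
  m <- cbind(rep("accept_Ha", 10), c(rep("continue", 5),
                                     rep("accept_H0", 5)))
  expect_true(global_stop(m, 50))
  expect_false(global_stop(m, 51))
  expect_error(global_stop(character(0), 30), "empty mask")
  expect_error(global_stop(v, 0), "g_percent")
})

test_that("sign rule equals the larger-likelihood rule on a grid", {
  grid <- expand.grid(cb = seq(-3, 4, by = 0.25),
                      v = c(0.1, 0.5, 1, 5))
  lam <- lambda_one_sided(grid$cb, grid$v, 0, 1)
  larger_lik <- dnorm(grid$cb, 1, sqrt(grid$v)) >
    dnorm(grid$cb, 0, sqrt(grid$v))
  expect_equal(final_classify(lam) == "Ha", larger_lik)
  expect_equal(final_classify(0), "H0")
  expect_equal(final_classify(2.3), "Ha")
  expect_equal(final_classify(NA_real_), "H0")
})

test_that("SPRT with known variance respects the nominal error rates", {
  # random-walk construction of the sequential contrast estimate:
  # cb_t = theta + cumsum(x e) / cumsum(x^2), Var(cb_t) = s2 / Sx_t
  set.seed(31)
  n_series <- 600
  x <- two_task_design(500)[, "A"]
  x <- x - mean(x)
  sx <- cumsum(x^2)
  b <- compute_boundaries(0.01, 0.1, truncation = 500)
  run_one <- function(theta) {
    e <- rnorm(500)
    cb <- theta + cumsum(x * e) / sx
    lam <- lambda_one_sided(cb, 1 / sx, 0, 1)
    for (t in 10:500) {
      v <- decide(lam[t], b, t)
      if (v != "continue") return(v)
    }
    "continue"
  }
  null_verdicts <- replicate(n_series, run_one(0))
  alt_verdicts <- replicate(n_series, run_one(1))
  type1 <- mean(null_verdicts == "accept_Ha")
  type2 <- mean(alt_verdicts == "accept_H0")
  se1 <- sqrt(0.01 * 0.99 / n_series)
  se2 <- sqrt(0.1 * 0.9 / n_series)
  expect_lte(type1, 0.01 + 2 * se1)
  expect_lte(type2, 0.1 + 2 * se2)
  # essentially no test should reach truncation under these signals
  expect_lt(mean(alt_verdicts == "continue"), 0.02)
})

test_that("stopping is fastest at the alternative and slower in between", {
  set.seed(37)
  x <- two_task_design(400)[, "A"]
  x <- x - mean(x)
  sx <- cumsum(x^2)
  b <- compute_boundaries(0.05, 0.1, truncation = 400)
  stop_time <- function(theta, two_sided = FALSE) {
    e <- rnorm(400)
    cb <- theta + cumsum(x * e) / sx
    lam <- if (two_sided) lambda_two_sided(cb, 1 / sx, 0, 1)
           else lambda_one_sided(cb, 1 / sx, 0, 1)
    for (t in 10:400)
      if (decide(lam[t], b, t) != "continue") return(t)
    400
  }
  at_alt <- replicate(150, stop_time(1))
  midway <- replicate(150, stop_time(0.5))
  expect_lt(mean(at_alt), mean(midway))
  # two-sided tests of the same data need more volumes on average
  two_sided <- replicate(150, stop_time(1, two_sided = TRUE))
  expect_lt(mean(at_alt), mean(two_sided))
})
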