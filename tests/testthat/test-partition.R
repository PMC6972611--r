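# Integral partitioning and the two-segment (linear rise + plateau) location
# of the binodal and spinodal limits.

test_that("integral split obeys the lever rule and conserves the total", {
  expect_equal(partition_from_integrals(2, 1, 3),
               data.frame(n_star_per_V = 1, mother_total_per_V = 2))
  expect_equal(partition_from_integrals(5, 0, 3)$n_star_per_V, 0)
  expect_equal(partition_from_integrals(0.9, 0.1, 3)$n_star_per_V, 0.3)
  set.seed(1)
  I_a <- runif(1000, 1e-6, 100); I_s <- runif(1000, 1e-6, 100)
  out <- partition_from_integrals(I_a, I_s, 3)
  expect_true(all(out$n_star_per_V + out$mother_total_per_V == 3))
  expect_true(all(out$n_star_per_V >= 0 & out$n_star_per_V <= 3))
  # only the integral ratio matters
  expect_equal(partition_from_integrals(17 * I_a, 17 * I_s, 3), out)
  expect_error(partition_from_integrals(0, 0, 3), "no signal")
  expect_error(partition_from_integrals(-1, 1, 3), "non-negative")
})

make_points <- function(n, binodal = 0.43, spinodal = 0.71, slope = 0.5) {
  data.frame(n_star_mM = n,
             c_IbuH_L1_mM = pmin(binodal + slope * n, spinodal))
}

test_that("binodal linear extrapolation recovers a noiseless intercept", {
  pts <- make_points(c(0.05, 0.10, 0.15, 0.20))
  fit <- fit_binodal(pts, breakpoint = 0.56)
  expect_equal(fit$intercept, 0.43, tolerance = 1e-10)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  # flat data: intercept equals the common level
  flat <- data.frame(n_star_mM = c(0.1, 0.2, 0.3, 0.4),
                     c_IbuH_L1_mM = rep(0.55, 4))
  expect_equal(fit_binodal(flat, breakpoint = 1)$intercept, 0.55)
  expect_error(fit_binodal(pts[1:2, ], breakpoint = 0.56), "at least 3")
})

test_that("binodal estimator is unbiased under Gaussian noise", {
  n_seeds <- 100
  est <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- runif(200, 0.02, 0.5)
    pts <- data.frame(n_star_mM = n,
                      c_IbuH_L1_mM = 0.43 + 0.5 * n + rnorm(200, 0, 0.01))
    est[s] <- fit_binodal(pts, breakpoint = 0.56)$intercept
  }
  expect_lt(abs(mean(est) - 0.43), 2 * sd(est) / sqrt(n_seeds))
})

test_that("two-segment fit recovers noiseless boundaries exactly", {
  n <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.8, 1.2, 1.6, 2.0, 2.2)
  pb <- fit_spinodal(make_points(n))
  expect_s3_class(pb, "phase_boundary")
  expect_true(pb$spinodal_determined)
  expect_equal(pb$binodal_mM, 0.43, tolerance = 1e-6)
  expect_equal(pb$spinodal_mM, 0.71, tolerance = 1e-6)
  expect_equal(pb$breakpoint_mM, 0.56, tolerance = 1e-6)
  expect_lt(pb$binodal_mM, pb$spinodal_mM)
})

test_that("strictly linear data leaves the spinodal undetermined", {
  n <- seq(0.05, 0.5, length.out = 8)
  pts <- data.frame(n_star_mM = n, c_IbuH_L1_mM = 0.43 + 0.5 * n)
  expect_warning(pb <- fit_spinodal(pts), "undetermined")
  expect_false(pb$spinodal_determined)
  expect_true(is.na(pb$spinodal_mM))
})

test_that("boundary estimates are invariant to uniform integral rescaling", {
  cfg <- scenario_config()
  raw <- generate_partition_series(cfg, seed = 3)
  scaled <- raw
  scaled$I_a <- raw$I_a * 1e4
  scaled$I_a_star <- raw$I_a_star * 1e4
  pb1 <- fit_spinodal(raw)
  pb2 <- fit_spinodal(scaled)
  expect_equal(pb1$binodal_mM, pb2$binodal_mM)
  expect_equal(pb1$spinodal_mM, pb2$spinodal_mM)
})

test_that("noisy synthetic series recover both boundaries closely", {
  cfg <- scenario_config()  # 2% integral noise, 0.01 pH noise
  bino <- spino <- numeric(50)
  for (s in 1:50) {
    raw <- generate_partition_series(cfg, n_points = 12, seed = s)
    pb <- fit_spinodal(raw, c_tot = cfg$c_tot_mM, pKa = cfg$pKa)
    bino[s] <- pb$binodal_mM; spino[s] <- pb$spinodal_mM
  }
  expect_lt(median(abs(bino - 0.43)), 0.02)
  expect_lt(median(abs(spino - 0.71)), 0.02)
  expect_true(all(bino < spino))
})
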