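# Like-spin dipolar T1/T2 ratio and its inversion into rotational
# correlation times.

omega0_400 <- 2 * pi * 400e6

# closed-form oracle written out from the spectral densities
ratio_oracle <- function(x) {
  J0 <- 2; J1 <- 2 / (1 + x^2); J2 <- 2 / (1 + 4 * x^2)  # per unit tau_c
  (1.5 * J0 + 2.5 * J1 + J2) / (J1 + 4 * J2)
}

test_that("forward ratio has the extreme-narrowing limit and exact values", {
  expect_equal(t1t2_ratio_from_tauc(1e-4 / omega0_400, omega0_400), 1,
               tolerance = 1e-7)
  # direct spectral-density evaluation at omega0 * tau_c = 1
  expect_equal(t1t2_ratio_from_tauc(1 / omega0_400, omega0_400),
               ratio_oracle(1))
  expect_equal(ratio_oracle(1), 2.95 / 1.3)
  expect_error(t1t2_ratio_from_tauc(-1, omega0_400), "positive")
})

test_that("forward ratio is >= 1 and monotone increasing in tau_c", {
  set.seed(3)
  for (i in 1:5) {
    omega0 <- 2 * pi * runif(1, 100e6, 900e6)
    tau <- sort(10^runif(40, -12, -7))
    r <- t1t2_ratio_from_tauc(tau, omega0)
    expect_true(all(r >= 1))
    expect_true(all(diff(r) > 0))
  }
})

test_that("inversion roundtrips the forward model over six decades", {
  tau_grid <- 10^seq(log10(1e-11), log10(1e-7), length.out = 60)
  for (tau in tau_grid) {
    ratio <- t1t2_ratio_from_tauc(tau, omega0_400)
    res <- tauc_from_t1t2(2, 2 / ratio, larmor_frequency_Hz = 400e6)
    expect_true(res$converged)
    expect_lt(abs(res$tau_c - tau) / tau, 1e-9)
  }
})

test_that("inversion agrees with a 1e6-point brute-force grid oracle", {
  x_grid <- 10^seq(-4, 4, length.out = 1e6)
  r_grid <- ratio_oracle(x_grid)
  for (target in c(1.5, 2.2692307692, 5, 50, 1000)) {
    x_oracle <- x_grid[which.min(abs(r_grid - target))]
    res <- tauc_from_t1t2(target, 1, larmor_frequency_Hz = 1 / (2 * pi))
    expect_lt(abs(res$omega_tau_c - x_oracle) / x_oracle, 1e-4)
  }
})

test_that("T1 = T2 reports below-detection; T1 < T2 is rejected", {
  res <- tauc_from_t1t2(1.3, 1.3, larmor_frequency_Hz = 400e6)
  expect_false(res$converged)
  expect_true(res$below_detection)
  expect_true(is.na(res$tau_c))
  expect_equal(res$tau_c_upper, 0.1 / omega0_400)
  expect_error(tauc_from_t1t2(1, 2), "unphysical")
})

test_that("dense/mother contrast factor is recovered at 2% noise", {
  expect_equal(tauc_contrast(tauc_from_t1t2(2, 1, 400e6),
                             tauc_from_t1t2(2, 1, 400e6)), 1)
  factors <- vapply(1:100, function(s) {
    m <- generate_relaxation_pair(0.3e-9, sigma = 0.02, peak = "a",
                                  seed = 2 * s)
    d <- generate_relaxation_pair(1.8e-9, sigma = 0.02, peak = "a*",
                                  seed = 2 * s + 1)
    tauc_contrast(tauc_from_t1t2(m), tauc_from_t1t2(d))
  }, numeric(1))
  expect_gt(mean(factors), 5)
  expect_lt(mean(factors), 7)
  # contrast is invariant to a common rescaling of both correlation times
  a <- tauc_from_t1t2(2, 0.8, 400e6); b <- tauc_from_t1t2(2, 0.2, 400e6)
  a2 <- tauc_from_t1t2(2, 0.8, 800e6); b2 <- tauc_from_t1t2(2, 0.2, 800e6)
  expect_equal(tauc_contrast(a, b), tauc_contrast(a2, b2))
})
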