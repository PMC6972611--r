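# Weak-acid speciation: mass-action fractions, mother-phase concentration
# from pH, and the titration charge-balance solver.

test_that("protonated fraction follows the mass-action law", {
  expect_equal(protonated_fraction(4.4, pKa = 4.4), 0.5)
  expect_equal(protonated_fraction(6.4, pKa = 4.4), 1 / 101)
  # direct evaluation oracle at pH 0
  expect_equal(protonated_fraction(0, pKa = 4.4), 1 / (1 + 10^(-4.4)))
})

test_that("protonated fraction is strictly decreasing in pH", {
  set.seed(42)
  for (pKa in runif(5, 2, 9)) {
    pH <- sort(runif(50, 0, 14))
    f <- protonated_fraction(pH, pKa)
    expect_true(all(diff(f) < 0))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("mother-phase IbuH concentration rearranges mass action", {
  expect_equal(mother_phase_ibuh(4.4, c_ibu_minus = 1.5, pKa = 4.4), 1.5)
  expect_equal(mother_phase_ibuh(3.4, c_ibu_minus = 0.1, pKa = 4.4), 1.0)
  expect_equal(mother_phase_ibuh(2.31, c_ibu_minus = 0.005, pKa = 4.4),
               0.005 * 10^(4.4 - 2.31))  # ~0.615 mM
  expect_error(mother_phase_ibuh(4, c_ibu_minus = -1), "non-negative")
})

test_that("titration solver handles the pure-water and strong-acid limits", {
  expect_equal(solve_titration_state(0, 0, speciation_config(c_tot_mM = 0))$pH,
               7, tolerance = 1e-8)
  # 1 mM strong acid, no drug: 21 mM HCl diluted 1 mL into 20 mL
  st <- solve_titration_state(1, 0, speciation_config(c_tot_mM = 0,
                                                      c_hcl_mM = 21))
  expect_equal(st$c_Cl_mM, 1)
  expect_equal(st$pH, 3, tolerance = 1e-4)
})

# independent oracle: dense pH-grid scan of the charge-balance residual
brute_force_pH <- function(v_hcl, v_ibuna, cfg) {
  v <- cfg$v0_mL + v_hcl + v_ibuna
  drug <- (cfg$c_tot_mM * cfg$v0_mL + cfg$c_ibuna_mM * v_ibuna) / v / 1000
  na <- drug
  cl <- cfg$c_hcl_mM * v_hcl / v / 1000
  Ka <- 10^(-cfg$pKa)
  pH <- seq(0, 14, by = 1e-4)
  h <- 10^(-pH)
  res <- na + h - cl - cfg$Kw / h - drug * Ka / (Ka + h)
  pH[which.min(abs(res))]
}

test_that("solver matches the brute-force pH-grid oracle on random configs", {
  set.seed(7)
  for (i in 1:100) {
    cfg <- speciation_config(pKa = runif(1, 3, 6),
                             c_tot_mM = runif(1, 0.5, 5),
                             c_hcl_mM = runif(1, 5, 25),
                             c_ibuna_mM = runif(1, 2, 10))
    v_hcl <- runif(1, 0, 2); v_ibuna <- runif(1, 0, 2)
    st <- solve_titration_state(v_hcl, v_ibuna, cfg)
    expect_equal(st$pH, brute_force_pH(v_hcl, v_ibuna, cfg),
                 tolerance = 1e-3)
    # solver-state invariants on the molar scale
    expect_lt(abs(st$charge_residual), 1e-10)
    expect_lt(abs(st$mass_action_residual), 1e-10)
    expect_true(all(unlist(st[c("c_IbuH_mM", "c_Ibu_minus_mM",
                                "c_Na_mM", "c_Cl_mM")]) >= 0))
  }
})

test_that("default scenario starts at the hydrolysis pH of the salt", {
  # 3 mM sodium salt of a pKa-4.4 acid: pH from hydrolysis, near 7.9
  st <- solve_titration_state(0, 0, speciation_config())
  expect_equal(st$pH, brute_force_pH(0, 0, speciation_config()),
               tolerance = 1e-3)
  expect_gt(st$pH, 7.5)
})
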