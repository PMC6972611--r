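# Synthetic generators: seeded determinism, zero-noise roundtrips through
# the matching estimators, and the titration forward model.

test_that("scenario config validates the phase-boundary ordering", {
  cfg <- scenario_config()
  expect_equal(cfg$breakpoint_mM, (0.71 - 0.43) / 0.5)
  expect_error(scenario_config(binodal_mM = 0.8, spinodal_mM = 0.7))
  expect_error(scenario_config(spinodal_mM = 3.5))
  expect_error(scenario_config(sigma_integral = -0.1))
})

test_that("every generator is deterministic in (config, seed)", {
  cfg <- scenario_config()
  expect_identical(generate_partition_series(cfg, seed = 7),
                   generate_partition_series(cfg, seed = 7))
  expect_false(identical(generate_partition_series(cfg, seed = 7)$I_a,
                         generate_partition_series(cfg, seed = 8)$I_a))
  expect_identical(generate_pfgste_decay(5e-10, seed = 3)$intensity,
                   generate_pfgste_decay(5e-10, seed = 3)$intensity)
  expect_identical(generate_noesy_intensities(seed = 2),
                   generate_noesy_intensities(seed = 2))
  m1 <- generate_relaxation_pair(1e-9, seed = 4)
  m2 <- generate_relaxation_pair(1e-9, seed = 4)
  expect_identical(m1$T1_s, m2$T1_s)
})

test_that("zero-noise generation roundtrips every ground-truth parameter", {
  cfg <- scenario_config(sigma_integral = 0, sigma_decay = 0,
                         sigma_relaxation = 0, sigma_noe = 0, sigma_pH = 0)
  # partition -> boundaries
  pb <- fit_spinodal(generate_partition_series(cfg, seed = 1))
  expect_equal(pb$binodal_mM, cfg$binodal_mM, tolerance = 1e-6)
  expect_equal(pb$spinodal_mM, cfg$spinodal_mM, tolerance = 1e-6)
  # decays -> D, both phases
  for (i in seq_len(nrow(cfg$diffusion_truth))) {
    for (col in c("D_mother", "D_dense")) {
      D <- cfg$diffusion_truth[[col]][i]
      fit <- fit_stejskal_tanner(generate_pfgste_decay(D, sigma = 0))
      expect_lt(abs(fit$D - D) / D, 1e-6)
    }
  }
  # relaxation -> tau_c both phases and their contrast
  m <- generate_relaxation_pair(cfg$tauc_mother_s, cfg$larmor_frequency_Hz,
                                sigma = 0, peak = "a")
  d <- generate_relaxation_pair(cfg$tauc_dense_s, cfg$larmor_frequency_Hz,
                                sigma = 0, peak = "a*")
  rm_ <- tauc_from_t1t2(m); rd <- tauc_from_t1t2(d)
  expect_equal(rm_$tau_c, cfg$tauc_mother_s, tolerance = 1e-8)
  expect_equal(rd$tau_c, cfg$tauc_dense_s, tolerance = 1e-8)
  expect_equal(tauc_contrast(rm_, rd),
               cfg$tauc_dense_s / cfg$tauc_mother_s, tolerance = 1e-8)
  # NOESY -> distances
  tab <- noe_distance_table(generate_noesy_intensities(cfg$distances_A,
                                                       sigma = 0))
  expect_equal(tab$distance_angstrom[match(names(cfg$distances_A), tab$pair)],
               unname(cfg$distances_A), tolerance = 1e-9)
})

test_that("generated partition rows conserve the total amount", {
  raw <- generate_partition_series(scenario_config(), seed = 6)
  out <- partition_from_integrals(raw$I_a, raw$I_a_star, 3)
  expect_true(all(out$n_star_per_V + out$mother_total_per_V == 3))
})

test_that("titration pH decreases monotonically and flags the onset", {
  cfg <- scenario_config()
  log <- generate_titration_series(cfg, t_end_s = 300, dt_s = 10,
                                   sigma_pH = 0)
  expect_true(all(diff(log$pH) < 0))
  expect_true(any(log$turbid))
  # turbidity begins exactly where c(IbuH) crosses the binodal
  first <- which(log$turbid)[1]
  expect_gt(log$c_IbuH_mM[first], cfg$binodal_mM)
  expect_lt(log$c_IbuH_mM[first - 1], cfg$binodal_mM)
  # zero dosing keeps the composition constant
  still <- scenario_config(titration = speciation_config(rate_mL_per_min = 0))
  log0 <- generate_titration_series(still, t_end_s = 50, dt_s = 10,
                                    sigma_pH = 0)
  expect_equal(diff(range(log0$pH)), 0)
})

test_that("onset root-find matches an independent fine volume scan", {
  cfg <- scenario_config()
  on <- titration_onset(cfg)
  expect_equal(on$c_IbuH_mM, cfg$binodal_mM, tolerance = 1e-3)
  v_grid <- seq(0, 2, by = 1e-3)
  c_grid <- vapply(v_grid, function(v)
    solve_titration_state(v, v, cfg$titration)$c_IbuH_mM, numeric(1))
  v_scan <- v_grid[which(c_grid >= cfg$binodal_mM)[1]]
  expect_equal(on$v_mL, v_scan, tolerance = 2e-3)
})

test_that("peak table mirrors the two-phase spectrum layout", {
  cfg <- scenario_config()
  single <- generate_peak_table(cfg, n_star_mM = 0)
  expect_false(any(grepl("\\*", single$peak)))
  two <- generate_peak_table(cfg, n_star_mM = 0.5)
  dense <- two[two$phase == "dense", ]
  mother <- two[two$phase == "mother", ]
  shift <- mother$ppm[match(sub("\\*", "", dense$peak), mother$peak)] -
    dense$ppm
  expect_equal(shift, ifelse(dense$type == "aromatic", 0.5, 0.3))
  # integrals follow the lever rule split
  expect_equal(unique(dense$integral) / unique(mother$integral), 0.5 / 2.5)
})
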