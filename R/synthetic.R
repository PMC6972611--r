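# Synthetic-data generators emulating the full measurement chain: titration
# logs, partition integral tables, PFG-STE decays, T1/T2 pairs and NOESY
# intensities, each a deterministic function of (config, seed).

#' Ground-truth scenario configuration for the synthetic generators
#'
#' Collects every ground-truth quantity the generators need. The defaults
#' describe the replication scenario for the ibuprofen study conditions: a
#' 3 mM total drug concentration, a miscibility gap with binodal 0.43 mM and
#' spinodal 0.71 mM, the measured per-composition diffusion coefficients of
#' both phases, a 6-fold rotational slowdown in the dense phase, and the
#' dense-phase interproton distances seen by NOESY. Noise levels are
#' multiplicative Gaussian fractions on NMR intensities and additive on pH.
#'
#' @param binodal_mM,spinodal_mM Miscibility-gap limits, mM
#'   (`0 < binodal < spinodal < c_tot`).
#' @param slope Slope of the mother-phase composition vs. dense-phase amount
#'   below the plateau (dimensionless, both axes mM). Fixes the plateau
#'   onset at `(spinodal - binodal) / slope` mM.
#' @param c_tot_mM Total drug concentration, mM.
#' @param pKa Acid dissociation exponent.
#' @param titration A [speciation_config()] for the titration generator.
#' @param diffusion_truth data.frame of per-composition ground-truth
#'   diffusion coefficients: columns `n_star_mM`, `D_mother`, `D_dense`
#'   (m^2 s^-1).
#' @param tauc_mother_s,tauc_dense_s Ground-truth rotational correlation
#'   times, s.
#' @param larmor_frequency_Hz Proton Larmor frequency, Hz.
#' @param distances_A Named vector of true dense-phase interproton
#'   distances, Angstrom.
#' @param d_ref_A Intramolecular NOE reference distance, Angstrom.
#' @param sigma_integral,sigma_decay,sigma_relaxation,sigma_noe Fractional
#'   (multiplicative Gaussian) noise levels on the respective intensities.
#' @param sigma_pH Additive Gaussian noise on pH readings, pH units.
#' @param seed Default random seed for the generators.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(binodal_mM = 0.43, spinodal_mM = 0.71,
                            slope = 0.5, c_tot_mM = 3, pKa = 4.4,
                            titration = speciation_config(pKa = pKa,
                                                          c_tot_mM = c_tot_mM),
                            diffusion_truth = data.frame(
                              n_star_mM = c(0.271, 0.328, 0.412, 0.616),
                              D_mother = c(555, 546, 498, 491) * 1e-12,
                              D_dense = c(16.3, 5.8, 2.48, 2.05) * 1e-12),
                            tauc_mother_s = 0.3e-9, tauc_dense_s = 1.8e-9,
                            larmor_frequency_Hz = 400e6,
                            distances_A = c("a*-b*" = 2.04, "b*-c*" = 2.71),
                            d_ref_A = NOE_D_REF_ANGSTROM,
                            sigma_integral = 0.02, sigma_decay = 0.01,
                            sigma_relaxation = 0.02, sigma_noe = 0.02,
                            sigma_pH = 0.01, seed = 1L) {
  stopifnot(binodal_mM > 0, binodal_mM < spinodal_mM, spinodal_mM < c_tot_mM,
            slope > 0, pKa > 0, pKa < 14,
            all(c("n_star_mM", "D_mother", "D_dense") %in%
                  names(diffusion_truth)),
            tauc_mother_s > 0, tauc_dense_s > 0, larmor_frequency_Hz > 0,
            all(distances_A > 0), d_ref_A > 0,
            sigma_integral >= 0, sigma_decay >= 0, sigma_relaxation >= 0,
            sigma_noe >= 0, sigma_pH >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(binodal_mM = binodal_mM, spinodal_mM = spinodal_mM,
                 slope = slope,
                 breakpoint_mM = (spinodal_mM - binodal_mM) / slope,
                 c_tot_mM = c_tot_mM, pKa = pKa, titration = titration,
                 diffusion_truth = diffusion_truth,
                 tauc_mother_s = tauc_mother_s, tauc_dense_s = tauc_dense_s,
                 larmor_frequency_Hz = larmor_frequency_Hz,
                 distances_A = distances_A, d_ref_A = d_ref_A,
                 sigma_integral = sigma_integral, sigma_decay = sigma_decay,
                 sigma_relaxation = sigma_relaxation, sigma_noe = sigma_noe,
                 sigma_pH = sigma_pH, seed = as.integer(seed)),
            class = "scenario_config")
}

# True mother-phase protonated concentration at a dense-phase amount n*:
# linear rise to the spinodal plateau (hard changepoint).
true_c_ibuh <- function(n_star, cfg) {
  pmin(cfg$binodal_mM + cfg$slope * n_star, cfg$spinodal_mM)
}

#' Simulate a double-dosing titration log
#'
#' Forward-simulates the single-phase speciation model along a double-dosing
#' titration (HCl plus drug-salt solution dosed at the same rate, keeping the
#' total drug concentration constant) and reports time, dosed volumes, pH and
#' the protonated drug concentration. A logical `turbid` column flags the
#' compositions at which `c(IbuH)` exceeds the configured binodal limit --
#' the qualitative analogue of the turbidity onset; the speciation forward
#' model itself remains single-phase throughout.
#'
#' @param cfg A [scenario_config()].
#' @param t_end_s Duration of the simulated titration, s.
#' @param dt_s Sampling interval, s.
#' @param sigma_pH Additive Gaussian noise on the reported pH (default: the
#'   scenario value). The noiseless pH is kept in `pH_true`.
#' @param seed Random seed (only used when `sigma_pH > 0`).
#' @return data.frame with columns `time_s`, `v_hcl_mL`, `v_ibuna_mL`, `pH`,
#'   `pH_true`, `c_IbuH_mM`, `turbid`.
#' @export
generate_titration_series <- function(cfg = scenario_config(), t_end_s = 600,
                                      dt_s = 5, sigma_pH = cfg$sigma_pH,
                                      seed = cfg$seed) {
  stopifnot(inherits(cfg, "scenario_config"), t_end_s >= 0, dt_s > 0)
  t <- seq(0, t_end_s, by = dt_s)
  rate_mL_s <- cfg$titration$rate_mL_per_min / 60
  v <- rate_mL_s * t
  states <- lapply(v, function(vi) solve_titration_state(vi, vi, cfg$titration))
  pH_true <- vapply(states, `[[`, numeric(1), "pH")
  c_ibuh <- vapply(states, `[[`, numeric(1), "c_IbuH_mM")
  pH <- pH_true
  if (sigma_pH > 0) {
    set.seed(seed)
    pH <- pH_true + stats::rnorm(length(pH_true), 0, sigma_pH)
  }
  data.frame(time_s = t, v_hcl_mL = v, v_ibuna_mL = v, pH = pH,
             pH_true = pH_true, c_IbuH_mM = c_ibuh,
             turbid = c_ibuh > cfg$binodal_mM)
}

#' Titration volume and time at which the binodal is first reached
#'
#' Root-finds the dosed volume at which the single-phase forward model
#' reaches `c(IbuH) =` the configured binodal limit, i.e. the predicted
#' turbidity onset of the titration.
#'
#' @param cfg A [scenario_config()].
#' @param v_max_mL Upper bracket for the dosed volume per pump, mL.
#' @return List with `v_mL` (per pump), `time_s`, `pH`, `c_IbuH_mM`.
#' @export
titration_onset <- function(cfg = scenario_config(), v_max_mL = 10) {
  f <- function(v)
    solve_titration_state(v, v, cfg$titration)$c_IbuH_mM - cfg$binodal_mM
  if (f(0) >= 0) stop("solution starts beyond the binodal limit")
  if (f(v_max_mL) <= 0) stop("binodal not reached within `v_max_mL`")
  root <- stats::uniroot(f, c(0, v_max_mL), tol = 1e-10)
  st <- solve_titration_state(root$root, root$root, cfg$titration)
  rate_mL_s <- cfg$titration$rate_mL_per_min / 60
  list(v_mL = root$root,
       time_s = if (rate_mL_s > 0) root$root / rate_mL_s else NA_real_,
       pH = st$pH, c_IbuH_mM = st$c_IbuH_mM)
}

#' Simulate a partition peak-integral series across the miscibility gap
#'
#' Samples dense-phase amounts on both sides of the plateau onset (half the
#' points in the rising regime, half in the plateau regime), computes the
#' true mother-phase composition from the linear-then-plateau model, converts
#' to peak integrals through amount conservation, and degrades integrals with
#' multiplicative Gaussian noise and the pH reading with additive noise. The
#' output has exactly the columns of a raw partition table so the full
#' estimation chain (integral split, speciation, two-segment fit) can be
#' exercised end to end. Ground truth is attached as attribute `truth`.
#'
#' @param cfg A [scenario_config()].
#' @param n_points Number of sampled compositions (>= 6).
#' @param seed Random seed.
#' @param n_star_grid Optional explicit dense-phase amounts, mM.
#' @return data.frame with columns `pH`, `I_a`, `I_a_star`.
#' @export
generate_partition_series <- function(cfg = scenario_config(), n_points = 12,
                                      seed = cfg$seed, n_star_grid = NULL) {
  stopifnot(inherits(cfg, "scenario_config"), n_points >= 6)
  if (is.null(n_star_grid)) {
    n_lo <- ceiling(n_points / 2); n_hi <- n_points - n_lo
    x0 <- cfg$breakpoint_mM
    n_star_grid <- c(seq(0.05, 0.98 * x0, length.out = n_lo),
                     seq(1.4 * x0, 0.95 * (cfg$c_tot_mM - cfg$spinodal_mM),
                         length.out = n_hi))
  }
  n_star <- n_star_grid
  c_ibuh <- true_c_ibuh(n_star, cfg)
  mother_total <- cfg$c_tot_mM - n_star
  c_ibu_minus <- mother_total - c_ibuh
  if (any(c_ibu_minus <= 0))
    stop("infeasible composition: mother-phase total below its protonated part")
  pH_true <- cfg$pKa + log10(c_ibu_minus / c_ibuh)

  set.seed(seed)
  I_a <- mother_total * (1 + stats::rnorm(length(n_star), 0, cfg$sigma_integral))
  I_a_star <- n_star * (1 + stats::rnorm(length(n_star), 0, cfg$sigma_integral))
  pH <- pH_true + stats::rnorm(length(n_star), 0, cfg$sigma_pH)
  if (any(I_a <= 0) || any(I_a_star <= 0))
    stop("noise level too large: generated a non-positive integral")

  out <- data.frame(pH = pH, I_a = I_a, I_a_star = I_a_star)
  attr(out, "truth") <- list(n_star_mM = n_star, c_IbuH_L1_mM = c_ibuh,
                             pH = pH_true, binodal_mM = cfg$binodal_mM,
                             spinodal_mM = cfg$spinodal_mM,
                             breakpoint_mM = cfg$breakpoint_mM, seed = seed)
  out
}

#' Default gradient schedule for a target diffusion coefficient
#'
#' Chooses `n_steps` equally spaced gradient strengths whose largest value
#' attenuates the echo by `exp(-b_max * D) = exp(-4)`, a well-conditioned
#' dynamic range for the log-linear fit regardless of how slow the diffusion
#' is.
#'
#' @param D Target diffusion coefficient, m^2 s^-1.
#' @param n_steps Number of gradient steps.
#' @param delta_s,Delta_s,gamma Timing parameters, see [b_factor()].
#' @param bD_max Target maximum diffusion weighting `b * D`.
#' @return Vector of gradient strengths, T m^-1.
#' @export
gradient_schedule <- function(D, n_steps = 16, delta_s = 2e-3, Delta_s = 0.1,
                              gamma = GAMMA_1H, bD_max = 4) {
  stopifnot(D > 0, n_steps >= 4, bD_max > 0)
  g_max <- sqrt(bD_max / (D * (Delta_s - delta_s / 3))) / (gamma * delta_s)
  seq(g_max / n_steps, g_max, length.out = n_steps)
}

#' Simulate a PFG-STE echo decay
#'
#' Generates `I(g) = I0 * exp(-b(g) * D)` on a gradient schedule and applies
#' multiplicative Gaussian noise, deterministic in the seed.
#'
#' @param D True diffusion coefficient, m^2 s^-1.
#' @param sigma Fractional intensity noise.
#' @param g Gradient schedule, T m^-1; defaults to [gradient_schedule()] for
#'   `D`.
#' @param n_steps Number of gradient steps when `g` is defaulted.
#' @param delta_s,Delta_s,gamma Timing parameters, see [b_factor()].
#' @param I0 Zero-gradient intensity.
#' @param phase Phase label for the curve.
#' @param seed Random seed.
#' @return A [decay_curve()] with attribute `truth` (list with `D`, `I0`).
#' @export
generate_pfgste_decay <- function(D, sigma = 0.01, g = NULL, n_steps = 16,
                                  delta_s = 2e-3, Delta_s = 0.1,
                                  gamma = GAMMA_1H, I0 = 1,
                                  phase = c("mother", "dense"), seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(D > 0, sigma >= 0, I0 > 0)
  if (is.null(g))
    g <- gradient_schedule(D, n_steps = n_steps, delta_s = delta_s,
                           Delta_s = Delta_s, gamma = gamma)
  b <- b_factor(g, delta_s, Delta_s, gamma)
  set.seed(seed)
  I <- I0 * exp(-b * D) * (1 + stats::rnorm(length(b), 0, sigma))
  if (any(I <= 0))
    stop("noise level too large: generated a non-positive intensity")
  curve <- decay_curve(g = g, intensity = I, delta_s = delta_s,
                       Delta_s = Delta_s, gamma = gamma, phase = phase)
  attr(curve, "truth") <- list(D = D, I0 = I0, sigma = sigma, seed = seed)
  curve
}

#' Simulate a T1/T2 relaxation measurement for a given correlation time
#'
#' Computes the forward like-spin dipolar `T1/T2` ratio at the true
#' correlation time, anchors it to a nominal `T1` scale, and applies
#' independent multiplicative Gaussian noise to both times. Noise can push
#' the pair into the unphysical `T2 > T1` corner; such draws are clipped back
#' to `T2 = T1`.
#'
#' @param tau_c True rotational correlation time, s.
#' @param larmor_frequency_Hz Proton Larmor frequency, Hz.
#' @param sigma Fractional noise on each relaxation time.
#' @param T1_s Nominal longitudinal relaxation time, s (sets the scale only;
#'   the inversion uses the ratio).
#' @param peak Peak label.
#' @param seed Random seed.
#' @return A [relaxation_measurement()] with attribute `truth`.
#' @export
generate_relaxation_pair <- function(tau_c, larmor_frequency_Hz = 400e6,
                                     sigma = 0.02, T1_s = 2,
                                     peak = c("a", "a*"), seed = 1L) {
  peak <- match.arg(peak)
  stopifnot(tau_c > 0, sigma >= 0, T1_s > 0)
  ratio <- t1t2_ratio_from_tauc(tau_c, 2 * pi * larmor_frequency_Hz)
  set.seed(seed)
  T1 <- T1_s * (1 + stats::rnorm(1, 0, sigma))
  T2 <- (T1_s / ratio) * (1 + stats::rnorm(1, 0, sigma))
  if (T1 <= 0 || T2 <= 0)
    stop("noise level too large: generated a non-positive relaxation time")
  if (T2 > T1) T2 <- T1
  m <- relaxation_measurement(T1, T2, larmor_frequency_Hz, peak)
  attr(m, "truth") <- list(tau_c = tau_c, sigma = sigma, seed = seed)
  m
}

#' Simulate a NOESY cross-peak intensity table
#'
#' Forward r^-6 intensities for the configured true distances, plus the
#' intramolecular reference pair, each with multiplicative Gaussian noise.
#'
#' @param distances_A Named vector of true distances, Angstrom.
#' @param d_ref_A Reference distance, Angstrom.
#' @param I_ref Reference intensity.
#' @param sigma Fractional intensity noise.
#' @param ref_pair Label of the reference pair.
#' @param seed Random seed.
#' @return data.frame with columns `pair`, `intensity`, `is_reference` and
#'   attribute `truth`.
#' @export
generate_noesy_intensities <- function(distances_A = c("a*-b*" = 2.04,
                                                       "b*-c*" = 2.71),
                                       d_ref_A = NOE_D_REF_ANGSTROM, I_ref = 1,
                                       sigma = 0.02, ref_pair = "a*-c*",
                                       seed = 1L) {
  stopifnot(all(distances_A > 0), d_ref_A > 0, I_ref > 0, sigma >= 0,
            !is.null(names(distances_A)))
  I_true <- vapply(distances_A, function(d)
    noe_intensity_from_distances(d, d_ref = d_ref_A, I_ref = I_ref),
    numeric(1))
  set.seed(seed)
  noise <- 1 + stats::rnorm(length(I_true) + 1L, 0, sigma)
  if (any(noise <= 0))
    stop("noise level too large: generated a non-positive intensity")
  out <- data.frame(
    pair = c(names(distances_A), ref_pair),
    intensity = c(I_true * noise[seq_along(I_true)],
                  I_ref * noise[length(noise)]),
    is_reference = c(rep(FALSE, length(I_true)), TRUE)
  )
  attr(out, "truth") <- list(distances_A = distances_A, d_ref_A = d_ref_A,
                             I_ref = I_ref, sigma = sigma, seed = seed)
  out
}

#' Nominal 1D peak table for a two-phase sample
#'
#' Emits the mother-phase proton resonances of the drug and, for a
#' phase-separated sample, their dense-phase twins shifted upfield by
#' 0.3 ppm (aliphatic protons) or 0.5 ppm (aromatic protons), with integrals
#' proportional to the per-phase amounts from the lever rule. This exercises
#' real-data ingestion paths; no lineshape physics is simulated.
#'
#' @param cfg A [scenario_config()].
#' @param n_star_mM Dense-phase amount per total volume, mM (0 for a
#'   single-phase sample).
#' @return data.frame with columns `peak`, `ppm`, `type`, `phase`,
#'   `integral`.
#' @export
generate_peak_table <- function(cfg = scenario_config(), n_star_mM = 0) {
  stopifnot(n_star_mM >= 0, n_star_mM < cfg$c_tot_mM)
  base <- data.frame(
    peak = c("a", "b", "c", "ar"),
    ppm = c(1.36, 1.82, 0.84, 7.22),
    type = c("aliphatic", "aliphatic", "aliphatic", "aromatic")
  )
  mother <- cbind(base, phase = "mother",
                  integral = cfg$c_tot_mM - n_star_mM)
  if (n_star_mM == 0) return(mother)
  shift <- ifelse(base$type == "aromatic", 0.5, 0.3)
  dense <- data.frame(peak = paste0(base$peak, "*"), ppm = base$ppm - shift,
                      type = base$type, phase = "dense",
                      integral = n_star_mM)
  rbind(mother, dense)
}
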