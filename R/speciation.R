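# Weak-acid protolysis speciation along a double-dosing potentiometric
# titration: IbuH <-> Ibu- + H+ with sodium and chloride bookkeeping.

#' Titration and speciation configuration
#'
#' Bundles the protolysis constant and the titration bookkeeping needed to
#' forward-model a double-dosing experiment in which dilute HCl lowers the pH
#' of a drug sodium-salt solution while a second pump doses more salt solution
#' so that the total drug concentration stays constant.
#'
#' The acid dissociation exponent `pKa` is a required physical input: it is
#' not measured by this package and the default of 4.4 (a literature value
#' commonly quoted for ibuprofen in water) should be overridden whenever a
#' better value for the compound and medium at hand is available.
#'
#' @param pKa Acid dissociation exponent (dimensionless), must lie in (0, 14).
#' @param Kw Ion product of water on the molar concentration scale.
#' @param c_tot_mM Total (phase-summed) drug concentration in mM.
#' @param c_hcl_mM Concentration of the HCl titrant, mM.
#' @param c_ibuna_mM Concentration of the drug sodium-salt titrant, mM.
#' @param rate_mL_per_min Dosing rate of each pump, mL per minute.
#' @param v0_mL Initial solution volume, mL.
#' @return An object of class `speciation_config`.
#' @examples
#' cfg <- speciation_config()
#' cfg$pKa
#' @export
speciation_config <- function(pKa = 4.4, Kw = 1e-14, c_tot_mM = 3,
                              c_hcl_mM = 15, c_ibuna_mM = 6,
                              rate_mL_per_min = 0.2, v0_mL = 20) {
  stopifnot(is.numeric(pKa), length(pKa) == 1L, pKa > 0, pKa < 14,
            is.numeric(Kw), Kw > 0,
            c_tot_mM >= 0, c_hcl_mM >= 0, c_ibuna_mM >= 0,
            rate_mL_per_min >= 0, v0_mL > 0)
  structure(list(pKa = pKa, Kw = Kw, c_tot_mM = c_tot_mM,
                 c_hcl_mM = c_hcl_mM, c_ibuna_mM = c_ibuna_mM,
                 rate_mL_per_min = rate_mL_per_min, v0_mL = v0_mL),
            class = "speciation_config")
}

#' @export
print.speciation_config <- function(x, ...) {
  cat("Speciation / titration configuration\n")
  cat(sprintf("  pKa = %.3g, Kw = %.3g\n", x$pKa, x$Kw))
  cat(sprintf("  c_tot = %.3g mM; titrants: HCl %.3g mM, salt %.3g mM\n",
              x$c_tot_mM, x$c_hcl_mM, x$c_ibuna_mM))
  cat(sprintf("  dosing %.3g mL/min each, initial volume %.3g mL\n",
              x$rate_mL_per_min, x$v0_mL))
  invisible(x)
}

#' Protonated fraction of a weak acid at a given pH
#'
#' Mass-action fraction of the acid that is in the neutral (protonated) form,
#' `1 / (1 + 10^(pH - pKa))`. This is the quantity that controls the
#' pH-adjustable supersaturation of a poorly soluble acidic drug: only the
#' protonated form is sparingly soluble and partitions into the dense phase.
#'
#' @param pH pH value(s).
#' @param pKa Acid dissociation exponent.
#' @return Fraction in \[0, 1\], strictly decreasing in pH.
#' @examples
#' protonated_fraction(4.4, pKa = 4.4)  # 0.5 at pH = pKa
#' @export
protonated_fraction <- function(pH, pKa = 4.4) {
  stopifnot(is.numeric(pH), is.numeric(pKa))
  1 / (1 + 10^(pH - pKa))
}

#' Protonated drug concentration in the mother phase from pH
#'
#' Rearranged mass action: given the measured pH and the deprotonated
#' concentration in the dilute (mother) phase, the protonated concentration is
#' `c_IbuH = c_Ibu_minus * 10^(pKa - pH)`. Together with phase-sum
#' conservation this reduces to
#' `c_IbuH = mother_total * protonated_fraction(pH, pKa)`, which is how the
#' partitioning workflow computes the mother-phase composition from a peak
#' integral and a pH reading.
#'
#' @param pH Measured pH.
#' @param c_ibu_minus Deprotonated drug concentration in the mother phase, mM.
#' @param pKa Acid dissociation exponent.
#' @return Protonated drug concentration, mM.
#' @examples
#' mother_phase_ibuh(2.31, c_ibu_minus = 0.005, pKa = 4.4)
#' @export
mother_phase_ibuh <- function(pH, c_ibu_minus, pKa = 4.4) {
  stopifnot(is.numeric(pH), is.numeric(c_ibu_minus))
  if (any(c_ibu_minus < 0))
    stop("`c_ibu_minus` must be non-negative")
  c_ibu_minus * 10^(pKa - pH)
}

# Totals (mM) after dosing v_hcl and v_ibuna mL, assuming volume additivity.
titration_totals <- function(v_hcl_mL, v_ibuna_mL, cfg) {
  v_tot <- cfg$v0_mL + v_hcl_mL + v_ibuna_mL
  list(
    V_total_mL = v_tot,
    drug_mM = (cfg$c_tot_mM * cfg$v0_mL + cfg$c_ibuna_mM * v_ibuna_mL) / v_tot,
    na_mM   = (cfg$c_tot_mM * cfg$v0_mL + cfg$c_ibuna_mM * v_ibuna_mL) / v_tot,
    cl_mM   = cfg$c_hcl_mM * v_hcl_mL / v_tot
  )
}

# Charge-balance residual (molar scale) as a function of pH for fixed totals.
# f(pH) = [Na+] + [H+] - [Cl-] - [OH-] - [Ibu-]; strictly decreasing in pH.
charge_balance_residual <- function(pH, drug_M, na_M, cl_M, Ka, Kw) {
  h <- 10^(-pH)
  na_M + h - cl_M - Kw / h - drug_M * Ka / (Ka + h)
}

#' Solve the single-phase speciation state at one titration instant
#'
#' Solves the coupled charge-balance, mass-action and mass-conservation system
#' for a homogeneous (single liquid phase) solution of the weak-acid drug, its
#' sodium salt and HCl, assuming ideal dilute behaviour (activity coefficients
#' of one) and additive titrant volumes. The charge balance
#' `[Na+] + [H+] = [Cl-] + [OH-] + [Ibu-]` is strictly monotone in pH, so the
#' root is bracketed on pH in \[0, 14\] and then polished by Newton steps to
#' machine precision.
#'
#' @param v_hcl_mL Volume of HCl titrant added so far, mL.
#' @param v_ibuna_mL Volume of salt titrant added so far, mL.
#' @param cfg A [speciation_config()].
#' @return An object of class `speciation_state`: a list with `pH`,
#'   `c_IbuH_mM`, `c_Ibu_minus_mM`, `c_Na_mM`, `c_Cl_mM`, `V_total_mL`, and
#'   the solver residuals (`charge_residual`, `mass_action_residual`, molar
#'   scale).
#' @examples
#' solve_titration_state(0, 0, speciation_config())$pH
#' @export
solve_titration_state <- function(v_hcl_mL, v_ibuna_mL, cfg = speciation_config()) {
  stopifnot(inherits(cfg, "speciation_config"),
            v_hcl_mL >= 0, v_ibuna_mL >= 0)
  tot <- titration_totals(v_hcl_mL, v_ibuna_mL, cfg)
  drug_M <- tot$drug_mM / 1000
  na_M <- tot$na_mM / 1000
  cl_M <- tot$cl_mM / 1000
  Ka <- 10^(-cfg$pKa)
  Kw <- cfg$Kw

  f <- function(pH) charge_balance_residual(pH, drug_M, na_M, cl_M, Ka, Kw)
  root <- stats::uniroot(f, interval = c(0, 14), tol = 1e-12)
  pH <- root$root
  # Newton polish on h; f is smooth and monotone so 3 steps reach eps.
  h <- 10^(-pH)
  for (i in 1:3) {
    res <- na_M + h - cl_M - Kw / h - drug_M * Ka / (Ka + h)
    dres <- 1 + Kw / h^2 + drug_M * Ka / (Ka + h)^2
    h <- h - res / dres
    if (h <= 0) { h <- 10^(-pH); break }
  }
  pH <- -log10(h)

  ibu_minus_M <- drug_M * Ka / (Ka + h)
  ibuh_M <- drug_M - ibu_minus_M
  charge_res <- na_M + h - cl_M - Kw / h - ibu_minus_M
  ma_res <- Ka * ibuh_M - ibu_minus_M * h
  if (abs(charge_res) > 1e-10 || abs(ma_res) > 1e-10)
    stop(sprintf(paste0("speciation solver did not converge: charge residual ",
                        "%.3e, mass-action residual %.3e (molar scale)"),
                 charge_res, ma_res))

  structure(list(pH = pH,
                 c_IbuH_mM = 1000 * ibuh_M,
                 c_Ibu_minus_mM = 1000 * ibu_minus_M,
                 c_Na_mM = tot$na_mM,
                 c_Cl_mM = tot$cl_mM,
                 V_total_mL = tot$V_total_mL,
                 charge_residual = charge_res,
                 mass_action_residual = ma_res),
            class = "speciation_state")
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("Speciation state: pH %.4f in %.3g mL\n", x$pH, x$V_total_mL))
  cat(sprintf("  IbuH %.5g mM, Ibu- %.5g mM, Na+ %.5g mM, Cl- %.5g mM\n",
              x$c_IbuH_mM, x$c_Ibu_minus_mM, x$c_Na_mM, x$c_Cl_mM))
  invisible(x)
}
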