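# Peak-integral partitioning between the mother phase and the dense liquid
# phase, and location of the binodal / spinodal limits of the liquid-liquid
# miscibility gap from the partitioning curve.

#' Split the total drug concentration between the two liquid phases
#'
#' The 1D spectrum of a phase-separated sample shows each drug resonance
#' twice: the mother-phase peak and a shifted dense-phase twin. Because both
#' phases are observed in the same tube, the integral ratio gives the lever
#' rule split of the (invariant) total concentration:
#' `n_star_per_V = c_tot * I_a_star / (I_a + I_a_star)` and the mother-phase
#' total is the exact complement, so the two outputs always sum to `c_tot`.
#'
#' @param I_a Integral of the mother-phase peak, arbitrary units.
#' @param I_a_star Integral of the dense-phase peak, same units.
#' @param c_tot Total drug concentration, mM.
#' @return A data.frame with columns `n_star_per_V` (dense-phase amount per
#'   total volume, mM) and `mother_total_per_V` (mM). Vector inputs are
#'   recycled row-wise.
#' @examples
#' partition_from_integrals(2, 1, c_tot = 3)
#' @export
partition_from_integrals <- function(I_a, I_a_star, c_tot = 3) {
  stopifnot(is.numeric(I_a), is.numeric(I_a_star), c_tot > 0)
  if (any(I_a < 0) || any(I_a_star < 0))
    stop("peak integrals must be non-negative")
  if (any(I_a + I_a_star == 0))
    stop("no signal: both integrals are zero")
  n_star <- c_tot * I_a_star / (I_a + I_a_star)
  data.frame(n_star_per_V = n_star, mother_total_per_V = c_tot - n_star)
}

#' Reduce a raw partition table to composition coordinates
#'
#' Converts rows of `(pH, I_a, I_a_star)` into the coordinates in which the
#' phase boundaries are read off: the dense-phase amount per total volume
#' (abscissa) and the protonated drug concentration in the mother phase
#' (ordinate). The latter combines the lever-rule mother-phase total with the
#' mass-action protonated fraction at the measured pH; the small loss of
#' mother-phase volume to the dense phase is neglected.
#'
#' @param points data.frame with columns `pH`, `I_a`, `I_a_star`, or already
#'   reduced columns `n_star_mM`, `c_IbuH_L1_mM` (returned unchanged).
#' @param c_tot Total drug concentration, mM.
#' @param pKa Acid dissociation exponent.
#' @return data.frame with columns `n_star_mM` and `c_IbuH_L1_mM`.
#' @export
reduce_partition_points <- function(points, c_tot = 3, pKa = 4.4) {
  stopifnot(is.data.frame(points))
  if (all(c("n_star_mM", "c_IbuH_L1_mM") %in% names(points)))
    return(points[, c("n_star_mM", "c_IbuH_L1_mM")])
  need <- c("pH", "I_a", "I_a_star")
  miss <- setdiff(need, names(points))
  if (length(miss))
    stop("partition table is missing column(s): ", paste(miss, collapse = ", "))
  split <- partition_from_integrals(points$I_a, points$I_a_star, c_tot = c_tot)
  data.frame(
    n_star_mM = split$n_star_per_V,
    c_IbuH_L1_mM = split$mother_total_per_V * protonated_fraction(points$pH, pKa)
  )
}

# Closed-form OLS of y on z = pmin(x, x0); returns coefficients and RSS.
segment_ols <- function(x, y, x0) {
  z <- pmin(x, x0)
  zbar <- mean(z); ybar <- mean(y)
  sxx <- sum((z - zbar)^2)
  if (sxx <= .Machine$double.eps * max(1, mean(z)^2) * length(z))
    return(list(a = NA_real_, b = NA_real_, rss = Inf, sxx = sxx))
  b <- sum((z - zbar) * (y - ybar)) / sxx
  a <- ybar - b * zbar
  list(a = a, b = b, rss = sum((y - a - b * z)^2), sxx = sxx)
}

#' Binodal limit by linear extrapolation of the pre-plateau segment
#'
#' Below the saturation plateau the mother-phase concentration rises linearly
#' with the amount held in the dense phase; extrapolating that line back to a
#' vanishing dense phase gives the lowest concentration at which two liquid
#' phases can coexist, i.e. the binodal limit. Ordinary least squares is run
#' on the points with `n_star_mM` below `breakpoint` and the intercept is the
#' binodal estimate.
#'
#' @param points data.frame with columns `n_star_mM`, `c_IbuH_L1_mM` (or raw
#'   columns accepted by [reduce_partition_points()]).
#' @param breakpoint Composition (mM) at which the plateau is taken to begin;
#'   only points strictly below it enter the fit.
#' @param c_tot,pKa Passed to [reduce_partition_points()] for raw tables.
#' @return List with `intercept` (binodal, mM), `slope`, `intercept_se`,
#'   `slope_se`, `r_squared`, `n_points`.
#' @export
fit_binodal <- function(points, breakpoint, c_tot = 3, pKa = 4.4) {
  pts <- reduce_partition_points(points, c_tot = c_tot, pKa = pKa)
  stopifnot(is.numeric(breakpoint), length(breakpoint) == 1L, breakpoint > 0)
  sel <- pts$n_star_mM < breakpoint
  if (sum(sel) < 3)
    stop("need at least 3 points below the breakpoint for the linear fit")
  x <- pts$n_star_mM[sel]; y <- pts$c_IbuH_L1_mM[sel]
  if (stats::var(x) <= .Machine$double.eps)
    stop("dense-phase amounts below the breakpoint have zero variance")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless series fit perfectly
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       intercept_se = sm$coefficients[1, 2],
       slope_se = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       n_points = sum(sel))
}

#' Locate binodal and spinodal limits with a two-segment saturation fit
#'
#' Fits the continuous piecewise model "linear rise joined to a constant
#' plateau" to the partitioning curve by least squares: for each candidate
#' breakpoint `x0` the model is linear in `pmin(n_star, x0)`, so the profile
#' residual sum of squares is scanned over a breakpoint grid and polished by
#' 1-D optimisation. The intercept of the rising segment is the binodal limit
#' and the plateau level `intercept + slope * x0` is the spinodal limit: once
#' the mother phase reaches the spinodal composition it cannot be driven any
#' further, so added drug only grows the dense phase.
#'
#' Standard errors are conditional on the fitted breakpoint. If the best
#' breakpoint sits at the upper edge of the data (fewer than two points beyond
#' it), no plateau is detectable and the spinodal is reported as undetermined
#' with a warning.
#'
#' @param points data.frame with columns `n_star_mM`, `c_IbuH_L1_mM` (or raw
#'   columns accepted by [reduce_partition_points()]).
#' @param breakpoint Optional fixed breakpoint (mM); when supplied the grid
#'   scan is skipped.
#' @param n_grid Number of candidate breakpoints in the scan.
#' @param c_tot,pKa Passed to [reduce_partition_points()] for raw tables.
#' @return Object of class `phase_boundary`: list with `binodal_mM`,
#'   `binodal_se`, `spinodal_mM`, `spinodal_se`, `slope`, `breakpoint_mM`,
#'   `spinodal_determined`, `r_squared`, `residuals`, `n_points`,
#'   `n_linear`, `n_plateau`.
#' @examples
#' n <- c(0.05, 0.15, 0.25, 0.4, 0.9, 1.4, 1.9, 2.2)
#' c_l1 <- pmin(0.43 + 0.5 * n, 0.71)
#' fit_spinodal(data.frame(n_star_mM = n, c_IbuH_L1_mM = c_l1))
#' @export
fit_spinodal <- function(points, breakpoint = NULL, n_grid = 201,
                         c_tot = 3, pKa = 4.4) {
  pts <- reduce_partition_points(points, c_tot = c_tot, pKa = pKa)
  x <- pts$n_star_mM; y <- pts$c_IbuH_L1_mM
  if (length(x) < 6)
    stop("need at least 6 points spanning the rising and plateau segments")
  ord <- order(x); x <- x[ord]; y <- y[ord]
  xmin <- x[2]; xmax <- x[length(x)]

  if (is.null(breakpoint)) {
    grid <- seq(xmin, xmax, length.out = n_grid)
    rss <- vapply(grid, function(x0) segment_ols(x, y, x0)$rss, numeric(1))
    i <- which.min(rss)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(x0) segment_ols(x, y, x0)$rss,
                           interval = c(lo, hi), tol = 1e-12)
    # keep whichever of grid best / polished best is lower
    x0 <- if (opt$objective <= rss[i]) opt$minimum else grid[i]
  } else {
    stopifnot(is.numeric(breakpoint), length(breakpoint) == 1L, breakpoint > 0)
    x0 <- breakpoint
  }

  n_plateau <- sum(x > x0)
  determined <- n_plateau >= 2 && x0 < xmax
  if (!determined)
    warning("no plateau detected: best breakpoint lies at the data edge; ",
            "spinodal is undetermined")

  ols <- segment_ols(x, y, x0)
  if (!is.finite(ols$rss))
    stop("degenerate fit: predictor has zero variance at the breakpoint")
  n <- length(x)
  dof <- n - 2L
  sigma2 <- ols$rss / dof
  z <- pmin(x, x0); zbar <- mean(z)
  var_b <- sigma2 / ols$sxx
  var_a <- sigma2 * (1 / n + zbar^2 / ols$sxx)
  cov_ab <- -sigma2 * zbar / ols$sxx
  spin <- ols$a + ols$b * x0
  spin_var <- var_a + x0^2 * var_b + 2 * x0 * cov_ab
  tss <- sum((y - mean(y))^2)

  structure(list(
    binodal_mM = ols$a,
    binodal_se = sqrt(var_a),
    spinodal_mM = if (determined) spin else NA_real_,
    spinodal_se = if (determined) sqrt(max(spin_var, 0)) else NA_real_,
    slope = ols$b,
    slope_se = sqrt(var_b),
    breakpoint_mM = x0,
    spinodal_determined = determined,
    r_squared = if (tss > 0) 1 - ols$rss / tss else NA_real_,
    residuals = y - (ols$a + ols$b * z),
    n_points = n,
    n_linear = sum(x <= x0),
    n_plateau = n_plateau
  ), class = "phase_boundary")
}

#' @export
print.phase_boundary <- function(x, ...) {
  cat("Liquid-liquid phase boundary estimate (two-segment fit)\n")
  cat(sprintf("  binodal:  %.4f +/- %.4f mM\n", x$binodal_mM, x$binodal_se))
  if (x$spinodal_determined) {
    cat(sprintf("  spinodal: %.4f +/- %.4f mM (plateau from %.4f mM, %d points)\n",
                x$spinodal_mM, x$spinodal_se, x$breakpoint_mM, x$n_plateau))
  } else {
    cat("  spinodal: undetermined (no plateau in the sampled range)\n")
  }
  cat(sprintf("  slope %.4f, R^2 %.4f, n = %d\n",
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}
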