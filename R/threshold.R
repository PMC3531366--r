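# Metabolic-threshold analysis: outward-transport vs glucokinase rate
# curves, the steady-state GK-rate surface over (epsilon1, epsilon2), the
# iso-critical-rate contour and regime classification.

#' Transporter expression scenario
#'
#' @param epsilon1,epsilon2 Membrane expression fractions of GLUT-1 and
#'   GLUT-2 relative to healthy (non-negative).
#' @param label Free-text label, e.g. `"healthy"` or `"T2D"`.
#' @return An object of class `expression_scenario`.
#' @export
expression_scenario <- function(epsilon1, epsilon2, label = "") {
  stopifnot(is.numeric(epsilon1), is.numeric(epsilon2),
            epsilon1 >= 0, epsilon2 >= 0)
  structure(list(epsilon1 = epsilon1, epsilon2 = epsilon2,
                 label = as.character(label)),
            class = "expression_scenario")
}

#' Outward transport vs glucokinase rate curves
#'
#' For a grid of intracellular glucose concentrations, the unidirectional
#' outward (export) Michaelis-Menten rates of GLUT-1 and GLUT-2 at the
#' scenario's expression levels, and the glucokinase rate.  Comparing
#' these curves locates the transition between GK-limited and
#' transport-limited G6P formation: in healthy cells outward transport far
#' exceeds the GK rate, so GK is the glucose sensor.
#'
#' @param params A [reduced_model_params()] object.
#' @param scenario An [expression_scenario()].
#' @param glucose_in_grid Non-negative intracellular glucose values (mM).
#' @return Data frame with columns `glucose_in_mM`, `outward_glut1`,
#'   `outward_glut2`, `gk_rate` (fluxes in nmol/min/1e5 cells).
#' @export
rate_comparison_curves <- function(params, scenario, glucose_in_grid) {
  stopifnot(inherits(params, "reduced_model_params"),
            inherits(scenario, "expression_scenario"))
  p <- set_epsilon(params, scenario$epsilon1, scenario$epsilon2)
  data.frame(
    glucose_in_mM = glucose_in_grid,
    outward_glut1 = mm_flux(effective_vmax(p$glut1), p$glut1$km,
                            glucose_in_grid),
    outward_glut2 = mm_flux(effective_vmax(p$glut2), p$glut2$km,
                            glucose_in_grid),
    gk_rate = gk_rate(p$gk, glucose_in_grid)
  )
}

#' Steady-state GK-rate surface over transporter expression
#'
#' Element `(i, j)` is the steady-state glucokinase rate with
#' `epsilon1 = epsilon1_grid[i]` and `epsilon2 = epsilon2_grid[j]` at the
#' given extracellular glucose.  The surface is non-decreasing along both
#' axes.
#'
#' @param params A [reduced_model_params()] object.
#' @param epsilon1_grid,epsilon2_grid Expression-fraction grids.
#' @param glucose_out Extracellular glucose (mM).
#' @return Matrix (rows: `epsilon1_grid`, columns: `epsilon2_grid`) with
#'   dimnames set to the grid values.
#' @export
gk_rate_surface <- function(params, epsilon1_grid, epsilon2_grid,
                            glucose_out = 16.8) {
  stopifnot(all(epsilon1_grid >= 0), all(epsilon2_grid >= 0))
  m <- matrix(NA_real_, length(epsilon1_grid), length(epsilon2_grid),
              dimnames = list(signif(epsilon1_grid, 8),
                              signif(epsilon2_grid, 8)))
  for (i in seq_along(epsilon1_grid)) {
    for (j in seq_along(epsilon2_grid)) {
      m[i, j] <- solve_steady_state(
        set_epsilon(params, epsilon1_grid[i], epsilon2_grid[j]),
        glucose_out)$gk_rate
    }
  }
  m
}

steady_gk_at <- function(params, e1, e2, glucose_out) {
  solve_steady_state(set_epsilon(params, e1, e2), glucose_out)$gk_rate
}

#' GLUT-2 expression at which the GK rate hits a critical level
#'
#' With GLUT-1 absent, bisects on `epsilon2` until the steady-state GK
#' rate equals `critical_rate`.  With the calibrated defaults and the
#' critical rate 0.07 nmol/min/1e5 cells this returns 0.20: the threshold
#' scenario where outward GLUT-2 transport becomes comparable to the GK
#' rate.
#'
#' @param params A [reduced_model_params()] object.
#' @param glucose_out Extracellular glucose (mM).
#' @param critical_rate Target steady-state GK rate (nmol/min/1e5 cells).
#' @param epsilon2_max Upper end of the bisection bracket.
#' @param tol Tolerance on `epsilon2`.
#' @return The expression fraction `epsilon2` (at `epsilon1 = 0`).
#' @export
find_threshold_epsilon2 <- function(params, glucose_out = 16.8,
                                    critical_rate, epsilon2_max = 1,
                                    tol = 1e-6) {
  stopifnot(critical_rate >= 0)
  if (critical_rate == 0) return(0)
  top <- steady_gk_at(params, 0, epsilon2_max, glucose_out)
  if (critical_rate > top) {
    stop("critical_rate ", critical_rate, " is unattainable: the GK rate ",
         "at epsilon2 = ", epsilon2_max, " is ", signif(top, 4),
         call. = FALSE)
  }
  if (critical_rate == top) return(epsilon2_max)
  uniroot(function(e2) steady_gk_at(params, 0, e2, glucose_out) - critical_rate,
          c(0, epsilon2_max), tol = tol)$root
}

#' Iso-critical-rate contour in the expression plane
#'
#' For each `epsilon1` in the grid, the `epsilon2` at which the
#' steady-state GK rate equals `critical_rate` (the threshold line of the
#' expression surface separating transport-limited from
#' phosphorylation-limited G6P formation).  Where GLUT-1 alone already
#' exceeds the critical rate at `epsilon2 = 0`, `epsilon2` is recorded as
#' 0 and flagged.
#'
#' @inheritParams find_threshold_epsilon2
#' @param epsilon1_grid Grid of GLUT-1 expression fractions.
#' @return Data frame with columns `epsilon1`, `epsilon2`,
#'   `glut1_compensates` (logical: GLUT-1 alone reaches the critical
#'   rate).
#' @export
iso_rate_contour <- function(params, glucose_out = 16.8, critical_rate,
                             epsilon1_grid = seq(0, 1, length.out = 101),
                             tol = 1e-6) {
  stopifnot(all(epsilon1_grid >= 0), critical_rate >= 0)
  e2 <- numeric(length(epsilon1_grid))
  comp <- logical(length(epsilon1_grid))
  for (i in seq_along(epsilon1_grid)) {
    e1 <- epsilon1_grid[i]
    at0 <- steady_gk_at(params, e1, 0, glucose_out)
    if (at0 >= critical_rate) {
      e2[i] <- 0; comp[i] <- TRUE
    } else {
      e2[i] <- uniroot(function(x) steady_gk_at(params, e1, x, glucose_out) -
                         critical_rate,
                       c(0, 1), tol = tol, extendInt = "upX")$root
    }
  }
  data.frame(epsilon1 = epsilon1_grid, epsilon2 = e2,
             glut1_compensates = comp)
}

#' Classify a scenario as transport- or phosphorylation-limited
#'
#' A scenario below the iso-critical-rate contour (steady-state GK rate
#' below the critical rate) is transport-limited: glucose entry, not GK,
#' limits G6P formation there.
#'
#' @inheritParams find_threshold_epsilon2
#' @param scenario An [expression_scenario()].
#' @return `"transport_limited"` or `"phosphorylation_limited"`.
#' @export
classify_regime <- function(params, scenario, glucose_out = 16.8,
                            critical_rate) {
  stopifnot(inherits(scenario, "expression_scenario"))
  rate <- steady_gk_at(params, scenario$epsilon1, scenario$epsilon2,
                       glucose_out)
  if (rate < critical_rate) "transport_limited" else "phosphorylation_limited"
}
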