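# Reduced kinetic model: transporter and glucokinase rate laws, parameter
# containers, and the two-state right-hand side.

#' Michaelis-Menten flux
#'
#' Rate of a saturable carrier as a function of substrate concentration,
#' `vmax * conc / (km + conc)`.
#'
#' @param vmax Maximum rate (nmol/min/1e5 cells).
#' @param km Half-saturation concentration (mM); must be positive.
#' @param conc Substrate concentration (mM); must be non-negative.
#' @return Flux in the units of `vmax`.
#' @examples
#' mm_flux(1, 17, 17)   # half-saturation identity: 0.5
#' @export
mm_flux <- function(vmax, km, conc) {
  if (any(!is.finite(km)) || any(km <= 0)) {
    stop("`km` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be non-negative and finite", call. = FALSE)
  }
  vmax * conc / (km + conc)
}

#' Transporter kinetic parameters
#'
#' Michaelis-Menten parameters for one facilitative glucose transporter
#' species, together with its membrane expression fraction `epsilon`
#' relative to a healthy beta cell.  The effective maximum rate is
#' `epsilon * vmax_normal`; it is always recomputed, never stored.
#'
#' @param name `"GLUT1"` or `"GLUT2"`.
#' @param km Half-saturation glucose concentration (mM).
#' @param vmax_normal Maximum rate at normal expression (nmol/min/1e5 cells).
#' @param epsilon Fraction of normal membrane-resident expression; values
#'   above 1 are allowed (overexpression scans), negative values are not.
#' @return An object of class `transporter_kinetics`.
#' @export
transporter_kinetics <- function(name, km, vmax_normal, epsilon = 1) {
  name <- match.arg(name, c("GLUT1", "GLUT2"))
  stopifnot(is.numeric(km), length(km) == 1L, is.numeric(vmax_normal),
            length(vmax_normal) == 1L, is.numeric(epsilon), length(epsilon) == 1L)
  if (!is.finite(km) || km <= 0) stop("`km` must be positive", call. = FALSE)
  if (!is.finite(vmax_normal) || vmax_normal < 0) {
    stop("`vmax_normal` must be non-negative", call. = FALSE)
  }
  if (!is.finite(epsilon) || epsilon < 0) {
    stop("`epsilon` must be non-negative", call. = FALSE)
  }
  structure(list(name = name, km = km, vmax_normal = vmax_normal,
                 epsilon = epsilon),
            class = "transporter_kinetics")
}

#' Effective maximum transport rate
#'
#' @param transporter A [transporter_kinetics()] object.
#' @return `epsilon * vmax_normal` (nmol/min/1e5 cells).
#' @export
effective_vmax <- function(transporter) {
  stopifnot(inherits(transporter, "transporter_kinetics"))
  transporter$epsilon * transporter$vmax_normal
}

#' Glucokinase Hill kinetics
#'
#' @param s_half Glucose concentration of half-maximal rate, S0.5 (mM).
#' @param hill_exponent Hill exponent (dimensionless).
#' @param vmax_gk Maximum phosphorylation rate (nmol/min/1e5 cells).
#' @return An object of class `gk_kinetics`.
#' @export
gk_kinetics <- function(s_half = 8, hill_exponent = 1.7, vmax_gk) {
  stopifnot(is.numeric(s_half), is.numeric(hill_exponent), is.numeric(vmax_gk))
  if (s_half <= 0) stop("`s_half` must be positive", call. = FALSE)
  if (hill_exponent <= 0) stop("`hill_exponent` must be positive", call. = FALSE)
  if (vmax_gk < 0) stop("`vmax_gk` must be non-negative", call. = FALSE)
  structure(list(s_half = s_half, hill_exponent = hill_exponent,
                 vmax_gk = vmax_gk),
            class = "gk_kinetics")
}

#' Glucokinase rate
#'
#' Hill-kinetic phosphorylation rate
#' `vmax_gk * conc^h / (s_half^h + conc^h)`.
#'
#' @param gk A [gk_kinetics()] object.
#' @param conc Intracellular glucose concentration (mM), non-negative.
#' @return Flux (nmol/min/1e5 cells).
#' @export
gk_rate <- function(gk, conc) {
  stopifnot(inherits(gk, "gk_kinetics"))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be non-negative and finite", call. = FALSE)
  }
  h <- gk$hill_exponent
  gk$vmax_gk * conc^h / (gk$s_half^h + conc^h)
}

#' Invert the glucokinase Hill curve
#'
#' Glucose concentration at which the GK rate equals `rate`.
#'
#' @param gk A [gk_kinetics()] object.
#' @param rate Target rate, in `[0, vmax_gk)`.
#' @return Concentration (mM).
#' @export
invert_gk_rate <- function(gk, rate) {
  stopifnot(inherits(gk, "gk_kinetics"))
  if (rate < 0 || rate >= gk$vmax_gk) {
    stop("`rate` must lie in [0, vmax_gk)", call. = FALSE)
  }
  if (rate == 0) return(0)
  x <- rate / gk$vmax_gk
  gk$s_half * (x / (1 - x))^(1 / gk$hill_exponent)
}

#' Net transport flux through one transporter
#'
#' Difference between the inward and outward Michaelis-Menten arms of a
#' bidirectional facilitative transporter; positive values are net uptake.
#'
#' @param transporter A [transporter_kinetics()] object.
#' @param glucose_out Extracellular glucose (mM).
#' @param glucose_in Intracellular glucose (mM).
#' @return Net flux (nmol/min/1e5 cells).
#' @export
net_transport_flux <- function(transporter, glucose_out, glucose_in) {
  v <- effective_vmax(transporter)
  mm_flux(v, transporter$km, glucose_out) - mm_flux(v, transporter$km, glucose_in)
}

#' Cell state of the reduced model
#'
#' @param glucose_in Intracellular unphosphorylated glucose (mM).
#' @param g6p_pool Cumulative phosphorylated-glucose pool (mM): G6P lumped
#'   with its downstream glycolytic derivatives, with no efflux term, so it
#'   is non-decreasing along any trajectory.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(glucose_in, g6p_pool = 0) {
  stopifnot(is.numeric(glucose_in), is.numeric(g6p_pool))
  if (glucose_in < 0 || g6p_pool < 0) {
    stop("state concentrations must be non-negative", call. = FALSE)
  }
  structure(list(glucose_in = glucose_in, g6p_pool = g6p_pool),
            class = "cell_state")
}

#' Parameters of the reduced model
#'
#' Bundles the two transporters, glucokinase, and the cytosolic volume used
#' to convert fluxes (nmol/min/1e5 cells) into concentration rates (mM/min).
#' Steady states are provably independent of the volume (it only sets the
#' kinetic timescale); the default corresponds to 1 pL per cell.
#'
#' @param glut1,glut2 [transporter_kinetics()] objects.
#' @param gk A [gk_kinetics()] object.
#' @param volume_per_1e5_cells Cytosolic volume of 1e5 cells (litres).
#' @return An object of class `reduced_model_params`.
#' @export
reduced_model_params <- function(glut1, glut2, gk, volume_per_1e5_cells = 1e-7) {
  stopifnot(inherits(glut1, "transporter_kinetics"),
            inherits(glut2, "transporter_kinetics"),
            inherits(gk, "gk_kinetics"))
  if (!is.finite(volume_per_1e5_cells) || volume_per_1e5_cells <= 0) {
    stop("`volume_per_1e5_cells` must be positive", call. = FALSE)
  }
  structure(list(glut1 = glut1, glut2 = glut2, gk = gk,
                 volume_per_1e5_cells = volume_per_1e5_cells),
            class = "reduced_model_params")
}

#' Replace the expression fractions of a parameter set
#'
#' @param params A [reduced_model_params()] object.
#' @param epsilon1,epsilon2 New membrane expression fractions for GLUT-1 and
#'   GLUT-2 (non-negative; `NULL` keeps the current value).
#' @return A modified copy of `params`.
#' @export
set_epsilon <- function(params, epsilon1 = NULL, epsilon2 = NULL) {
  stopifnot(inherits(params, "reduced_model_params"))
  if (!is.null(epsilon1)) {
    params$glut1 <- transporter_kinetics("GLUT1", params$glut1$km,
                                         params$glut1$vmax_normal, epsilon1)
  }
  if (!is.null(epsilon2)) {
    params$glut2 <- transporter_kinetics("GLUT2", params$glut2$km,
                                         params$glut2$vmax_normal, epsilon2)
  }
  params
}

# nmol/min/1e5 cells -> mM/min for the cytosol of 1e5 cells
flux_to_conc_rate <- function(flux, volume_per_1e5_cells) {
  flux * 1e-6 / volume_per_1e5_cells
}

#' Right-hand side of the reduced model
#'
#' Time derivatives of intracellular glucose and the cumulative
#' phosphorylated-glucose pool:
#' `d(glucose_in)/dt = (J_GLUT1 + J_GLUT2 - v_GK) / V`,
#' `d(g6p_pool)/dt = v_GK / V`, with the flux-to-concentration conversion
#' `V = volume_per_1e5_cells`.
#'
#' @param state A [cell_state()] object or named numeric vector with
#'   elements `glucose_in` and `g6p_pool`.
#' @param params A [reduced_model_params()] object.
#' @param glucose_out Extracellular glucose (mM).
#' @return A list with `derivatives` (named, mM/min) and `fluxes` (named,
#'   nmol/min/1e5 cells: `net_flux_glut1`, `net_flux_glut2`, `gk_rate`).
#' @export
reduced_rhs <- function(state, params, glucose_out) {
  stopifnot(inherits(params, "reduced_model_params"))
  if (inherits(state, "cell_state")) state <- unlist(state)
  g_in <- state[["glucose_in"]]
  if (g_in < 0) stop("`glucose_in` must be non-negative", call. = FALSE)
  j1 <- net_transport_flux(params$glut1, glucose_out, g_in)
  j2 <- net_transport_flux(params$glut2, glucose_out, g_in)
  vgk <- gk_rate(params$gk, g_in)
  conv <- function(f) flux_to_conc_rate(f, params$volume_per_1e5_cells)
  list(
    derivatives = c(glucose_in = conv(j1 + j2 - vgk), g6p_pool = conv(vgk)),
    fluxes = c(net_flux_glut1 = j1, net_flux_glut2 = j2, gk_rate = vgk)
  )
}
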