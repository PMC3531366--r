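# Steady-state solving and time-course simulation of the reduced model.

#' Steady state of the reduced model
#'
#' Solves the flux balance
#' `J_GLUT1(glucose_in) + J_GLUT2(glucose_in) = v_GK(glucose_in)`
#' for intracellular glucose on `[0, glucose_out]` by bracketed root
#' finding (Brent).  At the root the GK rate equals the total net
#' transport flux, so the steady state is independent of the cell volume.
#'
#' @param params A [reduced_model_params()] object.
#' @param glucose_out Extracellular glucose (mM), non-negative.
#' @param tol Absolute tolerance on `glucose_in` (mM).
#' @return A list with `glucose_in` (mM), `net_flux_glut1`,
#'   `net_flux_glut2`, `gk_rate` (nmol/min/1e5 cells), and `degenerate`
#'   (`TRUE` when both expression fractions are zero and the steady state
#'   collapses to `glucose_in = 0`).
#' @export
solve_steady_state <- function(params, glucose_out, tol = 1e-10) {
  stopifnot(inherits(params, "reduced_model_params"))
  if (!is.finite(glucose_out) || glucose_out < 0) {
    stop("`glucose_out` must be non-negative", call. = FALSE)
  }
  balance <- function(g) {
    net_transport_flux(params$glut1, glucose_out, g) +
      net_transport_flux(params$glut2, glucose_out, g) -
      gk_rate(params$gk, g)
  }
  degenerate <- (params$glut1$epsilon == 0 && params$glut2$epsilon == 0) ||
    glucose_out == 0
  if (degenerate) {
    g <- 0
  } else if (balance(glucose_out) >= 0) {
    # no consumption (vmax_gk == 0): diffusive equilibrium
    g <- glucose_out
  } else {
    g <- uniroot(balance, c(0, glucose_out), tol = tol)$root
  }
  list(
    glucose_in = g,
    net_flux_glut1 = net_transport_flux(params$glut1, glucose_out, g),
    net_flux_glut2 = net_transport_flux(params$glut2, glucose_out, g),
    gk_rate = gk_rate(params$gk, g),
    degenerate = degenerate
  )
}

#' Simulate a glucose excursion
#'
#' Integrates the reduced model through a time-dependent extracellular
#' glucose profile (for example the postprandial step from 2.8 to
#' 16.8 mM).  Integration uses a stiff-capable solver (`deSolve::lsoda`,
#' rtol 1e-8 / atol 1e-10) and is restarted at each profile breakpoint so
#' step discontinuities are handled exactly.
#'
#' @param params A [reduced_model_params()] object.
#' @param glucose_profile A [generate_profile()] object, or a function of
#'   time (min) returning extracellular glucose (mM).
#' @param t_end End time (min).
#' @param initial A [cell_state()] for `t = 0`; default is the steady state
#'   at the profile's initial glucose level, so trajectories start at rest.
#' @param n_out Approximate number of output rows.
#' @return A data frame of class `bcglut_trajectory` with columns
#'   `time_min`, `glucose_out_mM`, `glucose_in_mM`, `g6p_mM`,
#'   `net_flux_glut1`, `net_flux_glut2`, `gk_rate` (fluxes in
#'   nmol/min/1e5 cells).
#' @export
simulate_excursion <- function(params, glucose_profile, t_end,
                               initial = NULL, n_out = 401) {
  stopifnot(inherits(params, "reduced_model_params"), t_end > 0)
  prof <- as_profile_function(glucose_profile)
  breaks <- profile_breakpoints(glucose_profile)
  breaks <- sort(unique(c(0, breaks[breaks > 0 & breaks < t_end], t_end)))
  if (is.null(initial)) {
    initial <- cell_state(solve_steady_state(params, prof(0))$glucose_in, 0)
  }
  stopifnot(inherits(initial, "cell_state"))

  deriv <- function(t, y, p) {
    list(reduced_rhs(y, params, prof(t))$derivatives)
  }
  y <- c(glucose_in = initial$glucose_in, g6p_pool = initial$g6p_pool)
  out <- NULL
  dt <- t_end / (n_out - 1)
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    times <- unique(c(seq(t0, t1, by = dt), t1))
    seg <- try(deSolve::lsoda(y, times, deriv, NULL,
                              rtol = 1e-8, atol = 1e-10), silent = TRUE)
    if (inherits(seg, "try-error") ||
        attr(seg, "istate")[1L] < 0) {
      stop("ODE integration failed on [", t0, ", ", t1, "] min: ",
           if (inherits(seg, "try-error")) conditionMessage(attr(seg, "condition"))
           else paste("lsoda istate", attr(seg, "istate")[1L]),
           call. = FALSE)
    }
    seg <- as.data.frame(unclass(seg))
    y <- c(glucose_in = seg$glucose_in[nrow(seg)],
           g6p_pool = seg$g6p_pool[nrow(seg)])
    if (!is.null(out)) seg <- seg[-1L, , drop = FALSE]
    out <- rbind(out, seg)
  }
  g_out <- vapply(out$time, prof, numeric(1))
  fl <- t(vapply(seq_len(nrow(out)), function(i) {
    reduced_rhs(c(glucose_in = out$glucose_in[i], g6p_pool = out$g6p_pool[i]),
                params, g_out[i])$fluxes
  }, numeric(3)))
  res <- data.frame(
    time_min = out$time,
    glucose_out_mM = g_out,
    glucose_in_mM = out$glucose_in,
    g6p_mM = out$g6p_pool,
    net_flux_glut1 = fl[, "net_flux_glut1"],
    net_flux_glut2 = fl[, "net_flux_glut2"],
    gk_rate = fl[, "gk_rate"]
  )
  class(res) <- c("bcglut_trajectory", "data.frame")
  res
}
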