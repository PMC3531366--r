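# Algebraic calibration of the reduced model from printed steady-state
# anchors, and least-squares calibration of the regulatory network.

#' Printed steady-state anchors used for calibration
#'
#' The maximum rates of the reduced model are not published; they are
#' reconstructed from steady-state values that are: the threshold scenario
#' (no GLUT-1, GLUT-2 at 20% of normal) reaching 6.5 mM intracellular
#' glucose and a GK rate of 0.07 nmol/min/1e5 cells at 16.8 mM
#' extracellular glucose, the statement that this intracellular level is
#' 50% of normal (hence healthy 13.0 mM), and the healthy GK rate of
#' 0.12 nmol/min/1e5 cells retained as a redundancy check.
#'
#' @param km_glut1,km_glut2 Transporter half-saturation constants (mM).
#' @param s_half,hill_exponent Glucokinase Hill parameters.
#' @param glucose_out_high Extracellular glucose of the anchors (mM).
#' @param threshold_epsilon2 GLUT-2 expression fraction of the threshold
#'   scenario (GLUT-1 absent).
#' @param threshold_glucose_in,threshold_gk_rate Steady state at the
#'   threshold scenario (mM; nmol/min/1e5 cells).
#' @param healthy_glucose_in Healthy steady intracellular glucose (mM).
#' @param healthy_gk_rate Healthy steady GK rate (nmol/min/1e5 cells);
#'   redundant anchor, reported in provenance.
#' @return An object of class `calibration_anchors`.
#' @export
calibration_anchors <- function(km_glut1 = 3, km_glut2 = 17,
                                s_half = 8, hill_exponent = 1.7,
                                glucose_out_high = 16.8,
                                threshold_epsilon2 = 0.2,
                                threshold_glucose_in = 6.5,
                                threshold_gk_rate = 0.07,
                                healthy_glucose_in = 13.0,
                                healthy_gk_rate = 0.12) {
  a <- list(km_glut1 = km_glut1, km_glut2 = km_glut2, s_half = s_half,
            hill_exponent = hill_exponent, glucose_out_high = glucose_out_high,
            threshold_epsilon2 = threshold_epsilon2,
            threshold_glucose_in = threshold_glucose_in,
            threshold_gk_rate = threshold_gk_rate,
            healthy_glucose_in = healthy_glucose_in,
            healthy_gk_rate = healthy_gk_rate)
  if (any(vapply(a, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all anchors must be positive numbers", call. = FALSE)
  }
  if (!(threshold_glucose_in < healthy_glucose_in &&
        healthy_glucose_in < glucose_out_high)) {
    stop("anchors must satisfy threshold_glucose_in < healthy_glucose_in ",
         "< glucose_out_high", call. = FALSE)
  }
  structure(a, class = "calibration_anchors")
}

#' Calibrate the reduced model from steady-state anchors
#'
#' Reconstructs the three maximum rates algebraically:
#'
#' 1. `vmax_gk` from the threshold point: the Hill rate at 6.5 mM equals
#'    0.07 nmol/min/1e5 cells.
#' 2. `vmax_normal_glut2` from the threshold flux balance: at steady state
#'    with GLUT-1 absent and GLUT-2 at 20%, net GLUT-2 transport equals
#'    the GK rate.
#' 3. `vmax_normal_glut1` from the healthy flux balance at 13.0 mM.
#'
#' The printed healthy GK rate (0.12) is redundant given the other anchors;
#' its residual is reported in the provenance table rather than absorbed.
#'
#' @param anchors A [calibration_anchors()] object.
#' @param volume_per_1e5_cells Passed to [reduced_model_params()].
#' @param max_residual Hard error threshold on the relative residual of the
#'   redundant healthy-GK-rate anchor (anchor inconsistency check).
#' @return An object of class `calibrated_params`: a list with the three
#'   fitted rates, `params` (a ready-to-use [reduced_model_params()] with
#'   both expression fractions at 1), and a `provenance` data frame listing
#'   every anchor, how it was used, and its residual.
#' @export
calibrate_reduced <- function(anchors = calibration_anchors(),
                              volume_per_1e5_cells = 1e-7,
                              max_residual = 0.10) {
  stopifnot(inherits(anchors, "calibration_anchors"))
  a <- anchors
  h <- a$hill_exponent
  hillg <- function(g) g^h / (a$s_half^h + g^h)

  # (1) GK maximum rate from the threshold point
  vmax_gk <- a$threshold_gk_rate / hillg(a$threshold_glucose_in)

  # (2) GLUT-2 normal Vmax from the threshold flux balance
  b2 <- function(g_in) {
    a$glucose_out_high / (a$km_glut2 + a$glucose_out_high) -
      g_in / (a$km_glut2 + g_in)
  }
  vmax_glut2 <- a$threshold_gk_rate /
    (a$threshold_epsilon2 * b2(a$threshold_glucose_in))

  # (3) GLUT-1 normal Vmax from the healthy flux balance
  b1 <- function(g_in) {
    a$glucose_out_high / (a$km_glut1 + a$glucose_out_high) -
      g_in / (a$km_glut1 + g_in)
  }
  gk_healthy <- vmax_gk * hillg(a$healthy_glucose_in)
  vmax_glut1 <- (gk_healthy - vmax_glut2 * b2(a$healthy_glucose_in)) /
    b1(a$healthy_glucose_in)
  if (vmax_glut1 <= 0) {
    stop("anchor set is inconsistent: healthy flux balance implies a ",
         "non-positive GLUT-1 Vmax (", signif(vmax_glut1, 4), ")",
         call. = FALSE)
  }

  redundant_resid <- abs(gk_healthy - a$healthy_gk_rate) / a$healthy_gk_rate
  if (redundant_resid > max_residual) {
    stop("anchor inconsistency: healthy GK rate implied by the threshold ",
         "anchors is ", signif(gk_healthy, 4), " vs printed ",
         a$healthy_gk_rate, " (relative residual ",
         signif(redundant_resid, 3), " > ", max_residual, ")", call. = FALSE)
  }

  provenance <- data.frame(
    anchor = c("threshold_gk_rate@6.5mM", "threshold_flux_balance",
               "healthy_flux_balance@13mM", "healthy_gk_rate (redundant)"),
    role = c("defines vmax_gk", "defines vmax_normal_glut2",
             "defines vmax_normal_glut1", "consistency check"),
    target = c(a$threshold_gk_rate, a$threshold_gk_rate, 0, a$healthy_gk_rate),
    achieved = c(vmax_gk * hillg(a$threshold_glucose_in),
                 a$threshold_epsilon2 * vmax_glut2 * b2(a$threshold_glucose_in),
                 vmax_glut1 * b1(a$healthy_glucose_in) +
                   vmax_glut2 * b2(a$healthy_glucose_in) - gk_healthy,
                 gk_healthy),
    residual_rel = c(0, 0, 0, redundant_resid)
  )

  params <- reduced_model_params(
    glut1 = transporter_kinetics("GLUT1", a$km_glut1, vmax_glut1, 1),
    glut2 = transporter_kinetics("GLUT2", a$km_glut2, vmax_glut2, 1),
    gk = gk_kinetics(a$s_half, a$hill_exponent, vmax_gk),
    volume_per_1e5_cells = volume_per_1e5_cells
  )
  structure(list(vmax_gk = vmax_gk,
                 vmax_normal_glut1 = vmax_glut1,
                 vmax_normal_glut2 = vmax_glut2,
                 params = params,
                 anchors = anchors,
                 provenance = provenance),
            class = "calibrated_params")
}

#' @export
print.calibrated_params <- function(x, ...) {
  cat("Calibrated reduced-model parameters (nmol/min/1e5 cells):\n")
  cat(sprintf("  vmax_gk           = %.5f\n", x$vmax_gk))
  cat(sprintf("  vmax_normal_glut1 = %.5f\n", x$vmax_normal_glut1))
  cat(sprintf("  vmax_normal_glut2 = %.5f\n", x$vmax_normal_glut2))
  cat("Anchor provenance:\n")
  print(x$provenance, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Calibrate the regulatory network
#'
#' Fits the free parameters of the full model so that its steady states
#' reproduce the printed constraints:
#'
#' * the unperturbed steady state is the normalised healthy fixed point
#'   (all species at 1, membrane composition 80/20 GLUT-1/GLUT-2);
#' * the Type-2-diabetes scenario (a single nuclear-exclusion factor
#'   acting on both transcription factors) yields membrane expression
#'   fractions `epsilon1 = 0.14` and `epsilon2 = 0.05`;
#' * soluble-glycan competition strengths reproduce the mean printed
#'   membrane reductions (77.5% of normal for LacNAc, 52.5% for
#'   (LacNAc)3).
#'
#' The nuclear-exclusion factor is not identifiable from the printed
#' membrane fractions alone and is fixed by convention
#' (`exclusion_factor`, default 3, i.e. nuclear TF at 40% of normal); the
#' gene-specific promoter basal levels of *GLUT1* and *GLUT2* are then
#' solved exactly by bisection, and the glycan strengths in closed form.
#'
#' @param reduced A [calibrate_reduced()] result.
#' @param epsilon_t2d Target membrane fractions `c(epsilon1, epsilon2)`.
#' @param glycan_targets Target membrane fractions (both transporters) for
#'   the two soluble glycans.
#' @param exclusion_factor Nuclear-exclusion factor of the T2D scenario.
#' @param tol_epsilon Acceptable absolute error on the fitted fractions.
#' @return An object of class `full_model_fit`: list with `params` (a
#'   [regulatory_params()] set with fitted basal levels), `t2d`
#'   (a [perturbation_spec()] for the T2D scenario), `glycan_strengths`
#'   (named vector), and `report` (data frame of constraints, fitted
#'   values and residuals).
#' @export
calibrate_full <- function(reduced,
                           epsilon_t2d = c(0.14, 0.05),
                           glycan_targets = c(LacNAc = 0.775, LacNAc3 = 0.525),
                           exclusion_factor = 3,
                           tol_epsilon = 0.01) {
  stopifnot(inherits(reduced, "calibrated_params"))
  base <- regulatory_params(reduced$params)

  # membrane fraction as a function of promoter basal level, at the given
  # exclusion factor, with the MGAT4A chain already resolved
  eps_of_basal <- function(b, which, pars) {
    pars$promoter_basal[[which]] <- b
    ss <- steady_state_full(pars,
                            perturbation_spec(nuclear_exclusion_factor =
                                                exclusion_factor))
    ss[[paste0("epsilon", if (which == "GLUT1") 1 else 2)]]
  }
  fit_basal <- function(which, target) {
    f <- function(b) eps_of_basal(b, which, base) - target
    if (f(1e-9) > 0 || f(1e6) < 0) {
      stop("T2D target for ", which, " is outside the reachable range at ",
           "exclusion factor ", exclusion_factor, call. = FALSE)
    }
    uniroot(f, c(1e-9, 1e6), tol = 1e-12)$root
  }
  b1 <- fit_basal("GLUT1", epsilon_t2d[1])
  base$promoter_basal[["GLUT1"]] <- b1
  b2 <- fit_basal("GLUT2", epsilon_t2d[2])
  base$promoter_basal[["GLUT2"]] <- b2

  # glycan competition: at the healthy baseline the glycosylated pool is 1,
  # so epsilon(s) = (kon/kendo) * hillL(1/(1+s)); invert for each target
  lf <- base$lectin
  strength_for <- function(target) {
    f <- function(s) {
      (lf$k_on / lf$k_endo) *
        hill_fn(1 / (1 + s), lf$hill_n, lf$hill_k) - target
    }
    uniroot(f, c(0, 1e6), tol = 1e-12)$root
  }
  strengths <- vapply(glycan_targets, strength_for, numeric(1))

  t2d <- perturbation_spec(nuclear_exclusion_factor = exclusion_factor)
  ss_t2d <- steady_state_full(base, t2d)
  ss_healthy <- steady_state_full(base, perturbation_spec())
  glycan_fit <- vapply(strengths, function(s) {
    steady_state_full(base, perturbation_spec(
      glycan_competitor = list(name = "glycan", strength = s)))$epsilon1
  }, numeric(1))

  report <- data.frame(
    constraint = c("healthy epsilon1", "healthy epsilon2",
                   "t2d epsilon1", "t2d epsilon2",
                   paste0(names(glycan_targets), " membrane fraction")),
    target = c(1, 1, epsilon_t2d, unname(glycan_targets)),
    fitted = c(ss_healthy$epsilon1, ss_healthy$epsilon2,
               ss_t2d$epsilon1, ss_t2d$epsilon2, unname(glycan_fit))
  )
  report$residual_abs <- abs(report$fitted - report$target)
  worst <- which.max(report$residual_abs)
  if (max(report$residual_abs[3:4]) > tol_epsilon) {
    stop("regulatory-network fit failed; worst constraint: ",
         report$constraint[worst], " (residual ",
         signif(report$residual_abs[worst], 3), ")", call. = FALSE)
  }
  structure(list(params = base, t2d = t2d,
                 glycan_strengths = strengths, report = report),
            class = "full_model_fit")
}

#' @export
print.full_model_fit <- function(x, ...) {
  cat("Regulatory-network calibration\n")
  cat(sprintf("  T2D nuclear-exclusion factor: %.4g\n",
              x$t2d$nuclear_exclusion_factor))
  cat(sprintf("  promoter basal levels: GLUT1 %.4f, GLUT2 %.4f, MGAT4A %.4f\n",
              x$params$promoter_basal[["GLUT1"]],
              x$params$promoter_basal[["GLUT2"]],
              x$params$promoter_basal[["MGAT4A"]]))
  cat(sprintf("  glycan strengths: %s\n",
              paste(names(x$glycan_strengths),
                    signif(x$glycan_strengths, 4), collapse = ", ")))
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}
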