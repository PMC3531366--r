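# Scenario generation: glucose input profiles, synthetic noisy uptake
# datasets emulating fixed-glucose uptake assays, and least-squares
# recovery of transporter expression fractions from such data.

#' Extracellular glucose profile
#'
#' Builds a time-dependent extracellular glucose input for
#' [simulate_excursion()].
#'
#' * `"constant"`: `levels[1]` for all times.
#' * `"step"`: piecewise-constant; `levels[i]` holds until
#'   `switch_times[i]`, then `levels[i+1]`, etc.  The default emulates the
#'   postprandial excursion from 2.8 to 16.8 mM.
#' * `"meal"`: piecewise-linear interpolation through
#'   `(switch_times, levels[-1])` starting from `levels[1]` at `t = 0`
#'   (a smooth rise-and-decay bump); values never leave
#'   `[min(levels), max(levels)]`.
#'
#' @param kind Profile type.
#' @param levels Glucose levels (mM), non-negative.
#' @param switch_times Strictly increasing switch/knot times (min).
#' @return An object of class `glucose_profile`; use it as a function of
#'   time or pass it to [simulate_excursion()].
#' @export
generate_profile <- function(kind = c("step", "constant", "meal"),
                             levels = c(2.8, 16.8),
                             switch_times = 10) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(levels), all(levels >= 0))
  if (kind != "constant") {
    stopifnot(is.numeric(switch_times))
    if (is.unsorted(switch_times, strictly = TRUE)) {
      stop("`switch_times` must be strictly increasing", call. = FALSE)
    }
  }
  if (kind == "step" && length(levels) != length(switch_times) + 1L) {
    stop("step profile needs length(levels) == length(switch_times) + 1",
         call. = FALSE)
  }
  if (kind == "meal" && length(levels) != length(switch_times) + 1L) {
    stop("meal profile needs length(levels) == length(switch_times) + 1",
         call. = FALSE)
  }
  f <- switch(kind,
    constant = local({ lv <- levels[1]; function(t) rep(lv, length(t)) }),
    step = local({
      lv <- levels; st <- switch_times
      function(t) lv[findInterval(t, st) + 1L]
    }),
    meal = local({
      kt <- c(0, switch_times); lv <- levels
      fn <- approxfun(kt, lv, rule = 2)
      function(t) fn(t)
    })
  )
  structure(f, class = c("glucose_profile", "function"),
            kind = kind, levels = levels,
            switch_times = if (kind == "constant") numeric(0) else switch_times)
}

as_profile_function <- function(profile) {
  if (inherits(profile, "glucose_profile") || is.function(profile)) {
    return(profile)
  }
  stop("`glucose_profile` must be a function or generate_profile() object",
       call. = FALSE)
}

profile_breakpoints <- function(profile) {
  if (inherits(profile, "glucose_profile")) attr(profile, "switch_times")
  else numeric(0)
}

#' Synthetic glucose-uptake dataset
#'
#' Emulates uptake assays at fixed extracellular glucose: for each
#' expression scenario and glucose level, the deterministic steady-state
#' net transport flux (equal to the GK rate at steady state) is multiplied
#' by i.i.d. lognormal deviates with mean 1 and coefficient of variation
#' `cv`.  A single seeded generator drives all draws, so regenerating with
#' the same seed reproduces the dataset bit-exactly.
#'
#' @param params A [reduced_model_params()] or [calibrate_reduced()] object.
#' @param scenarios List of [expression_scenario()] objects.
#' @param glucose_levels Extracellular glucose concentrations (mM).
#' @param n_replicates Replicates per scenario x level.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed Integer seed.
#' @return Data frame of class `uptake_dataset` with columns `scenario`,
#'   `epsilon1`, `epsilon2`, `glucose_out_mM`, `replicate`,
#'   `uptake_nmol_min_1e5` and attributes `cv` and `seed`.
#' @export
generate_uptake_dataset <- function(params, scenarios,
                                    glucose_levels = c(2.8, 10, 16.8),
                                    n_replicates = 3, cv = 0.1, seed = 1L) {
  if (inherits(params, "calibrated_params")) params <- params$params
  stopifnot(inherits(params, "reduced_model_params"),
            is.list(scenarios), length(scenarios) > 0,
            n_replicates >= 1, cv >= 0)
  if (!all(vapply(scenarios, inherits, logical(1), "expression_scenario"))) {
    stop("`scenarios` must be a list of expression_scenario objects",
         call. = FALSE)
  }
  grid <- expand.grid(i = seq_along(scenarios),
                      glucose_out_mM = glucose_levels,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$i, grid$glucose_out_mM, grid$replicate), ]
  truth <- mapply(function(i, g_out) {
    sc <- scenarios[[i]]
    ss <- solve_steady_state(set_epsilon(params, sc$epsilon1, sc$epsilon2),
                             g_out)
    ss$net_flux_glut1 + ss$net_flux_glut2
  }, grid$i, grid$glucose_out_mM)
  sigma <- sqrt(log(1 + cv^2))
  noise <- withr_seed(seed, function() {
    if (cv == 0) rep(1, nrow(grid))
    else rlnorm(nrow(grid), meanlog = -sigma^2 / 2, sdlog = sigma)
  })
  out <- data.frame(
    scenario = vapply(scenarios[grid$i], function(s) s$label, character(1)),
    epsilon1 = vapply(scenarios[grid$i], function(s) s$epsilon1, numeric(1)),
    epsilon2 = vapply(scenarios[grid$i], function(s) s$epsilon2, numeric(1)),
    glucose_out_mM = grid$glucose_out_mM,
    replicate = grid$replicate,
    uptake_nmol_min_1e5 = truth * noise
  )
  rownames(out) <- NULL
  attr(out, "cv") <- cv
  attr(out, "seed") <- seed
  class(out) <- c("uptake_dataset", "data.frame")
  out
}

# run fn() under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Model-predicted steady-state uptake
#'
#' Steady-state total net glucose uptake (nmol/min/1e5 cells) as a
#' function of the expression fractions, vectorised over glucose levels.
#' This is the forward model behind [recover_expression()].
#'
#' @param epsilon1,epsilon2 Expression fractions.
#' @param glucose_out Vector of extracellular glucose levels (mM).
#' @param params A [reduced_model_params()] object.
#' @return Vector of uptake fluxes, one per element of `glucose_out`.
#' @export
predict_uptake <- function(epsilon1, epsilon2, glucose_out, params) {
  p <- set_epsilon(params, epsilon1, epsilon2)
  lv <- unique(glucose_out)
  u <- vapply(lv, function(g) {
    ss <- solve_steady_state(p, g)
    ss$net_flux_glut1 + ss$net_flux_glut2
  }, numeric(1))
  u[match(glucose_out, lv)]
}

#' Recover expression fractions from uptake data
#'
#' Least-squares fit of `(epsilon1, epsilon2)` to measured uptake fluxes
#' using the steady-state forward model ([predict_uptake()]), via
#' Levenberg-Marquardt with a non-negativity bound.  The two fractions
#' are separable only because the transporters' Km values differ, so the
#' data must span at least two glucose levels; with a single level the
#' design is near-collinear and a warning with the design condition
#' number is emitted.
#'
#' @param dataset A [generate_uptake_dataset()] data frame (or any data
#'   frame with columns `glucose_out_mM` and `uptake_nmol_min_1e5`).
#' @param params A [reduced_model_params()] or [calibrate_reduced()] object.
#' @param start Starting values for the two fractions.
#' @return A list of class `expression_fit`: `estimate` (named vector),
#'   `se` (named vector of standard errors), `vcov`, `residual_sd`,
#'   `condition_number` of the scaled Jacobian, and the underlying `fit`.
#' @export
recover_expression <- function(dataset, params, start = c(0.5, 0.5)) {
  if (inherits(params, "calibrated_params")) params <- params$params
  stopifnot(inherits(params, "reduced_model_params"),
            all(c("glucose_out_mM", "uptake_nmol_min_1e5") %in%
                  names(dataset)))
  n_levels <- length(unique(dataset$glucose_out_mM))
  g <- dataset$glucose_out_mM
  u <- dataset$uptake_nmol_min_1e5
  resid_fn <- function(par) predict_uptake(par[1], par[2], g, params) - u
  fit <- minpack.lm::nls.lm(
    par = c(e1 = start[1], e2 = start[2]),
    lower = c(0, 0),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- fit$par
  # Gauss-Newton covariance from a fresh finite-difference Jacobian
  h <- 1e-6
  jac_col <- function(i) {
    lo <- est; hi <- est
    hi[i] <- est[i] + h
    lo[i] <- max(est[i] - h, 0)
    (predict_uptake(hi[1], hi[2], g, params) -
       predict_uptake(lo[1], lo[2], g, params)) / (hi[i] - lo[i])
  }
  J <- cbind(jac_col(1), jac_col(2))
  dof <- length(u) - 2L
  sigma2 <- sum(resid_fn(est)^2) / dof
  vc <- tryCatch(sigma2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  sv <- svd(J)$d
  kappa <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  if (n_levels < 2) {
    warning("uptake data span a single glucose level; epsilon1 and ",
            "epsilon2 are nearly confounded (design condition number ",
            signif(kappa, 3), ")", call. = FALSE)
  }
  structure(list(
    estimate = setNames(as.numeric(est), c("epsilon1", "epsilon2")),
    se = setNames(as.numeric(se), c("epsilon1", "epsilon2")),
    vcov = vc,
    residual_sd = sqrt(sigma2),
    condition_number = kappa,
    fit = fit
  ), class = "expression_fit")
}

#' @export
print.expression_fit <- function(x, ...) {
  cat("Recovered membrane expression fractions:\n")
  for (p in names(x$estimate)) {
    cat(sprintf("  %s = %.4f (SE %.4f)\n", p, x$estimate[[p]], x$se[[p]]))
  }
  cat(sprintf("  residual SD %.4g, design condition number %.3g\n",
              x$residual_sd, x$condition_number))
  invisible(x)
}
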