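# Regulatory network: HNF1A/FOXA2 expression and nuclear translocation,
# two-layer transcriptional activation (promoter acetylation + TF binding),
# GNT-4A-dependent glycosylation, and lectin-mediated membrane residency.
#
# All species are non-dimensionalised to their healthy steady state, so the
# unperturbed fixed point is 1 for every abundance.  Rate constants are
# derived from a single turnover rate so that normalisation holds exactly.

hill_fn <- function(x, n, k = 1) x^n / (k^n + x^n)

.tf_genes <- c("HNF1A", "FOXA2")
.target_genes <- c("GLUT1", "GLUT2", "MGAT4A")
.network_genes <- c(.tf_genes, .target_genes, "CTRL")

#' Names of the full-model state variables
#'
#' Order of the named state vector used by [full_rhs()] and
#' [steady_state_full()].
#'
#' @return Character vector of length 22.
#' @export
regulatory_state_names <- function() {
  c("hnf1a_rna", "hnf1a_cyt", "hnf1a_nuc",
    "foxa2_rna", "foxa2_cyt", "foxa2_nuc",
    "acet_GLUT1", "acet_GLUT2", "acet_MGAT4A",
    "rna_GLUT1", "rna_GLUT2", "rna_MGAT4A", "rna_CTRL",
    "gnt4a_protein",
    "unglyc_GLUT1", "glyc_GLUT1", "mem_GLUT1",
    "unglyc_GLUT2", "glyc_GLUT2", "mem_GLUT2",
    "glucose_in", "g6p_pool")
}

#' Parameters of the regulatory network
#'
#' Structural constants of the full model.  Species are normalised to
#' their healthy steady state; the rate constants of each module are
#' derived from one turnover rate (`deg_rate`) so that the all-ones state
#' is an exact fixed point of the unperturbed system:
#' transcription-factor import/export satisfy `k_in = k_out + deg_rate`,
#' target transcription rates equal `deg_rate` times the promoter
#' activation multiplier, glycosylation conversion equals `deg_rate`, and
#' lectin-mediated membrane delivery balances endocytic turnover.
#'
#' Both transcriptional layers carry basal (TF-independent) terms:
#' `acet_basal` for nucleosome acetylation and per-gene `promoter_basal`
#' for transcription.  The basal levels of *GLUT1* and *GLUT2* are the
#' gene-specific free parameters fitted by [calibrate_full()]; they are
#' what lets a single shared nuclear-exclusion factor produce unequal
#' reductions of the two transporters.
#'
#' @param reduced A [reduced_model_params()] object (metabolic layer).
#' @param deg_rate First-order turnover rate shared by RNAs and proteins
#'   (1/min).
#' @param tf_k_out Nuclear export rate of the transcription factors (1/min).
#' @param acet_basal,acet_tf,acet_deac Acetylation gain (basal and
#'   HNF1A-dependent) and deacetylation rate (1/min).
#' @param acet_hill_n,promoter_hill_n,lectin_hill_n Hill exponents of
#'   HNF1A-driven acetylation, TF-promoter binding, and lectin binding.
#' @param promoter_basal Named list of basal transcription levels for
#'   GLUT1, GLUT2, MGAT4A (relative to the TF-driven part at baseline).
#' @param w_hnf1a,w_foxa2 Promoter binding weights of the two TFs.
#' @param k_endo Endocytic removal rate of membrane transporters (1/min).
#' @return An object of class `regulatory_params`.
#' @export
regulatory_params <- function(reduced,
                              deg_rate = 0.1,
                              tf_k_out = 0.1,
                              acet_basal = 0.1, acet_tf = 0.1,
                              acet_deac = 0.1,
                              acet_hill_n = 2,
                              promoter_hill_n = 4,
                              lectin_hill_n = 2,
                              promoter_basal = list(GLUT1 = 0.5, GLUT2 = 0.5,
                                                    MGAT4A = 0.5),
                              w_hnf1a = 0.5, w_foxa2 = 0.5,
                              k_endo = 0.1) {
  stopifnot(inherits(reduced, "reduced_model_params"),
            deg_rate > 0, tf_k_out > 0, k_endo > 0,
            all(.target_genes %in% names(promoter_basal)))
  # baseline (all species = 1) must be a fixed point: derive dependent rates
  k_in <- tf_k_out + deg_rate
  tf <- list(k_tx = deg_rate, k_tl = deg_rate + k_in - tf_k_out,
             k_in = k_in, k_out = tf_k_out, deg = deg_rate)
  acet <- list(k_basal = acet_basal, k_tf = acet_tf, k_deac = acet_deac,
               hill_n = acet_hill_n, hill_k = 1)
  acet$baseline <- {
    r <- acet_basal + acet_tf * hill_fn(1, acet_hill_n)
    r / (r + acet_deac)
  }
  promoter <- list(hill_n = promoter_hill_n, hill_k = 1,
                   w_hnf1a = w_hnf1a, w_foxa2 = w_foxa2,
                   basal = promoter_basal)
  transporter <- list(k_gly = deg_rate, k_syn = 2 * deg_rate, deg = deg_rate)
  lectin <- list(hill_n = lectin_hill_n, hill_k = 1, k_endo = k_endo,
                 k_on = k_endo / hill_fn(1, lectin_hill_n))
  structure(list(reduced = reduced, deg = deg_rate, tf = tf, acet = acet,
                 promoter = promoter, promoter_basal = promoter_basal,
                 transporter = transporter, lectin = lectin,
                 healthy_split = c(GLUT1 = 0.8, GLUT2 = 0.2)),
            class = "regulatory_params")
}

#' Declarative in-silico perturbation
#'
#' @param nuclear_exclusion_factor Non-negative multiplier `f` reducing TF
#'   nuclear import by `1/(1 + f)`; 0 means no exclusion.  A single factor
#'   acts on both HNF1A and FOXA2.
#' @param glycan_competitor List with `name` and non-negative `strength`;
#'   a soluble glycan competing with glycosylated transporters for lectin
#'   binding (the effective ligand is divided by `1 + strength`).
#' @param rna_clamp Optional named list/vector clamping RNA species
#'   (genes among HNF1A, FOXA2, GLUT1, GLUT2, MGAT4A, CTRL) at fixed
#'   abundances.
#' @param epsilon_override Optional `c(epsilon1, epsilon2)` bypassing the
#'   network when computing the metabolic layer.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(nuclear_exclusion_factor = 0,
                              glycan_competitor = list(name = "none",
                                                       strength = 0),
                              rna_clamp = NULL,
                              epsilon_override = NULL) {
  stopifnot(is.numeric(nuclear_exclusion_factor),
            nuclear_exclusion_factor >= 0,
            is.list(glycan_competitor),
            glycan_competitor$strength >= 0)
  if (!is.null(rna_clamp)) {
    rna_clamp <- as.list(rna_clamp)
    bad <- setdiff(names(rna_clamp), .network_genes)
    if (length(bad)) {
      stop("unknown gene(s) in rna_clamp: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(unlist(rna_clamp) < 0)) {
      stop("clamped RNA abundances must be non-negative", call. = FALSE)
    }
  }
  if (!is.null(epsilon_override)) {
    stopifnot(length(epsilon_override) == 2L, all(epsilon_override >= 0))
  }
  structure(list(nuclear_exclusion_factor = nuclear_exclusion_factor,
                 glycan_competitor = glycan_competitor,
                 rna_clamp = rna_clamp,
                 epsilon_override = epsilon_override),
            class = "perturbation_spec")
}

clamp_value <- function(perturbation, gene) {
  if (is.null(perturbation$rna_clamp)) return(NULL)
  perturbation$rna_clamp[[gene]]
}

#' Transcription-factor dynamics
#'
#' Mass-action dynamics of one TF's RNA, cytoplasmic protein and nuclear
#' protein.  Nuclear import is scaled by `1/(1 + f)` where `f` is the
#' perturbation's nuclear-exclusion factor; export and degradation both
#' act on the nuclear pool.
#'
#' @param state Named numeric vector containing `<tf>_rna`, `<tf>_cyt`,
#'   `<tf>_nuc` for `tf` in `hnf1a`, `foxa2` (as produced by
#'   [healthy_regulatory_state()]).
#' @param params A [regulatory_params()] object.
#' @param perturbation A [perturbation_spec()].
#' @return Named vector of time derivatives for the six TF states.
#' @export
tf_rhs <- function(state, params, perturbation = perturbation_spec()) {
  stopifnot(inherits(params, "regulatory_params"))
  if (any(state[c("hnf1a_rna", "hnf1a_cyt", "hnf1a_nuc",
                  "foxa2_rna", "foxa2_cyt", "foxa2_nuc")] < 0)) {
    stop("TF state must be non-negative", call. = FALSE)
  }
  tf <- params$tf
  I <- 1 / (1 + perturbation$nuclear_exclusion_factor)
  d <- numeric(0)
  for (g in c("hnf1a", "foxa2")) {
    gene <- toupper(g)
    r <- state[[paste0(g, "_rna")]]
    cyt <- state[[paste0(g, "_cyt")]]
    nuc <- state[[paste0(g, "_nuc")]]
    dr <- if (is.null(clamp_value(perturbation, gene))) tf$k_tx - tf$deg * r else 0
    dc <- tf$k_tl * r - tf$deg * cyt - tf$k_in * I * cyt + tf$k_out * nuc
    dn <- tf$k_in * I * cyt - tf$k_out * nuc - tf$deg * nuc
    d <- c(d, setNames(c(dr, dc, dn),
                       paste0(g, c("_rna", "_cyt", "_nuc"))))
  }
  d
}

#' Promoter activation multiplier
#'
#' Transcription-rate multiplier of a target gene: the acetylation level
#' (relative to baseline) times the basal-plus-TF-binding term,
#' `(b_g + w_H hill(n_HNF1A) + w_F hill(n_FOXA2))`, normalised so the
#' multiplier is exactly 1 at the healthy baseline.  With both TFs absent
#' the multiplier falls to its basal floor, not to zero.
#'
#' @param nuclear_hnf1a,nuclear_foxa2 Nuclear TF abundances (normalised).
#' @param acetylation Promoter acetylation level in `[0, 1]`.
#' @param params A [regulatory_params()] object.
#' @param gene `"GLUT1"`, `"GLUT2"` or `"MGAT4A"`.
#' @return Non-negative multiplier (1 at the healthy baseline).
#' @export
promoter_activation <- function(nuclear_hnf1a, nuclear_foxa2, acetylation,
                                params, gene = "GLUT1") {
  stopifnot(nuclear_hnf1a >= 0, nuclear_foxa2 >= 0,
            acetylation >= 0, acetylation <= 1)
  gene <- match.arg(gene, .target_genes)
  pr <- params$promoter
  b <- params$promoter_basal[[gene]]
  binding <- b + pr$w_hnf1a * hill_fn(nuclear_hnf1a, pr$hill_n, pr$hill_k) +
    pr$w_foxa2 * hill_fn(nuclear_foxa2, pr$hill_n, pr$hill_k)
  binding_base <- b + (pr$w_hnf1a + pr$w_foxa2) * hill_fn(1, pr$hill_n, pr$hill_k)
  (acetylation / params$acet$baseline) * binding / binding_base
}

#' Promoter acetylation dynamics
#'
#' `da/dt = (k_basal + k_tf * hill(n_HNF1A)) * (1 - a) - k_deac * a`;
#' bounded in `[0, 1]`.  HNF1A drives hyperacetylation on top of a basal
#' acetylation gain.
#'
#' @param acetylation Current level in `[0, 1]`.
#' @param nuclear_hnf1a Nuclear HNF1A abundance (normalised).
#' @param params A [regulatory_params()] object.
#' @return Time derivative of the acetylation level.
#' @export
acetylation_rhs <- function(acetylation, nuclear_hnf1a, params) {
  stopifnot(acetylation >= 0, acetylation <= 1, nuclear_hnf1a >= 0)
  ac <- params$acet
  gain <- ac$k_basal + ac$k_tf * hill_fn(nuclear_hnf1a, ac$hill_n, ac$hill_k)
  gain * (1 - acetylation) - ac$k_deac * acetylation
}

steady_acetylation <- function(nuclear_hnf1a, params) {
  ac <- params$acet
  gain <- ac$k_basal + ac$k_tf * hill_fn(nuclear_hnf1a, ac$hill_n, ac$hill_k)
  gain / (gain + ac$k_deac)
}

#' Glycosylation dynamics of one transporter
#'
#' Synthesis of the unglycosylated pool proportional to the transporter's
#' RNA, mass-action conversion to the glycosylated form proportional to
#' GNT-4A, and first-order degradation of both pools.  Kinetic constants
#' are identical for GLUT-1 and GLUT-2.
#'
#' @param unglycosylated,glycosylated Pool abundances (normalised); may be
#'   vectors (one element per transporter).
#' @param gnt4a_protein GNT-4A enzyme abundance (normalised).
#' @param rna The transporter's RNA abundance (normalised).
#' @param params A [regulatory_params()] object.
#' @return List with derivatives `unglycosylated` and `glycosylated`.
#' @export
glycosylation_rhs <- function(unglycosylated, glycosylated, gnt4a_protein,
                              rna, params) {
  stopifnot(all(unglycosylated >= 0), all(glycosylated >= 0),
            gnt4a_protein >= 0, all(rna >= 0))
  tr <- params$transporter
  conv <- tr$k_gly * gnt4a_protein * unglycosylated
  list(unglycosylated = tr$k_syn * rna - conv - tr$deg * unglycosylated,
       glycosylated = conv - tr$deg * glycosylated)
}

#' Membrane residency dynamics
#'
#' Lectin-mediated delivery to (and retention at) the plasma membrane,
#' `dm/dt = k_on * hillL(y / (1 + s)) - k_endo * m`, where `y` is the
#' glycosylated pool and `s` the strength of a soluble glycan competitor
#' that dilutes the effective lectin ligand (competitive binding).  Only
#' glycosylated transporters reach stable membrane residency.
#'
#' @param membrane Membrane-resident abundance (normalised); vectorised.
#' @param glycosylated Glycosylated pool abundance; vectorised.
#' @param params A [regulatory_params()] object.
#' @param competitor_strength Non-negative competitor strength `s`.
#' @return Time derivative of the membrane pool.
#' @export
membrane_residency_rhs <- function(membrane, glycosylated, params,
                                   competitor_strength = 0) {
  stopifnot(all(membrane >= 0), all(glycosylated >= 0),
            competitor_strength >= 0)
  lf <- params$lectin
  lf$k_on * hill_fn(glycosylated / (1 + competitor_strength),
                    lf$hill_n, lf$hill_k) - lf$k_endo * membrane
}

#' Healthy reference state of the full model
#'
#' All normalised abundances at 1, acetylation at its baseline, and the
#' metabolic layer at its steady state for the given extracellular
#' glucose.
#'
#' @param params A [regulatory_params()] object.
#' @param glucose_out Extracellular glucose (mM).
#' @return Named numeric state vector (see `regulatory_state_names`).
#' @export
healthy_regulatory_state <- function(params, glucose_out = 16.8) {
  stopifnot(inherits(params, "regulatory_params"))
  s <- setNames(rep(1, length(regulatory_state_names())),
                regulatory_state_names())
  s[c("acet_GLUT1", "acet_GLUT2", "acet_MGAT4A")] <- params$acet$baseline
  s["glucose_in"] <- solve_steady_state(
    set_epsilon(params$reduced, 1, 1), glucose_out)$glucose_in
  s["g6p_pool"] <- 0
  s
}

#' Right-hand side of the full model
#'
#' Concatenates the TF, acetylation, target-gene RNA, GNT-4A,
#' glycosylation, membrane-residency and metabolic derivatives.  The
#' effective expression fractions of the metabolic layer are read from the
#' membrane pools (or taken from the perturbation's `epsilon_override`).
#' Clamped RNA species have derivative zero.
#'
#' @param state Named numeric vector over `regulatory_state_names()`.
#' @param params A [regulatory_params()] object.
#' @param perturbation A [perturbation_spec()].
#' @param glucose_out Extracellular glucose (mM).
#' @return List with `derivatives` (named vector), `epsilon1`, `epsilon2`,
#'   and the metabolic `fluxes`.
#' @export
full_rhs <- function(state, params, perturbation = perturbation_spec(),
                     glucose_out = 16.8) {
  stopifnot(inherits(params, "regulatory_params"),
            inherits(perturbation, "perturbation_spec"))
  nm <- regulatory_state_names()
  if (!all(nm %in% names(state))) {
    stop("`state` must contain all ", length(nm), " model variables",
         call. = FALSE)
  }
  d <- setNames(numeric(length(nm)), nm)

  d[names(tf_rhs(state, params, perturbation))] <-
    tf_rhs(state, params, perturbation)

  n_h <- state[["hnf1a_nuc"]]; n_f <- state[["foxa2_nuc"]]
  for (g in .target_genes) {
    a <- min(max(state[[paste0("acet_", g)]], 0), 1)
    d[paste0("acet_", g)] <- acetylation_rhs(a, n_h, params)
    act <- promoter_activation(n_h, n_f, a, params, g)
    d[paste0("rna_", g)] <-
      if (is.null(clamp_value(perturbation, g))) {
        params$deg * act - params$deg * state[[paste0("rna_", g)]]
      } else 0
  }
  d["rna_CTRL"] <- if (is.null(clamp_value(perturbation, "CTRL"))) {
    params$deg * (1 - state[["rna_CTRL"]])
  } else 0
  d["gnt4a_protein"] <- params$deg *
    (state[["rna_MGAT4A"]] - state[["gnt4a_protein"]])

  s <- perturbation$glycan_competitor$strength
  for (g in c("GLUT1", "GLUT2")) {
    gl <- glycosylation_rhs(state[[paste0("unglyc_", g)]],
                            state[[paste0("glyc_", g)]],
                            state[["gnt4a_protein"]],
                            state[[paste0("rna_", g)]], params)
    d[paste0("unglyc_", g)] <- gl$unglycosylated
    d[paste0("glyc_", g)] <- gl$glycosylated
    d[paste0("mem_", g)] <- membrane_residency_rhs(
      state[[paste0("mem_", g)]], state[[paste0("glyc_", g)]], params, s)
  }

  if (is.null(perturbation$epsilon_override)) {
    eps1 <- state[["mem_GLUT1"]]; eps2 <- state[["mem_GLUT2"]]
  } else {
    eps1 <- perturbation$epsilon_override[1]
    eps2 <- perturbation$epsilon_override[2]
  }
  met <- reduced_rhs(c(glucose_in = max(state[["glucose_in"]], 0),
                       g6p_pool = state[["g6p_pool"]]),
                     set_epsilon(params$reduced, eps1, eps2), glucose_out)
  d["glucose_in"] <- met$derivatives[["glucose_in"]]
  d["g6p_pool"] <- met$derivatives[["g6p_pool"]]
  list(derivatives = d, epsilon1 = eps1, epsilon2 = eps2,
       fluxes = met$fluxes)
}

#' Steady state of the full model
#'
#' The regulatory cascade is feed-forward (TFs -> acetylation/RNA ->
#' proteins -> pools -> membrane fractions -> metabolism), so the default
#' method solves each module algebraically in sequence; `method = "ode"`
#' instead integrates [full_rhs()] to stationarity (the cumulative
#' phosphorylated pool is excluded from the stationarity check) and is
#' used as an independent cross-check.
#'
#' @param params A [regulatory_params()] object.
#' @param perturbation A [perturbation_spec()].
#' @param glucose_out Extracellular glucose (mM).
#' @param method `"algebraic"` or `"ode"`.
#' @param t_max,tol ODE-method controls: maximum integration time (min)
#'   and stationarity tolerance on the derivatives.
#' @return List with `state` (named vector), `epsilon1`, `epsilon2`,
#'   `glucose_in`, `gk_rate`, `fluxes`, `composition` (membrane molecule
#'   fractions of GLUT-1/GLUT-2) and `method`.
#' @export
steady_state_full <- function(params, perturbation = perturbation_spec(),
                              glucose_out = 16.8,
                              method = c("algebraic", "ode"),
                              t_max = 20000, tol = 1e-8) {
  stopifnot(inherits(params, "regulatory_params"),
            inherits(perturbation, "perturbation_spec"))
  method <- match.arg(method)
  if (method == "algebraic") {
    res <- steady_full_algebraic(params, perturbation, glucose_out)
  } else {
    res <- steady_full_ode(params, perturbation, glucose_out, t_max, tol)
  }
  res$composition <- membrane_composition(res$epsilon1, res$epsilon2,
                                          params$healthy_split)
  res$method <- method
  res
}

steady_full_algebraic <- function(params, pert, glucose_out) {
  tf <- params$tf
  I <- 1 / (1 + pert$nuclear_exclusion_factor)
  tf_block <- function(gene) {
    cl <- clamp_value(pert, gene)
    r <- if (is.null(cl)) tf$k_tx / tf$deg else cl
    cyt <- tf$k_tl * r / (tf$deg * (1 + tf$k_in * I / (tf$k_out + tf$deg)))
    nuc <- tf$k_in * I * cyt / (tf$k_out + tf$deg)
    c(rna = r, cyt = cyt, nuc = nuc)
  }
  hn <- tf_block("HNF1A"); fx <- tf_block("FOXA2")
  a <- steady_acetylation(hn[["nuc"]], params)
  rna <- setNames(numeric(3), .target_genes)
  for (g in .target_genes) {
    cl <- clamp_value(pert, g)
    rna[g] <- if (is.null(cl)) {
      promoter_activation(hn[["nuc"]], fx[["nuc"]], a, params, g)
    } else cl
  }
  ctrl <- clamp_value(pert, "CTRL"); if (is.null(ctrl)) ctrl <- 1
  p <- rna[["MGAT4A"]]
  tr <- params$transporter
  u <- tr$k_syn * rna[c("GLUT1", "GLUT2")] / (tr$k_gly * p + tr$deg)
  y <- tr$k_gly * p * u / tr$deg
  s <- pert$glycan_competitor$strength
  lf <- params$lectin
  mem <- (lf$k_on / lf$k_endo) * hill_fn(y / (1 + s), lf$hill_n, lf$hill_k)

  if (is.null(pert$epsilon_override)) {
    eps1 <- mem[["GLUT1"]]; eps2 <- mem[["GLUT2"]]
  } else {
    eps1 <- pert$epsilon_override[1]; eps2 <- pert$epsilon_override[2]
  }
  met <- solve_steady_state(set_epsilon(params$reduced, eps1, eps2),
                            glucose_out)
  state <- setNames(numeric(length(regulatory_state_names())),
                    regulatory_state_names())
  state[c("hnf1a_rna", "hnf1a_cyt", "hnf1a_nuc")] <- hn
  state[c("foxa2_rna", "foxa2_cyt", "foxa2_nuc")] <- fx
  state[c("acet_GLUT1", "acet_GLUT2", "acet_MGAT4A")] <- a
  state[paste0("rna_", .target_genes)] <- rna
  state["rna_CTRL"] <- ctrl
  state["gnt4a_protein"] <- p
  state[c("unglyc_GLUT1", "unglyc_GLUT2")] <- u
  state[c("glyc_GLUT1", "glyc_GLUT2")] <- y
  state[c("mem_GLUT1", "mem_GLUT2")] <- mem
  state["glucose_in"] <- met$glucose_in
  state["g6p_pool"] <- 0
  list(state = state, epsilon1 = eps1, epsilon2 = eps2,
       glucose_in = met$glucose_in, gk_rate = met$gk_rate,
       fluxes = c(net_flux_glut1 = met$net_flux_glut1,
                  net_flux_glut2 = met$net_flux_glut2,
                  gk_rate = met$gk_rate))
}

steady_full_ode <- function(params, pert, glucose_out, t_max, tol) {
  y0 <- healthy_regulatory_state(params, glucose_out)
  for (g in names(pert$rna_clamp)) {
    nm <- if (g == "HNF1A") "hnf1a_rna" else if (g == "FOXA2") "foxa2_rna"
          else paste0("rna_", g)
    y0[nm] <- pert$rna_clamp[[g]]
  }
  deriv <- function(t, y, p) {
    list(full_rhs(y, params, pert, glucose_out)$derivatives)
  }
  moving <- setdiff(regulatory_state_names(), "g6p_pool")
  t_hi <- 2000
  repeat {
    out <- deSolve::lsoda(y0, c(0, t_hi), deriv, NULL,
                          rtol = 1e-10, atol = 1e-12)
    y <- out[nrow(out), regulatory_state_names()]
    dmax <- max(abs(full_rhs(y, params, pert, glucose_out)$derivatives[moving]))
    if (dmax < tol || t_hi >= t_max) break
    y0 <- y
    t_hi <- t_hi * 4
  }
  if (dmax >= tol) {
    stop("full model did not reach stationarity by t = ", t_max,
         " min (max |d/dt| = ", signif(dmax, 3), ")", call. = FALSE)
  }
  rhs <- full_rhs(y, params, pert, glucose_out)
  list(state = y, epsilon1 = rhs$epsilon1, epsilon2 = rhs$epsilon2,
       glucose_in = y[["glucose_in"]],
       gk_rate = rhs$fluxes[["gk_rate"]], fluxes = rhs$fluxes)
}

#' Membrane molecule composition
#'
#' Molecule fractions of GLUT-1 and GLUT-2 at the plasma membrane, given
#' expression fractions relative to healthy and the healthy molecule
#' split (80% GLUT-1 / 20% GLUT-2):
#' `frac_GLUT1 = 0.8 eps1 / (0.8 eps1 + 0.2 eps2)`.
#'
#' @param epsilon1,epsilon2 Membrane expression fractions.
#' @param healthy_split Healthy molecule fractions (must sum to 1).
#' @return Named vector `c(GLUT1 = ..., GLUT2 = ...)` summing to 1 (both
#'   `NaN` when both fractions are zero).
#' @export
membrane_composition <- function(epsilon1, epsilon2,
                                 healthy_split = c(GLUT1 = 0.8, GLUT2 = 0.2)) {
  stopifnot(epsilon1 >= 0, epsilon2 >= 0,
            abs(sum(healthy_split) - 1) < 1e-12)
  w <- c(GLUT1 = unname(healthy_split[["GLUT1"]] * epsilon1),
         GLUT2 = unname(healthy_split[["GLUT2"]] * epsilon2))
  w / sum(w)
}
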