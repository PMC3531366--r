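# Local sensitivity analysis of the steady-state glucokinase rate with
# respect to RNA abundances, used to rank therapeutic control points in
# the perturbed (T2D) full model.

#' Normalised sensitivity coefficient of the GK rate to one RNA
#'
#' Computes `S = (RNA_j / v_GK) * d v_GK / d RNA_j` at the perturbed
#' steady state by clamping the gene's RNA at `(1 +/- rel_step)` times its
#' steady value, re-solving the downstream steady state (the cascade is
#' feed-forward), and central-differencing the steady-state GK rate.
#' The clamp interpretation matches the normalisation by RNA abundance:
#' the perturbation fixes the RNA pool itself, not a transcription rate.
#'
#' `gene = "CTRL"` is an inert negative-control RNA with no downstream
#' targets; its coefficient is exactly zero.
#'
#' @param params A [regulatory_params()] object (typically the fitted set
#'   from [calibrate_full()]).
#' @param gene One of `"HNF1A"`, `"FOXA2"`, `"MGAT4A"`, `"GLUT1"`,
#'   `"GLUT2"`, `"CTRL"`.
#' @param glucose_out Extracellular glucose (mM).
#' @param perturbation Background perturbation defining the reference
#'   state (default: none; pass the fitted T2D spec to rank therapeutic
#'   targets in disease).
#' @param rel_step Relative finite-difference step, in `(0, 0.1]`.
#' @return A one-row data frame of class `sensitivity_result` with columns
#'   `gene`, `glucose_out_mM`, `coefficient`, `rel_step`.
#' @export
sensitivity_coefficient <- function(params, gene, glucose_out = 16.8,
                                    perturbation = perturbation_spec(),
                                    rel_step = 0.01) {
  stopifnot(inherits(params, "regulatory_params"),
            inherits(perturbation, "perturbation_spec"))
  gene <- match.arg(gene, .network_genes)
  if (!is.finite(rel_step) || rel_step <= 0 || rel_step > 0.1) {
    stop("`rel_step` must lie in (0, 0.1]", call. = FALSE)
  }
  base <- steady_state_full(params, perturbation, glucose_out)
  v0 <- base$gk_rate
  if (v0 <= 0) stop("baseline GK rate is zero; sensitivity undefined",
                    call. = FALSE)
  rna0 <- baseline_rna(base$state, gene)
  v_at <- function(mult) {
    pert <- perturbation
    pert$rna_clamp <- modifyList(as.list(pert$rna_clamp),
                                 setNames(list(rna0 * mult), gene))
    steady_state_full(params, pert, glucose_out)$gk_rate
  }
  coefficient <- (v_at(1 + rel_step) - v_at(1 - rel_step)) /
    (2 * rel_step * v0)
  out <- data.frame(gene = gene, glucose_out_mM = glucose_out,
                    coefficient = coefficient, rel_step = rel_step)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

baseline_rna <- function(state, gene) {
  nm <- switch(gene,
               HNF1A = "hnf1a_rna", FOXA2 = "foxa2_rna",
               paste0("rna_", gene))
  state[[nm]]
}

#' Sensitivity table across genes and glucose levels
#'
#' Full cross-product of [sensitivity_coefficient()] over the requested
#' genes and extracellular glucose concentrations; deterministic given the
#' model and step.
#'
#' @inheritParams sensitivity_coefficient
#' @param genes Character vector of gene labels.
#' @param glucose_levels Extracellular glucose concentrations (mM).
#' @return Data frame with one row per gene x glucose level, columns as in
#'   [sensitivity_coefficient()].
#' @export
sensitivity_table <- function(params,
                              genes = c("HNF1A", "FOXA2", "MGAT4A",
                                        "GLUT1", "GLUT2"),
                              glucose_levels = c(2.8, 16.8),
                              perturbation = perturbation_spec(),
                              rel_step = 0.01) {
  rows <- lapply(glucose_levels, function(g_out) {
    do.call(rbind, lapply(genes, function(g) {
      sensitivity_coefficient(params, g, g_out, perturbation, rel_step)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
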