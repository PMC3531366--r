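# Shared fixtures: calibrated parameter sets built once per test run.

cal_fix <- calibrate_reduced()
params_fix <- cal_fix$params
full_fix <- calibrate_full(cal_fix)

t2d_scenario <- expression_scenario(0.14, 0.05, "T2D")
healthy_scenario <- expression_scenario(1, 1, "healthy")

# independently coded steady acetylation level (mini-oracle for the
# basal + HNF1A-driven acetylation layer)
steady_acetylation_at <- function(nuclear_hnf1a, params) {
  ac <- params$acet
  gain <- ac$k_basal +
    ac$k_tf * nuclear_hnf1a^ac$hill_n / (1 + nuclear_hnf1a^ac$hill_n)
  gain / (gain + ac$k_deac)
}

# steady-state GK rate shortcut used across threshold tests
gk_at <- function(e1, e2, glucose_out = 16.8, params = params_fix) {
  solve_steady_state(set_epsilon(params, e1, e2), glucose_out)$gk_rate
}
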