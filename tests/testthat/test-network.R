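# Regulatory network: fixed point, perturbations, module behaviour.

test_that("the healthy state is an exact fixed point of the full model", {
  st <- healthy_regulatory_state(full_fix$params, 16.8)
  rhs <- full_rhs(st, full_fix$params, perturbation_spec(), 16.8)
  moving <- setdiff(regulatory_state_names(), "g6p_pool")
  expect_lt(max(abs(rhs$derivatives[moving])), 1e-10)
  expect_equal(rhs$epsilon1, 1)
  expect_equal(rhs$epsilon2, 1)
})

test_that("an all-neutral perturbation leaves the steady state untouched", {
  base <- steady_state_full(full_fix$params, perturbation_spec())
  neutral <- perturbation_spec(nuclear_exclusion_factor = 0,
                               glycan_competitor = list(name = "x",
                                                        strength = 0))
  pert <- steady_state_full(full_fix$params, neutral)
  expect_lt(max(abs(pert$state - base$state)), 1e-12)
})

test_that("nuclear TF pools fall monotonically with the exclusion factor", {
  nuc <- vapply(c(0, 0.5, 1, 2, 4, 8, 1e4), function(f) {
    steady_state_full(full_fix$params,
                      perturbation_spec(nuclear_exclusion_factor = f)
                      )$state[["hnf1a_nuc"]]
  }, numeric(1))
  expect_equal(nuc[1], 1, tolerance = 1e-10)
  expect_true(all(diff(nuc) < 0))
  expect_lt(tail(nuc, 1), 1e-3)   # f -> Inf drains the nucleus
})

test_that("promoter activation is normalised and HNF1A outranks FOXA2", {
  p <- full_fix$params
  a0 <- p$acet$baseline
  expect_equal(promoter_activation(1, 1, a0, p, "GLUT2"), 1)
  # with both TFs absent the multiplier falls to its basal floor
  floor_val <- promoter_activation(0, 0, steady_acetylation_at(0, p), p,
                                   "GLUT2")
  expect_gt(floor_val, 0)
  expect_lt(floor_val, 1)
  # halving HNF1A (with the acetylation layer responding) cuts activation
  # more than halving FOXA2, because HNF1A acts on both layers
  act_h <- promoter_activation(0.5, 1, steady_acetylation_at(0.5, p), p,
                               "GLUT2")
  act_f <- promoter_activation(1, 0.5, steady_acetylation_at(1, p), p,
                               "GLUT2")
  expect_lt(act_h, act_f)
})

test_that("acetylation dynamics stay bounded with a basal floor", {
  p <- full_fix$params
  # baseline is a fixed point
  expect_equal(acetylation_rhs(p$acet$baseline, 1, p), 0, tolerance = 1e-12)
  # steady level is monotone in nuclear HNF1A, with a positive floor
  lv <- vapply(c(0, 0.25, 0.5, 1, 2), steady_acetylation_at, numeric(1),
               params = p)
  expect_true(all(diff(lv) > 0))
  floor_expect <- p$acet$k_basal / (p$acet$k_basal + p$acet$k_deac)
  expect_equal(lv[1], floor_expect)
  expect_true(all(lv >= 0 & lv <= 1))
  # derivative pushes back into [0, 1] at the boundaries
  expect_gt(acetylation_rhs(0, 1, p), 0)
  expect_lt(acetylation_rhs(1, 1, p), 0)
})

test_that("glycosylation is obligatory for membrane residency", {
  p <- full_fix$params
  # no GNT-4A: glycosylated pool (and hence membrane) vanish
  off <- steady_state_full(p, perturbation_spec(
    rna_clamp = list(MGAT4A = 0)))
  expect_equal(off$state[["glyc_GLUT1"]], 0)
  expect_equal(off$epsilon1, 0)
  expect_equal(off$epsilon2, 0)
  expect_equal(off$gk_rate, 0)
  # glycosylated fraction is monotone in GNT-4A abundance
  y <- vapply(c(0.1, 0.3, 1, 3), function(m) {
    steady_state_full(p, perturbation_spec(rna_clamp = list(MGAT4A = m))
                      )$state[["glyc_GLUT2"]]
  }, numeric(1))
  expect_true(all(diff(y) > 0))
})

test_that("glycan competition reduces membrane residency monotonically", {
  p <- full_fix$params
  mem <- vapply(c(0, 0.1, 0.3, 0.7, 2, 1e4), function(s) {
    steady_state_full(p, perturbation_spec(
      glycan_competitor = list(name = "glycan", strength = s)))$epsilon1
  }, numeric(1))
  expect_equal(mem[1], 1, tolerance = 1e-12)
  expect_true(all(diff(mem) < 0))
  expect_lt(tail(mem, 1), 1e-3)
  # fitted strengths reproduce the mean printed reductions, identically
  # for the two transporters (shared post-translational kinetics)
  for (i in seq_along(full_fix$glycan_strengths)) {
    ss <- steady_state_full(p, perturbation_spec(
      glycan_competitor = list(name = names(full_fix$glycan_strengths)[i],
                               strength = full_fix$glycan_strengths[[i]])))
    expect_equal(ss$epsilon1, c(0.775, 0.525)[i], tolerance = 1e-6)
    expect_equal(ss$epsilon2, ss$epsilon1, tolerance = 1e-12)
  }
})

test_that("nuclear exclusion alone reproduces all observed alterations", {
  base <- steady_state_full(full_fix$params, perturbation_spec())
  t2d <- steady_state_full(full_fix$params, full_fix$t2d)
  lowered <- c("hnf1a_nuc", "foxa2_nuc", "rna_MGAT4A", "rna_GLUT1",
               "rna_GLUT2", "mem_GLUT1", "mem_GLUT2", "glucose_in")
  for (v in lowered) expect_lt(t2d$state[[v]], base$state[[v]])
  expect_lt(t2d$gk_rate, base$gk_rate)
  # the fitted scenario hits the printed membrane reductions
  expect_equal(t2d$epsilon1, 0.14, tolerance = 1e-6)
  expect_equal(t2d$epsilon2, 0.05, tolerance = 1e-6)
})

test_that("steady GK rate decreases monotonically with nuclear exclusion", {
  v <- vapply(c(0, 1, 2, 3, 5, 10), function(f) {
    steady_state_full(full_fix$params,
                      perturbation_spec(nuclear_exclusion_factor = f)
                      )$gk_rate
  }, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("algebraic and ODE steady states agree", {
  perts <- list(perturbation_spec(),
                full_fix$t2d,
                perturbation_spec(glycan_competitor = list(
                  name = "LacNAc", strength = full_fix$glycan_strengths[[1]])),
                perturbation_spec(rna_clamp = list(GLUT2 = 0.5)))
  moving <- setdiff(regulatory_state_names(), "g6p_pool")
  for (pe in perts) {
    alg <- steady_state_full(full_fix$params, pe)
    ode <- steady_state_full(full_fix$params, pe, method = "ode")
    rel <- abs(ode$state[moving] - alg$state[moving]) /
      pmax(abs(alg$state[moving]), 1e-9)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("membrane composition follows the 80/20 arithmetic exactly", {
  set.seed(3)
  for (i in 1:10) {
    e1 <- runif(1, 0.01, 1.2); e2 <- runif(1, 0.01, 1.2)
    comp <- membrane_composition(e1, e2)
    expect_equal(unname(comp[["GLUT1"]]),
                 (0.8 * e1) / (0.8 * e1 + 0.2 * e2), tolerance = 1e-14)
    expect_equal(sum(comp), 1)
  }
  # healthy composition is the assumed 80/20 split
  expect_equal(unname(membrane_composition(1, 1)), c(0.8, 0.2))
})

test_that("uptake at 10 mM orders healthy > LacNAc > (LacNAc)3 > T2D", {
  eps <- list(healthy = c(1, 1),
              LacNAc = c(0.75, 0.80),       # printed per-transporter values
              LacNAc3 = c(0.57, 0.48),
              T2D = c(0.14, 0.05))
  uptake <- vapply(eps, function(e) {
    steady_state_full(full_fix$params,
                      perturbation_spec(epsilon_override = e),
                      glucose_out = 10)$gk_rate
  }, numeric(1))
  expect_true(all(diff(uptake) < 0))
})
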