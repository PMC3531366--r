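# Metabolic-threshold analysis over transporter expression.

test_that("rate comparison curves separate healthy and threshold regimes", {
  grid <- c(0, 2, 6.5, 10)
  he <- rate_comparison_curves(params_fix, healthy_scenario, grid)
  expect_equal(unlist(he[he$glucose_in_mM == 0, -1]),
               c(outward_glut1 = 0, outward_glut2 = 0, gk_rate = 0))
  # healthy at 6.5 mM: export through GLUT-2 far exceeds phosphorylation
  row <- he[he$glucose_in_mM == 6.5, ]
  expect_equal(row$outward_glut2, 1.588 * 6.5 / 23.5, tolerance = 1e-3)
  expect_equal(row$outward_glut2, 0.439, tolerance = 2e-3)
  expect_gt(row$outward_glut2 / row$gk_rate, 5)
  # 20% GLUT-2, no GLUT-1: export is comparable to the GK rate
  th <- rate_comparison_curves(params_fix, expression_scenario(0, 0.2),
                               6.5)
  expect_equal(th$outward_glut2, 0.088, tolerance = 2e-2)
  expect_lt(th$outward_glut2 / th$gk_rate, 1.5)
  expect_identical(th$outward_glut1, 0)
})

test_that("the GK-rate surface has the printed corners and is monotone", {
  eps <- seq(0, 1, length.out = 21)
  surf <- gk_rate_surface(params_fix, eps, eps, 16.8)
  expect_identical(surf[1, 1], 0)
  expect_equal(surf[21, 21], 0.118, tolerance = 2e-3)   # prints as 0.12
  expect_equal(gk_at(0, 0.2), 0.070, tolerance = 1e-3)
  expect_true(all(apply(surf, 1, function(r) all(diff(r) >= -1e-12))))
  expect_true(all(apply(surf, 2, function(cc) all(diff(cc) >= -1e-12))))
})

test_that("find_threshold_epsilon2 locates the 20% tipping point", {
  expect_identical(find_threshold_epsilon2(params_fix, 16.8, 0), 0)
  e2 <- find_threshold_epsilon2(params_fix, 16.8, 0.07)
  expect_equal(e2, 0.20, tolerance = 1e-4)
  # boundary identity: the rate attained at (0, 1) maps back to 1
  top <- gk_at(0, 1)
  expect_equal(find_threshold_epsilon2(params_fix, 16.8, top), 1)
  expect_error(find_threshold_epsilon2(params_fix, 16.8, top * 1.05),
               "unattainable")
})

test_that("the iso-rate contour is anchored, monotone and self-consistent", {
  crit <- gk_at(0, 0.2)
  ctr <- iso_rate_contour(params_fix, 16.8, crit,
                          epsilon1_grid = seq(0, 1, length.out = 26))
  expect_equal(ctr$epsilon2[ctr$epsilon1 == 0], 0.20, tolerance = 1e-3)
  # monotone: epsilon2 decreases as epsilon1 increases, until it hits 0
  pos <- ctr$epsilon2 > 0
  expect_true(all(diff(ctr$epsilon2[pos]) < 0))
  # GLUT-1 alone compensates at high expression
  expect_true(any(ctr$glut1_compensates))
  expect_true(all(ctr$epsilon2[ctr$glut1_compensates] == 0))
  # every contour point reproduces the critical rate within 1%
  for (i in which(!ctr$glut1_compensates)) {
    expect_equal(gk_at(ctr$epsilon1[i], ctr$epsilon2[i]), crit,
                 tolerance = 0.01)
  }
})

test_that("regimes classify consistently with the contour", {
  crit <- gk_at(0, 0.2)
  expect_identical(classify_regime(params_fix, healthy_scenario, 16.8, crit),
                   "phosphorylation_limited")
  expect_identical(classify_regime(params_fix, t2d_scenario, 16.8, crit),
                   "transport_limited")
  # normal GLUT-1 alone compensates for absent GLUT-2
  expect_identical(classify_regime(params_fix, expression_scenario(1, 0),
                                   16.8, crit),
                   "phosphorylation_limited")
  # componentwise above / below contour points
  ctr <- iso_rate_contour(params_fix, 16.8, crit,
                          epsilon1_grid = seq(0, 0.3, length.out = 7))
  inner <- ctr[!ctr$glut1_compensates & ctr$epsilon2 > 0.02, ]
  for (i in seq_len(nrow(inner))) {
    above <- expression_scenario(inner$epsilon1[i] + 0.02,
                                 inner$epsilon2[i] + 0.02)
    below <- expression_scenario(max(inner$epsilon1[i] - 0.02, 0),
                                 max(inner$epsilon2[i] - 0.02, 0))
    expect_identical(classify_regime(params_fix, above, 16.8, crit),
                     "phosphorylation_limited")
    expect_identical(classify_regime(params_fix, below, 16.8, crit),
                     "transport_limited")
  }
})

test_that("the critical rate sits near 60% of the healthy rate", {
  ratio <- gk_at(0, 0.2) / gk_at(1, 1)
  expect_gte(ratio, 0.55)
  expect_lte(ratio, 0.62)
})
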