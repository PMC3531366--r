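# Scenario generation, synthetic uptake data, expression recovery, I/O.

test_that("glucose profiles evaluate as declared", {
  const <- generate_profile("constant", 2.8)
  expect_equal(const(c(0, 50, 1e3)), rep(2.8, 3))
  step <- generate_profile("step", c(2.8, 16.8), 10)
  expect_equal(step(9.9), 2.8)
  expect_equal(step(10.1), 16.8)
  meal <- generate_profile("meal", c(2.8, 16.8, 5, 2.8), c(20, 60, 120))
  tt <- seq(0, 200, by = 0.5)
  expect_true(all(meal(tt) >= 2.8 - 1e-12 & meal(tt) <= 16.8 + 1e-12))
  expect_error(generate_profile("step", c(2.8, 16.8, 5), 10), "levels")
  expect_error(generate_profile("step", c(2.8, 16.8), c(10, 5)),
               "increasing")
})

test_that("uptake datasets are exact at cv = 0 and seed-deterministic", {
  scs <- list(healthy_scenario, t2d_scenario)
  d0 <- generate_uptake_dataset(cal_fix, scs, c(2.8, 10, 16.8),
                                n_replicates = 2, cv = 0, seed = 9)
  for (i in seq_len(nrow(d0))) {
    ss <- solve_steady_state(set_epsilon(params_fix, d0$epsilon1[i],
                                         d0$epsilon2[i]),
                             d0$glucose_out_mM[i])
    expect_equal(d0$uptake_nmol_min_1e5[i],
                 ss$net_flux_glut1 + ss$net_flux_glut2, tolerance = 1e-12)
  }
  a <- generate_uptake_dataset(cal_fix, scs, n_replicates = 4, seed = 33)
  b <- generate_uptake_dataset(cal_fix, scs, n_replicates = 4, seed = 33)
  expect_identical(a, b)
  c2 <- generate_uptake_dataset(cal_fix, scs, n_replicates = 4, seed = 34)
  expect_false(identical(a$uptake_nmol_min_1e5, c2$uptake_nmol_min_1e5))
})

test_that("noise is multiplicative with mean one (law of large numbers)", {
  d <- generate_uptake_dataset(cal_fix, list(healthy_scenario), 10,
                               n_replicates = 1000, cv = 0.1, seed = 4)
  truth <- solve_steady_state(set_epsilon(params_fix, 1, 1), 10)
  truth <- truth$net_flux_glut1 + truth$net_flux_glut2
  expect_lt(abs(mean(d$uptake_nmol_min_1e5) / truth - 1),
            3 * 0.1 / sqrt(1000))
})

test_that("noise-free recovery inverts the forward model exactly", {
  d <- generate_uptake_dataset(cal_fix, list(t2d_scenario),
                               c(2.8, 10, 16.8), n_replicates = 3,
                               cv = 0, seed = 1)
  fit <- recover_expression(d, cal_fix)
  expect_equal(unname(fit$estimate[["epsilon1"]]), 0.14, tolerance = 1e-6)
  expect_equal(unname(fit$estimate[["epsilon2"]]), 0.05, tolerance = 1e-6)
  # self-consistency at healthy expression with noise
  dh <- generate_uptake_dataset(cal_fix, list(healthy_scenario),
                                c(2.8, 10, 16.8), n_replicates = 20,
                                cv = 0.1, seed = 2)
  fh <- recover_expression(dh, cal_fix)
  expect_lt(abs(fh$estimate[["epsilon1"]] - 1), 4 * fh$se[["epsilon1"]] + 0.05)
  expect_lt(abs(fh$estimate[["epsilon2"]] - 1), 4 * fh$se[["epsilon2"]] + 0.05)
})

test_that("a single glucose level leaves the fractions confounded", {
  d1 <- generate_uptake_dataset(cal_fix, list(t2d_scenario), 10,
                                n_replicates = 20, cv = 0.05, seed = 6)
  expect_warning(fit1 <- recover_expression(d1, cal_fix), "single glucose")
  d3 <- generate_uptake_dataset(cal_fix, list(t2d_scenario),
                                c(2.8, 10, 16.8), n_replicates = 20,
                                cv = 0.05, seed = 6)
  fit3 <- recover_expression(d3, cal_fix)
  # spanning both Km regimes makes the design well conditioned
  expect_lt(fit3$condition_number, 100)
  expect_gt(fit1$condition_number, 1e4)
})

test_that("config files round-trip losslessly and validate keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(params_to_config(params_fix), path,
               comments = c("reduced-model parameters",
                            "fluxes in nmol/min/1e5 cells"))
  cfg <- read_config(path)
  p2 <- params_from_config(cfg)
  expect_equal(p2, params_fix, tolerance = 1e-14)
  # required-key validation names the missing key
  cfg_bad <- cfg
  cfg_bad$gk$vmax_gk <- NULL
  expect_error(params_from_config(cfg_bad), "gk.vmax_gk")
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg_bad, path2)
  expect_error(read_config(path2, required = "gk.vmax_gk"), "gk.vmax_gk")
  # malformed yaml is reported as a parse error
  path3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("glut1: {km: 3", "  oops"), path3)
  expect_error(read_config(path3), "malformed")
})

test_that("annotated TSV output round-trips with the declared schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  prof <- generate_profile("step", c(2.8, 16.8), 10)
  tr <- simulate_excursion(params_fix, prof, 60, n_out = 31)
  write_table_tsv(tr, path, comments = "fluxes in nmol/min/1e5 cells")
  back <- read_table_tsv(path)
  expect_identical(names(back), names(tr))
  expect_equal(ncol(back), 7)
  expect_equal(back$glucose_in_mM, tr$glucose_in_mM, tolerance = 1e-10)
  # header carries the package version
  expect_true(any(grepl("bcglut", readLines(path)[1])))
})

test_that("the CLI dispatcher writes the advertised outputs", {
  out <- withr::local_tempdir()
  files <- bcglut_cli(c("steady", "--out", out, "--epsilon1", "0",
                        "--epsilon2", "0.2"))
  expect_true(file.exists(file.path(out, "steady_state.tsv")))
  ss <- read_table_tsv(file.path(out, "steady_state.tsv"))
  expect_equal(ss$glucose_in_mM, 6.5, tolerance = 1e-6)
  bcglut_cli(c("calibrate", "--out", out))
  expect_true(file.exists(file.path(out, "calibrated_params.yaml")))
  p <- params_from_config(read_config(
    file.path(out, "calibrated_params.yaml")))
  expect_equal(p$gk$vmax_gk, cal_fix$vmax_gk, tolerance = 1e-12)
  expect_error(bcglut_cli("frobnicate"), "unknown subcommand")
})
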