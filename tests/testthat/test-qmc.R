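## Campaign tests run on a deliberately coarse oxygen grid and few sets to
## stay fast; the acceptance suite runs the full study conditions.
camp_grid <- c(seq(0.005, 0.08, by = 0.005), seq(0.085, 0.115, by = 0.0025),
               seq(0.12, 0.20, by = 0.01))

test_that("a single-point campaign at the nominal vector reproduces the
           nominal characterisation", {
  p <- cc_parameters()
  sp <- parameter_space(p)
  camp <- qmc_campaign(p, sp, points = matrix(sp$nominal, nrow = 1),
                       o2_grid = camp_grid)
  cv <- characterisation_curve(p, o2_grid = camp_grid)
  r <- camp$records
  expect_equal(r$o2_optimal[1], cv$o2_optimal, tolerance = 1e-6)
  expect_equal(r$ct_min[1], cv$ct_min, tolerance = 1e-6)
  expect_equal(r$k[1], cv$k, tolerance = 1e-6)
  expect_identical(r$shape[1], cv$shape)
})

test_that("campaign accounting reconciles records and exclusions", {
  p <- cc_parameters()
  camp <- qmc_campaign(p, n_sets = 12, o2_grid = camp_grid)
  r <- camp$records
  expect_equal(nrow(r), 12)
  n_ok <- sum(!is.na(r$o2_optimal))
  expect_equal(n_ok + sum(r$all_quiescent) + sum(r$failed), 12)
  s <- camp$summary
  expect_equal(s$n_sets, 12)
  expect_equal(s$o2_optimal_9_105$n_defined, n_ok)
  ## campaigns are bitwise reproducible
  camp2 <- qmc_campaign(p, n_sets = 12, o2_grid = camp_grid)
  expect_identical(camp$records, camp2$records)
})

test_that("paired sweeps evaluate identical parameter sets across arms", {
  p <- cc_parameters()
  sw <- o2th_sweep(p, n_sets = 6, thresholds = c(0.05, 0.15),
                   o2_grid = camp_grid)
  syms <- sw$campaigns[[1]]$space$symbols
  a <- sw$campaigns[[1]]$records[, syms]
  b <- sw$campaigns[[2]]$records[, syms]
  expect_identical(a, b)
})

test_that("o2_th at its nominal value reproduces the base campaign", {
  p <- cc_parameters()
  sw <- o2th_sweep(p, n_sets = 4, thresholds = c(0.10), o2_grid = camp_grid)
  base <- qmc_campaign(p, n_sets = 4, o2_grid = camp_grid)
  expect_equal(sw$campaigns[[1]]$records$o2_optimal,
               base$records$o2_optimal)
})

test_that("mechanism scenarios: identity, knockout wiring", {
  p <- cc_parameters()
  sc <- mechanism_scenarios(p, o2_grid = camp_grid)
  expect_named(sc, c("nominal", "ros_off", "hif2a_off", "both_off"))
  cv <- characterisation_curve(p, o2_grid = camp_grid)
  expect_equal(sc$nominal$ct, cv$ct, tolerance = 1e-10)
  ## ROS knockout means DEG identically 1
  q <- sc$ros_off$params
  expect_true(all(deg_factor(seq(0, 0.21, by = 0.01), q) == 1))
  ## Hif2a knockout means no Hif2a protein at any oxygen
  q2 <- sc$hif2a_off$params
  expect_true(all(hif2a_level(seq(0, 0.21, by = 0.01), q2) == 0))
})

test_that("multistability scan accounting closes", {
  p <- cc_parameters()
  ms <- multistability_scan(p, n_param_sets = 2, n_init_sets = 3,
                            o2_levels = c(0.05, 0.15), horizon = 300)
  expect_equal(ms$n_compared + ms$n_nonconverged +
                 ms$n_failed_sets * 3 * 2, ms$n_total)
  expect_true(is.na(ms$fraction_different) ||
                (ms$fraction_different >= 0 && ms$fraction_different <= 1))
})

test_that("the default initial condition reproduces its own steady state", {
  p <- cc_parameters()
  pv <- hifcycle:::.pack_parms(p, 0.08)
  a <- hifcycle:::.steady_state(pv, p$init, horizon = 300)
  b <- hifcycle:::.steady_state(pv, p$init, horizon = 300)
  expect_true(a$converged)
  expect_identical(a$state, b$state)
})

test_that("steady-state detection is horizon-stable", {
  p <- cc_parameters()
  pv <- hifcycle:::.pack_parms(p, 0.05)
  ss1 <- hifcycle:::.steady_state(pv, p$init, horizon = 300)
  ss2 <- hifcycle:::.steady_state(pv, p$init, horizon = 600)
  expect_true(ss1$converged && ss2$converged)
  expect_equal(ss1$state[5], ss2$state[5], tolerance = 1e-4)
})
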