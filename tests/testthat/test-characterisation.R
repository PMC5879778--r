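## A coarse grid keeps these tests quick; the acceptance suite exercises
## the default fine grid.
coarse_grid <- seq(0.005, 0.20, by = 0.005)

test_that("curve points agree with single-point commitment calls", {
  p <- cc_parameters()
  cv <- characterisation_curve(p, o2_grid = coarse_grid, refine = FALSE)
  for (o2 in c(0.02, 0.05, 0.1, 0.2)) {
    i <- which(abs(cv$o2 - o2) < 1e-12)
    r <- commitment_time(p, o2)
    expect_equal(cv$ct[i], r$ct, tolerance = 1e-10)
  }
  expect_false(any(is.finite(cv$ct) & !cv$committed))
})

test_that("a grid without the normoxia anchor is rejected", {
  p <- cc_parameters()
  expect_error(characterisation_curve(p, o2_grid = seq(0.01, 0.19, 0.01)),
               "0.20")
})

test_that("all transcription sources removed -> quiescent everywhere", {
  p <- cc_parameters()
  p <- cc_set(p, "g_Myc" = 0, "m13" = 0, "m_E2F" = 0, "m9" = 0,
              "m_5cycD" = 0, "m_E2F-RbP" = 0)
  cv <- characterisation_curve(p, o2_grid = c(0.01, 0.05, 0.1, 0.2),
                               t_max = 100)
  expect_false(any(cv$committed))
  expect_true(all(is.na(cv$ct)))
  expect_error(optimal_oxygen(cv), "no committed")
})

test_that("refined optimum matches a dense brute-force grid scan", {
  p <- cc_parameters()
  cv <- characterisation_curve(p, o2_grid = coarse_grid)
  fine <- seq(cv$o2_optimal - 0.005, min(cv$o2_optimal + 0.005, 0.2),
              by = 5e-4)
  cts <- vapply(fine, function(o) commitment_time(p, o)$ct, numeric(1))
  expect_lt(abs(cv$o2_optimal - fine[which.min(cts)]), 5e-4 + 1e-3)
  expect_lte(cv$ct_min, min(cts) + 1e-6)
})

test_that("k factor arithmetic and the toy example", {
  ## toy curve assembled directly: ct_norm 11 h, ct_min 6 h, o2_eq 2.1%
  toy <- structure(list(o2 = c(0.02, 0.1, 0.2), ct = c(11, 6, 11),
                        committed = rep(TRUE, 3), ct_norm = 11, ct_min = 6,
                        o2_optimal = 0.1, o2_eq = 0.021, k = NA,
                        shape = NA, t_max = 200), class = "cc_curve")
  expect_equal(k_factor(toy), 5 / 0.179, tolerance = 1e-12)
  toy$ct_min <- 11
  expect_equal(k_factor(toy), 0)
  toy$o2_eq <- NA_real_
  expect_true(is.na(k_factor(toy)))
})

test_that("shape classification follows k with the boundary at 1", {
  mk <- function(k) structure(list(k = k), class = "cc_curve")
  expect_identical(shape_class(mk(27.9)), "U")
  expect_identical(shape_class(mk(1)), "U")
  expect_identical(shape_class(mk(0.5)), "L")
  expect_identical(shape_class(mk(NA_real_)), "L")
})

test_that("equal-CT oxygen sits on the hypoxic branch below the optimum", {
  p <- cc_parameters()
  cv <- characterisation_curve(p, o2_grid = coarse_grid)
  expect_false(is.na(cv$o2_eq))
  expect_lt(cv$o2_eq, cv$o2_optimal)
  ## CT at o2_eq equals ct_norm
  expect_equal(commitment_time(p, cv$o2_eq)$ct, cv$ct_norm,
               tolerance = 5e-3)
})

test_that("quiescence boundary matches a fine grid scan and diagnostics", {
  p <- cc_parameters()
  b <- quiescence_boundary(p, tol = 1e-4)
  scan <- seq(b - 0.002, b + 0.002, by = 5e-4)
  qv <- vapply(scan, function(o) commitment_time(p, o)$committed,
               logical(1))
  first_committed <- scan[which(qv)[1]]
  expect_lt(abs(b - first_committed), 5e-4 + 1e-4)
  ## non-straddling bracket -> NA with a message
  expect_message(bb <- quiescence_boundary(p, bracket = c(0.05, 0.2)),
                 "straddle")
  expect_true(is.na(bb))
})

test_that("rate ratio is exactly 1 at normoxia and peaks at the optimum", {
  p <- cc_parameters()
  cv <- characterisation_curve(p, o2_grid = coarse_grid)
  expect_identical(rate_ratio(cv, 0.20), 1)
  rr <- rate_ratio(cv, cv$o2_optimal)
  expect_equal(rr, cv$ct_norm / cv$ct_min, tolerance = 1e-6)
  grid_rr <- rate_ratio(cv, cv$o2[cv$committed])
  expect_lte(max(grid_rr), rr + 1e-6)
  ## quiescent oxygen -> ratio 0
  expect_equal(rate_ratio(cv, 0.005), 0)
})

test_that("nominal curve is unimodal on the committed range", {
  p <- cc_parameters()
  cv <- characterisation_curve(p, o2_grid = coarse_grid, refine = FALSE)
  ct <- cv$ct[cv$committed]
  i_min <- which.min(ct)
  expect_true(all(diff(ct[seq_len(i_min)]) <= 1e-9))
  expect_true(all(diff(ct[i_min:length(ct)]) >= -1e-9))
})

test_that("disabling ROS removes the normoxic penalty", {
  p0 <- cc_parameters()
  p <- cc_set(p0, "n_deg" = 0)
  o2s <- seq(0.10, 0.20, by = 0.02)
  cts <- vapply(o2s, function(o) commitment_time(p, o)$ct, numeric(1))
  ## the curve plateaus: commitment at 20% is no slower than at 10%, and
  ## any residual variation across the plateau stays within a few percent
  ## (the declining Hif2a level is nearly compensated by freed Myc)
  expect_lte(cts[length(cts)], cts[1])
  expect_lt(diff(range(cts)) / min(cts), 0.05)
  ## whereas with ROS active the normoxic penalty is large
  cts_on <- vapply(o2s, function(o) commitment_time(p0, o)$ct, numeric(1))
  expect_gt(cts_on[length(cts_on)] / cts_on[1], 1.5)
})
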