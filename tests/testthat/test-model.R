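test_that("derivatives match the independent oracle to 1e-10 relative", {
  p <- cc_parameters()
  worst <- 0
  for (i in 1:500) {
    s <- random_state(i)
    o2 <- stats::runif(1, 0, 0.21)
    q <- if (i %% 5 == 0) perturbed_params(i) else p
    got <- cc_derivatives(s, o2, q)
    ref <- oracle_rhs(s, o2, q)
    rel <- abs(got - ref) / pmax(abs(ref), 1e-8)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-10)
})

test_that("unify option switches only the printed half-saturation mismatch", {
  p0 <- cc_parameters()
  p1 <- cc_parameters(unify_k_e2f_rbp = TRUE)
  s <- random_state(42)
  d0 <- cc_derivatives(s, 0.05, p0)
  d1 <- cc_derivatives(s, 0.05, p1)
  expect_equal(d1, oracle_rhs(s, 0.05, p1))
  ## only the hypo-phosphorylated-Rb balance may differ
  expect_equal(d0[setdiff(names(d0), "rbP")],
               d1[setdiff(names(d1), "rbP")])
  expect_false(isTRUE(all.equal(d0[["rbP"]], d1[["rbP"]])))
})

test_that("all-zero state with zero generation rates has zero derivatives", {
  p <- cc_parameters()
  p <- cc_set(p, "g_Myc" = 0, "g_cycD" = 0, "g_p/p" = 0, "g_Rb" = 0)
  s <- stats::setNames(rep(0, 13), names(random_state(1)))
  expect_equal(max(abs(cc_derivatives(s, 0.05, p))), 0)
})

test_that("Hif1a-Myc balance vanishes at binding equilibrium", {
  p <- cc_parameters()
  p <- cc_set(p, "d_Hif1a-Myc" = 0)
  s <- random_state(7)
  H1 <- hif1a_level(0.02, p)
  ## choose the complex level that equilibrates binding against unbinding
  s["hif1a_myc"] <- cc_get(p, "kf3A") * H1 * s[["myc"]] / cc_get(p, "kr3A")
  d <- cc_derivatives(s, 0.02, p)
  expect_equal(unname(d["hif1a_myc"]), 0, tolerance = 1e-12)
})

test_that("non-finite states are rejected with the species named", {
  p <- cc_parameters()
  s <- random_state(1)
  s["cycE"] <- NaN
  expect_error(cc_derivatives(s, 0.05, p), "cycE")
})

test_that("pure decay: no generation, no HIF input -> monotone decay to 0", {
  p <- cc_parameters()
  p <- cc_set(p, "g_Myc" = 0, "g_cycD" = 0, "g_p/p" = 0, "g_Rb" = 0,
              "m1" = 0, "m2" = 0, "n_deg" = 0,
              "m9" = 0, "m13" = 0, "m_E2F" = 0, "m_5cycD" = 0)
  init <- stats::setNames(rep(0.5, 13), names(random_state(1)))
  tr <- simulate_cc(p, o2 = 0.05, init = init, t_max = 50)
  final <- as.numeric(tr[nrow(tr), names(random_state(1))])
  expect_true(all(final >= 0))
  ## binding/phosphorylation only shuffles mass between pools; with no
  ## sources the total protein mass decays monotonically toward zero
  tot <- rowSums(as.data.frame(tr)[, names(random_state(1))])
  expect_true(all(diff(tot) < 1e-8))
  expect_lt(tot[length(tot)], 0.5 * tot[1])
})

test_that("commitment with threshold already reached at start is immediate", {
  p <- cc_parameters()
  init <- p$init
  init["e2f"] <- p$e2f_threshold + 0.5
  r <- commitment_time(p, 0.05, init = init)
  expect_true(r$committed)
  expect_equal(r$ct, 0)
})

test_that("commitment time is solver-tolerance and horizon invariant", {
  p <- cc_parameters()
  a <- commitment_time(p, 0.02)
  b <- commitment_time(p, 0.02, rtol = 5e-9, atol = 5e-11)
  c <- commitment_time(p, 0.02, rtol = 1e-9, atol = 1e-11)
  expect_lt(abs(b$ct - a$ct) / a$ct, 1e-3)
  expect_lt(abs(c$ct - a$ct) / a$ct, 1e-3)
  d <- commitment_time(p, 0.02, t_max = 400)
  expect_lt(abs(d$ct - a$ct) / a$ct, 1e-3)
})

test_that("raising the E2F threshold never shortens commitment", {
  p <- cc_parameters()
  cts <- vapply(c(0.5, 0.8, 1.0, 1.3), function(th)
    commitment_time(cc_set(p, "E2F_TH" = th), 0.05)$ct, numeric(1))
  expect_true(all(diff(cts) > 0))
})

test_that("species stay non-negative over the commitment horizon", {
  p <- cc_parameters()
  for (o2 in c(0.015, 0.02, 0.05, 0.1, 0.15, 0.2)) {
    tr <- simulate_cc(p, o2, t_max = 100)
    m <- as.matrix(as.data.frame(tr)[, names(random_state(1))])
    expect_gt(min(m), -1e-9)
  }
})

test_that("trajectory interpolates densely between stored points", {
  p <- cc_parameters()
  tr <- simulate_cc(p, 0.05, t_max = 20, times = seq(0, 20, by = 0.5))
  mid <- trajectory_at(tr, seq(0.25, 19.75, by = 0.5))
  ## compare with a finer simulation
  tr2 <- simulate_cc(p, 0.05, t_max = 20, times = seq(0, 20, by = 0.25))
  ref <- tr2$e2f[match(seq(0.25, 19.75, by = 0.5), tr2$time_h)]
  expect_equal(mid$e2f, ref, tolerance = 1e-3)
})
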