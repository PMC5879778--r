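test_that("local derivative: constant, identity and smooth-limit cases", {
  expect_equal(local_derivative(function(x) 5, c(1, 2), 1), 0)
  ## f(x) = x_i: E_i = (x_i(1+d) - x_i)/d = x_i exactly, for any d
  expect_equal(local_derivative(function(x) x[2], c(1, 3), 2, d = 0.01), 3)
  expect_equal(local_derivative(function(x) x[2], c(1, 3), 2, d = 1e-4), 3)
  ## smooth f: E_i -> x_i * df/dx_i as d -> 0 (central-difference oracle)
  f <- function(x) sin(x[1]) * exp(x[2])
  x <- c(0.7, 0.3)
  for (d in c(1e-3, 1e-4)) {
    Ei <- local_derivative(f, x, 1, d = d)
    h <- 1e-6
    central <- (f(c(x[1] + h, x[2])) - f(c(x[1] - h, x[2]))) / (2 * h)
    expect_equal(Ei, x[1] * central, tolerance = 10 * d)
  }
})

test_that("analytic toy integral recovers G = (0.2, 0.8)", {
  ## f(x1,x2) = x1 + 2*x2 on [0,1]^2: E1 = x1, E2 = 2*x2 in the limit
  ## d -> 0, so g1 = 1/3, g2 = 4/3 and G = (0.2, 0.8)
  space <- structure(list(symbols = c("x1", "x2"), nominal = c(0.5, 0.5),
                          lower = c(0, 0), upper = c(1, 1), dim = 2L),
                     class = "cc_space")
  f <- function(x) x[1] + 2 * x[2]
  r <- g_scores(space = space, o2 = 0.05, objective = f, d = 1e-4,
                batch = 256, tol = 1e-4, n_max = 4096)
  expect_equal(sum(r$G), 1, tolerance = 1e-9)
  expect_equal(unname(r$G), c(0.2, 0.8), tolerance = 0.01)
  expect_equal(unname(r$g), c(1 / 3, 4 / 3), tolerance = 0.02)
})

test_that("an objective depending on one symbol concentrates all weight", {
  space <- structure(list(symbols = c("a", "b", "c"),
                          nominal = c(1, 1, 1), lower = rep(0, 3),
                          upper = rep(2, 3), dim = 3L),
                     class = "cc_space")
  r <- g_scores(space = space, o2 = 0.05,
                objective = function(x) x[2]^2, d = 1e-3,
                batch = 128, tol = 1e-3, n_max = 1024)
  expect_equal(unname(r$G), c(0, 1, 0), tolerance = 1e-9)
})

test_that("QMC estimate converges through batches and is batch-size stable", {
  space <- structure(list(symbols = c("x1", "x2"), nominal = c(0.5, 0.5),
                          lower = c(0, 0), upper = c(1, 1), dim = 2L),
                     class = "cc_space")
  f <- function(x) x[1] + 2 * x[2]
  r1 <- g_scores(space = space, o2 = 0.05, objective = f, d = 1e-4,
                 batch = 256, tol = 0, n_max = 4096)
  r2 <- g_scores(space = space, o2 = 0.05, objective = f, d = 1e-4,
                 batch = 512, tol = 0, n_max = 4096)
  expect_equal(unname(r1$G), unname(r2$G), tolerance = 2e-3)
  ## the raw integral estimate sharpens with sample size (QMC decay)
  small <- g_scores(space = space, o2 = 0.05, objective = f, d = 1e-4,
                    batch = 64, tol = 0, n_max = 64)
  expect_lt(abs(r1$g[["x1"]] - 1 / 3), abs(small$g[["x1"]] - 1 / 3))
  ## every checkpoint is normalised
  expect_true(all(abs(rowSums(r1$history) - 1) < 1e-9))
})

test_that("identical configuration gives identical G-scores (no RNG)", {
  p <- cc_parameters()
  sp <- parameter_space(p, c("b1", "m13"))
  a <- g_scores(p, sp, o2 = 0.05, batch = 16, tol = 0.05, n_max = 32,
                t_max = 60)
  b <- g_scores(p, sp, o2 = 0.05, batch = 16, tol = 0.05, n_max = 32,
                t_max = 60)
  expect_identical(a$G, b$G)
  expect_equal(sum(a$G), 1, tolerance = 1e-9)
})

test_that("screening scores inactive parameters at zero", {
  p <- cc_set(cc_parameters(), "m2" = 0)
  ## with no Hif2a protein, its shape constants cannot influence CT
  ## (screened at 10% oxygen, where the knockout still commits)
  sc <- screen_parameters(p, o2_levels = c(0.10), top_k = Inf, t_max = 60)
  expect_equal(sc$score[sc$symbol == "t2"], 0)
  expect_equal(sc$score[sc$symbol == "b2"], 0)
  ## a full ranking is returned when top_k covers all symbols
  expect_gt(nrow(sc), 50)
  expect_true(!is.unsorted(rev(sc$score)))
})

test_that("regime with almost no committed samples aborts informatively", {
  p <- cc_parameters()
  ## half-saturation constants of inactive branches cannot rescue
  ## commitment under severe hypoxia, so every Sobol point is quiescent
  sp <- parameter_space(p, c("k9", "k_RbP"))
  expect_error(g_scores(p, sp, o2 = 0.002, batch = 10, n_max = 20,
                        t_max = 30), "regime unsuitable")
})
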