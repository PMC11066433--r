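test_that("right-hand side matches an independent term-by-term evaluation", {
  p <- endo_core()
  st <- c(thbs1 = 1, fmod = 0.1, tgfb1 = 0.5)
  # hand evaluation, written out term by term
  expected <- c(
    thbs1 = p$a * 0.5^p$na / (0.5^p$na + p$Ka) - p$d1 * 1,
    fmod  = p$b * p$Kb / (0.5^p$nb + p$Kb) - p$d2 * 0.1,
    tgfb1 = p$c * (1 / (1 + p$K1)) * (p$K2 / (0.1 + p$K2)) - p$d3 * 0.5)
  expect_equal(core_rhs(st, p), expected)
  # FMOD production at the origin equals b (= b/d2 under unit decay)
  expect_equal(unname(core_rhs(c(0, 0, 0), p)[["fmod"]]), 0.33)
  # a fixed point has zero derivative
  fps <- find_fixed_points(p)
  for (fp in fps$points)
    expect_equal(max(abs(core_rhs(fp$state, p))), 0, tolerance = 1e-8)
  expect_error(core_rhs(c(-1, 0, 0), p), "thbs1")
})

test_that("steady-state arms match the fitted plateaus and identities", {
  p <- fitted_core()
  expect_identical(steady_thbs1(0, p), 0)
  expect_equal(steady_thbs1(1e6, p), 2.36, tolerance = 1e-3)
  expect_equal(steady_thbs1(p$Ka^(1 / p$na), p), 1.18)
  expect_equal(steady_fmod(0, p), 0.33)
  expect_equal(steady_fmod(1e6, p), 0, tolerance = 1e-6)
  expect_equal(steady_fmod(p$Kb^(1 / p$nb), p), 0.165)
  # monotonicity over a dose grid
  doses <- seq(0, 10, length.out = 400)
  expect_true(all(diff(steady_thbs1(doses, p)) >= 0))
  expect_true(all(diff(steady_fmod(doses, p)) <= 0))
  expect_error(steady_thbs1(-0.1, p), "tgfb1")
})

test_that("reduced map is consistent with substituting the steady arms", {
  p <- endo_core()
  expect_identical(reduced_map(0, p), 0)
  # analytic saturating limit: TH -> a/d1, FMOD -> 0
  lim <- (p$c / p$d3) * 2.36 / (2.36 + 0.46)
  expect_equal(reduced_map(1e8, p), lim, tolerance = 1e-4)
  # grid self-consistency with the production-term formulation
  grid <- exp(seq(log(1e-6), log(5), length.out = 200))
  direct <- (p$c / p$d3) *
    (steady_thbs1(grid, p) / (steady_thbs1(grid, p) + p$K1)) *
    (p$K2 / (steady_fmod(grid, p) + p$K2))
  expect_equal(reduced_map(grid, p), direct)
  # closed-form derivative agrees with a central difference
  for (T in c(0.01, 0.1, 1, 3)) {
    h <- 1e-6 * T
    num <- (reduced_map(T + h, p) - reduced_map(T - h, p)) / (2 * h)
    expect_equal(reduced_map_deriv(T, p), num, tolerance = 1e-5)
  }
})

test_that("fixed points match the brute-force grid oracle on random sets", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_core()
    expected <- brute_force_roots(p)
    got <- as.data.frame(find_fixed_points(p))
    expect_equal(nrow(got), length(expected),
                 info = paste("set", i))
    expect_equal(got$tgfb1, expected, tolerance = 1e-4)
  }
})

test_that("endogenous production rate controls the fixed-point count", {
  # below the fold only the zero state survives; at the fitted rate the
  # system is bistable with stable/unstable/stable ordering
  lo <- default_core_params(c_d3 = 0.05)
  f_lo <- find_fixed_points(lo)
  expect_equal(length(f_lo$points), 1L)
  expect_equal(f_lo$points[[1]]$tgfb1, 0)
  hi <- endo_core()  # gamma = 3.5
  f_hi <- as.data.frame(find_fixed_points(hi))
  expect_equal(nrow(f_hi), 3L)
  expect_identical(f_hi$stability, c("stable", "unstable", "stable"))
  expect_equal(brute_force_roots(hi), f_hi$tgfb1, tolerance = 1e-6)
})

test_that("zero state is stable whenever the Hill exponents exceed one", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_core()
    z <- find_fixed_points(p)$points[[1]]
    expect_equal(z$tgfb1, 0)
    expect_identical(z$stability, "stable")
    expect_lt(z$slope, 1)
  }
})

test_that("reduced and Jacobian stability classifications agree", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_core()
    for (fp in find_fixed_points(p)$points) {
      red <- classify_stability(fp$tgfb1, p, mode = "reduced")
      jac <- classify_stability(fp$tgfb1, p, mode = "jacobian")
      expect_identical(red$stability, jac$stability,
                       info = sprintf("set %d at T = %g", i, fp$tgfb1))
      expect_equal(length(jac$eigenvalues), 3L)
    }
  }
})

test_that("fold structure is invariant to joint scaling of a/d1 and K1", {
  p <- endo_core()
  p2 <- p
  p2$a <- 2 * p2$a
  p2$K1 <- 2 * p2$K1
  for (g in c(0.05, 0.1, 1, 3.5)) {
    pa <- p; pa$c <- g
    pb <- p2; pb$c <- g
    expect_equal(length(find_fixed_points(pa)$points),
                 length(find_fixed_points(pb)$points), info = paste0("g=", g))
  }
})

test_that("deterministic integration respects basins and converges", {
  p <- endo_core()
  fps <- as.data.frame(find_fixed_points(p))
  unstable <- fps$tgfb1[fps$stability == "unstable"]
  upper <- max(fps$tgfb1)
  # from a fixed point the trajectory is constant
  tr <- simulate_deterministic(c(steady_thbs1(upper, p),
                                 steady_fmod(upper, p), upper),
                               p, t_end = 5, dt = 0.01)
  expect_lt(max(abs(tr$tgfb1 - upper)), 1e-6)
  # above the unstable root -> upper state; below -> zero state
  hi <- simulate_deterministic(c(0, 0, 10 * unstable), p, t_end = 60,
                               dt = 0.01)
  expect_equal(hi$tgfb1[nrow(hi)], upper, tolerance = 1e-3)
  lo <- simulate_deterministic(c(0, 0, 0.5 * unstable), p, t_end = 60,
                               dt = 0.01)
  expect_lt(lo$tgfb1[nrow(lo)], 1e-6)
  # halving dt moves the terminal state by less than first order
  hi2 <- simulate_deterministic(c(0, 0, 10 * unstable), p, t_end = 60,
                                dt = 0.005)
  expect_lt(abs(hi2$tgfb1[nrow(hi2)] - hi$tgfb1[nrow(hi)]), 0.01)
  expect_error(simulate_deterministic(c(0, 0, 1), p, t_end = 1, dt = 0),
               "dt")
})
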