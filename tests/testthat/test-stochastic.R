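test_that("TGF-beta-1 relaxation lands on the basin fixed point", {
  p <- endo_core()
  cfg <- sde_config(n_paths = 1)
  fps <- as.data.frame(find_fixed_points(p))
  unstable <- fps$tgfb1[fps$stability == "unstable"]
  upper <- max(fps$tgfb1)
  expect_identical(relax_tgfb1(0, p, cfg), 0)
  expect_equal(relax_tgfb1(3 * unstable, p, cfg), upper, tolerance = 1e-5)
  # decay toward zero halts once the per-step change is below tolerance
  expect_lt(relax_tgfb1(0.3 * unstable, p, cfg), 1e-6)
  # convergence contract: result is a fixed point of the reduced map
  x <- relax_tgfb1(c(0.1, 0.5, 2), p, cfg)
  expect_lt(max(abs(x - reduced_map(x, p))), 1e-6)
})

test_that("noiseless ensembles collapse onto the deterministic steady state", {
  p <- endo_core()
  cfg <- sde_config(sigma1 = 0, sigma2 = 0, n_paths = 100, seed = 2)
  ens <- simulate_ensemble(p, cfg)
  expect_equal(nrow(ens$samples), 100L)
  expect_equal(ens$samples$thbs1, steady_thbs1(ens$samples$tgfb1_bar, p),
               tolerance = 1e-6)
  expect_equal(ens$samples$fmod, steady_fmod(ens$samples$tgfb1_bar, p),
               tolerance = 1e-6)
})

test_that("ensembles are seed-reproducible and substream-stable", {
  p <- endo_core()
  cfg <- sde_config(n_paths = 40, seed = 9, t_stationary = 2)
  e1 <- simulate_ensemble(p, cfg)
  e2 <- simulate_ensemble(p, cfg)
  expect_identical(e1$samples, e2$samples)
  # enlarging the ensemble leaves the earlier paths untouched
  cfg2 <- cfg; cfg2$n_paths <- 80L
  e3 <- simulate_ensemble(p, cfg2)
  expect_identical(e3$samples[1:40, ], e1$samples)
  # TSV export is byte-stable
  f1 <- tempfile(); f2 <- tempfile()
  write_ensemble_tsv(e1, f1); write_ensemble_tsv(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("stationary spread matches the Ornstein-Uhlenbeck variance", {
  p <- endo_core()
  cfg <- sde_config(sigma1 = 0.2, sigma2 = 0.2, n_paths = 4000, seed = 5)
  ens <- simulate_ensemble(p, cfg)
  hi <- ens$samples$tgfb1_bar > 1
  expect_gt(sum(hi), 3500)  # nearly all paths start above the tiny threshold
  # sd -> sigma/sqrt(2) within Monte-Carlo error
  expect_equal(stats::sd(ens$samples$thbs1[hi]), 0.2 / sqrt(2),
               tolerance = 0.05)
  # on the upper branch THBS1 sits far from zero: clamping is rare
  expect_lt(ens$clamped_fraction_thbs1, 0.01)
})

test_that("basin weights follow the uniform initial measure", {
  p <- calibrate_cd3_for_k1_fold(k1_fold = 15)
  p$K1 <- 14
  fps <- as.data.frame(find_fixed_points(p))
  unstable <- fps$tgfb1[fps$stability == "unstable"]
  cfg <- sde_config(tgfb1_max = 0.2, n_paths = 2000, seed = 3,
                    t_stationary = 1)
  ens <- simulate_ensemble(p, cfg)
  frac_low <- mean(ens$samples$tgfb1_bar < unstable)
  expected <- unstable / 0.2
  expect_equal(frac_low, expected, tolerance = 3 * sqrt(0.2 * 0.8 / 2000) /
                 expected)
})

test_that("sigma -> 0 pulls the ensemble mean onto the deterministic value", {
  p <- endo_core()
  devs <- vapply(c(0.2, 0.05, 0.01), function(s) {
    cfg <- sde_config(sigma1 = s, sigma2 = s, n_paths = 400, seed = 11)
    ens <- simulate_ensemble(p, cfg)
    hi <- ens$samples$tgfb1_bar > 1
    abs(mean(ens$samples$thbs1[hi]) -
          steady_thbs1(ens$samples$tgfb1_bar[hi][1], p))
  }, 0)
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.005)
})

test_that("Silverman test calibrates on unimodal and detects bimodal data", {
  set.seed(1)
  # type-I calibration: unimodal null rarely rejected
  p_uni <- vapply(1:8, function(s) {
    set.seed(100 + s)
    silverman_test(stats::rnorm(300), k = 1, n_boot = 199,
                   seed = s)$p_value
  }, 0)
  expect_lt(mean(p_uni < 0.05), 0.2)
  # power: well-separated mixture strongly rejected
  set.seed(2)
  x <- c(stats::rnorm(250), stats::rnorm(250, mean = 8))
  expect_lt(silverman_test(x, k = 1, n_boot = 199, seed = 1)$p_value, 0.01)
  # null comfortably retained once k exceeds the true mode count
  expect_gt(silverman_test(x, k = 5, n_boot = 99, seed = 1)$p_value, 0.1)
  expect_error(silverman_test(rep(1, 50)), "degenerate")
  expect_error(silverman_test(c(1, 2)), "at least 10")
})

test_that("stochastic model reproduces the bimodal-to-unimodal shift", {
  # near the K1 fold both basins are populated (bimodal THBS1); deep in the
  # monostable-high regime the low mode disappears
  base <- calibrate_cd3_for_k1_fold(k1_fold = 15)
  near <- base; near$K1 <- 14
  far <- base; far$K1 <- 0.05
  cfg <- sde_config(tgfb1_max = 0.2, n_paths = 1500, seed = 21,
                    t_stationary = 5)
  x_near <- gen_cell_population(near, cfg, n_cells = 1500)
  x_far <- gen_cell_population(far, cfg, n_cells = 1500)
  p_near <- silverman_test(x_near, k = 1, n_boot = 199, seed = 4)$p_value
  p_far <- silverman_test(x_far, k = 1, n_boot = 199, seed = 4)$p_value
  expect_lt(p_near, 0.05)
  expect_gt(p_far, 0.05)
})
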