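test_that("default network is built with the ELISA SMAD pools and balances", {
  net <- cached_network()
  tot <- function(pool) sum(net$species[names(net$conserved[[pool]])])
  expect_equal(tot("SMAD2"), 0.060, tolerance = 1e-8)
  expect_equal(tot("SMAD3"), 0.38, tolerance = 1e-8)
  expect_equal(tot("SMAD4"), 0.0044, tolerance = 1e-8)
  # SMAD4 is the smallest SMAD pool
  expect_lt(tot("SMAD4"), tot("SMAD2"))
  expect_lt(tot("SMAD4"), tot("SMAD3"))
  expect_true(audit_conservation(net))
  # the trimer-formation reaction is present by name
  expect_true("trimer_form" %in%
                vapply(net$reactions, `[[`, "", "name"))
  expect_error(build_reduced_network(parameters = c(nope = 1)),
               "unknown parameter")
  expect_error(build_reduced_network(init = c(XYZ = 1)), "unknown species")
})

test_that("a serialized network simulates identically after reload", {
  net <- cached_network()
  f <- tempfile(fileext = ".yaml")
  write_network_yaml(net, f)
  net2 <- read_network_yaml(f)
  prot <- stimulus_protocol(tgfb1_dose = 1, t_grid = seq(0, 24, by = 2))
  tr1 <- simulate_pathway(net, prot)
  tr2 <- simulate_pathway(net2, prot)
  expect_equal(tr1$species, tr2$species, tolerance = 1e-7)
})

test_that("unstimulated network stays at its resting state", {
  net <- cached_network()
  tr <- simulate_pathway(net, stimulus_protocol(tgfb1_dose = 0))
  for (s in c("THBS1", "FMOD", "pAkt", "pSMAD3")) {
    v <- tr$species[, s]
    expect_lt(diff(range(v)), 1e-4 * max(max(v), 1e-6))
  }
})

test_that("washout removes the external ligand and events are breakpoints", {
  net <- cached_network()
  prot <- stimulus_protocol(tgfb1_dose = 1, washout_time = 4,
                            t_grid = seq(0, 12, by = 0.25))
  tr <- simulate_pathway(net, prot)
  i4 <- which(tr$times == 4)
  expect_lt(tr$species[i4, "TGFb_act"], 1e-12)
  expect_gt(tr$species[i4 - 1, "TGFb_act"], 1e-3)
  expect_error(stimulus_protocol(washout_time = -1), "washout_time")
  expect_error(
    simulate_pathway(net, stimulus_protocol(tgfb1_dose = 1,
                                            washout_time = 100),
                     horizon = 48),
    "event times")
  expect_error(
    simulate_pathway(net, stimulus_protocol(
      inhibitor_events = list(list(target = "no_such", time = 1,
                                   fraction = 0.5)))),
    "unknown inhibitor target")
})

test_that("conserved pools stay constant along stimulated trajectories", {
  net <- cached_network()
  tr <- simulate_pathway(net, stimulus_protocol(tgfb1_dose = 2,
                                                washout_time = 8))
  for (pool in c("SMAD2", "SMAD3", "SMAD4", "Akt", "ERK")) {
    w <- net$conserved[[pool]]
    tot <- as.vector(tr$species[, names(w), drop = FALSE] %*% w)
    expect_lt(diff(range(tot)) / tot[1], 1e-6)
  }
})

test_that("knockdowns scale initial pools and act at time zero", {
  net <- cached_network()
  prot <- stimulus_protocol(tgfb1_dose = 1,
                            knockdowns = list(list(pool = "SMAD4",
                                                   fraction = 0.2)))
  tr <- simulate_pathway(net, prot)
  w <- net$conserved$SMAD4
  tot <- as.vector(tr$species[, names(w), drop = FALSE] %*% w)
  expect_equal(tot[1], 0.2 * sum(net$species[names(w)]), tolerance = 1e-8)
  expect_error(stimulus_protocol(knockdowns = list(list(pool = "SMAD4",
                                                        fraction = 2))),
               "fraction")
})

test_that("integral metric is the trapezoid rule", {
  net <- cached_network()
  mk <- function(times, values) {
    tr <- list(times = times,
               species = matrix(values, ncol = 1,
                                dimnames = list(NULL, "THBS1")),
               observables = matrix(numeric(0), nrow = length(times),
                                    ncol = 0),
               observables_raw = matrix(numeric(0), nrow = length(times),
                                        ncol = 0))
    class(tr) <- "trajectory_set"
    tr
  }
  expect_equal(integral_metric(mk(c(0, 2, 5), rep(3, 3))), 15)
  expect_equal(integral_metric(mk(seq(0, 10, 1), seq(0, 5, 0.5))), 25)
  expect_error(integral_metric(mk(0, 1)), "two time points")
  # refining the output grid changes the integral by less than the
  # trapezoid error bound
  p1 <- stimulus_protocol(tgfb1_dose = 1, t_grid = seq(0, 48, by = 1))
  p2 <- stimulus_protocol(tgfb1_dose = 1, t_grid = seq(0, 48, by = 0.5))
  m1 <- integral_metric(simulate_pathway(net, p1))
  m2 <- integral_metric(simulate_pathway(net, p2))
  expect_lt(abs(m1 - m2) / m2, 1e-3)
})

test_that("min-max normalization contracts", {
  expect_equal(normalize_minmax(c(0, 5, 10)), c(0, 0.5, 1))
  x <- c(0.1, 0.7, 0.35, 1, 0)
  expect_equal(normalize_minmax(x), x)
  expect_equal(normalize_minmax(3 + 2 * x), x)
  expect_error(normalize_minmax(rep(2, 5)), "constant")
})

test_that("sensitivity coefficients obey exact oracles on toy networks", {
  # pass-through: M = integral of M_sp, production k_in * A, no decay of A
  toy <- reaction_network(
    species = c(A = 1, M_sp = 0, D = 1),
    parameters = c(k_in = 0.3, k_d = 0.1, k_dec = 0.7),
    reactions = list(
      list(name = "prod", k = "k_in", stoich = c(M_sp = 1), factors = "A",
           hill = list(), repress = list()),
      list(name = "deg", k = "k_d", stoich = c(M_sp = -1), factors = "M_sp",
           hill = list(), repress = list()),
      list(name = "decoy", k = "k_dec", stoich = c(D = -1), factors = "D",
           hill = list(), repress = list())))
  prot <- stimulus_protocol(t_grid = seq(0, 10, by = 0.5))
  sm <- sensitivity_analysis(toy, prot, metric_species = "M_sp",
                             horizon = 10)
  co <- stats::setNames(sm$coefficient, sm$target)
  expect_equal(unname(co["prod"]), 1, tolerance = 1e-4)
  expect_equal(unname(co["decoy"]), 0, tolerance = 1e-8)
  # species mode: M proportional to the input pool A
  sms <- sensitivity_analysis(toy, prot, metric_species = "M_sp",
                              target = "species", horizon = 10)
  cos <- stats::setNames(sms$coefficient, sms$target)
  expect_equal(unname(cos["A"]), 1, tolerance = 1e-4)
  expect_equal(unname(cos["D"]), 0, tolerance = 1e-8)
})

test_that("trimer formation dominates single-SMAD reactions in sensitivity", {
  net <- cached_network()
  sm <- sensitivity_analysis(net)
  co <- stats::setNames(abs(sm$coefficient), sm$target)
  expect_gt(co["trimer_form"], co["smad2_phos"])
  expect_gt(co["trimer_form"], co["smad3_phos"])
})

test_that("differential evolution is elitist, seeded, and recovers truth", {
  net <- cached_network()
  tc <- gen_timecourse(net, noise = noise_spec(cv = 0, seed = 1))
  free <- c("k_th", "k_fmdeg")
  lower <- stats::setNames(net$parameters[free] / 5, free)
  upper <- stats::setNames(net$parameters[free] * 5, free)
  fit <- estimate_parameters(net, tc, free, lower, upper, n_runs = 2,
                             de_options = list(np = 10, generations = 10),
                             seed = 7)
  expect_length(fit$runs, 2L)
  for (r in fit$runs) expect_true(all(diff(r$trace) <= 1e-12))
  fit2 <- estimate_parameters(net, tc, free, lower, upper, n_runs = 2,
                              de_options = list(np = 10, generations = 10),
                              seed = 7)
  expect_identical(fit$runs[[1]]$par, fit2$runs[[1]]$par)
  # best run reproduces the generating observables closely
  best <- fit$runs[[fit$best]]
  net2 <- net
  net2$parameters[free] <- best$par
  tr <- simulate_pathway(net2, tc$protocol, horizon = 48)
  idx <- match(tc$times, tr$times)
  rmse <- sqrt(mean((tr$observables[idx, "THBS1"] - tc$obs$THBS1[, 1])^2))
  expect_lt(rmse, 0.1)
  expect_error(estimate_parameters(net, tc, free, lower[1], upper),
               "bounds")
  expect_error(estimate_parameters(net, tc, "nope", lower, upper),
               "free parameters")
})
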