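# shared fixtures: the fitted parameter sets and small helpers

fitted_core <- function() default_core_params()
endo_core <- function() substitute_endogenous(default_extended_params())

# random valid core parameter set (d1 = d2 = d3 = 1)
random_core <- function() {
  core_params(a = stats::runif(1, 0.5, 5), b = stats::runif(1, 0.1, 2),
              c = stats::runif(1, 0.5, 5),
              Ka = 10^stats::runif(1, -3, -0.5),
              Kb = 10^stats::runif(1, -3, -0.5),
              K1 = stats::runif(1, 0.1, 2), K2 = stats::runif(1, 0.1, 2),
              na = stats::runif(1, 1.1, 2.5), nb = stats::runif(1, 1.1, 2.5))
}

# independent brute-force root scan of T - reduced_map(T) on a dense grid
brute_force_roots <- function(params, hi = NULL, n = 1e5) {
  if (is.null(hi)) hi <- 2 * params$c / params$d3 + 1
  grid <- c(0, exp(seq(log(1e-13), log(hi), length.out = n)))
  r <- grid - reduced_map(grid, params)
  sc <- which(sign(r[-1]) * sign(r[-length(r)]) < 0)
  nonzero <- vapply(sc, function(i)
    stats::uniroot(function(T) T - reduced_map(T, params),
                   c(grid[i], grid[i + 1]), tol = 1e-15)$root, 0)
  sort(c(0, nonzero[nonzero > 1e-12]))
}

# a minimal pathway network cached per test session (settled baseline)
cached_network <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_reduced_network()
    net
  }
})
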