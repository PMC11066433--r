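#' Configuration of the Ornstein-Uhlenbeck stochastic extension
#'
#' The stochastic model keeps TGF-beta-1 deterministic: each path first
#' relaxes the scalar TGF-beta-1 equation to its basin's fixed point
#' (`tgfb1_bar`), then THBS1 and FMOD fluctuate as Ornstein-Uhlenbeck
#' processes around their steady levels at `tgfb1_bar`, with unit
#' mean-reversion rate and noise amplitudes `sigma1`, `sigma2`.
#'
#' @param sigma1,sigma2 Noise amplitudes of the THBS1 and FMOD equations
#'   (`>= 0`). Default 0.2 each (the imaging-scale setting; the supplementary
#'   setting is 0.05).
#' @param tgfb1_max Upper bound of the uniform initial TGF-beta-1
#'   distribution (default 0.2; the supplementary setting is 1.0).
#' @param n_paths Ensemble size (default 10000).
#' @param dt Euler / Euler-Maruyama step (must satisfy `dt < 1` for the unit
#'   relaxation rate; default 0.01).
#' @param t_relax Horizon for the deterministic TGF-beta-1 relaxation
#'   (default 500 relaxation times; relaxation stops earlier once the
#'   per-step change falls below 1e-9).
#' @param t_stationary Ornstein-Uhlenbeck simulation horizon (default 20
#'   relaxation times, far beyond the e-folding mixing time).
#' @param seed Integer seed; per-path noise substreams are derived from it
#'   deterministically, so enlarging `n_paths` does not reshuffle earlier
#'   paths.
#' @return An `sde_config` object.
#' @export
sde_config <- function(sigma1 = 0.2, sigma2 = 0.2, tgfb1_max = 0.2,
                       n_paths = 10000, dt = 0.01, t_relax = 500,
                       t_stationary = 20, seed = 1) {
  if (sigma1 < 0 || sigma2 < 0) stop("sigma1, sigma2 must be >= 0",
                                     call. = FALSE)
  if (n_paths < 1) stop("n_paths must be >= 1", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (dt >= 1)
    stop("dt must be < 1 for stability of the explicit scheme at unit ",
         "relaxation rate", call. = FALSE)
  structure(list(sigma1 = sigma1, sigma2 = sigma2, tgfb1_max = tgfb1_max,
                 n_paths = as.integer(n_paths), dt = dt, t_relax = t_relax,
                 t_stationary = t_stationary, seed = as.integer(seed)),
            class = "sde_config")
}

#' Relax TGF-beta-1 to its basin fixed point
#'
#' Forward-Euler integration of `dT/dt = f(T) - T` (with `f` the reduced
#' steady-state map) from each initial value until the per-step change drops
#' below `tol` or `t_relax` is reached. The returned values are fixed points
#' of [reduced_map()] within tolerance; initial values below the unstable
#' root land on the zero state, values above land on the upper stable state.
#'
#' @param initial Initial TGF-beta-1 value(s), `>= 0` (vectorized).
#' @param params A [core_params()] object.
#' @param cfg An [sde_config()] (supplies `dt` and `t_relax`).
#' @param tol Per-step change threshold declaring convergence.
#' @return Numeric vector of relaxed values. Paths that fail to converge are
#'   flagged by a warning and carry attribute `unconverged` (their indices).
#' @export
relax_tgfb1 <- function(initial, params, cfg = sde_config(), tol = 1e-9) {
  stopifnot(inherits(params, "core_params"))
  check_dose(initial)
  x <- as.numeric(initial)
  dt <- cfg$dt
  n_steps <- ceiling(cfg$t_relax / dt)
  active <- rep(TRUE, length(x))
  for (i in seq_len(n_steps)) {
    if (!any(active)) break
    xa <- x[active]
    step <- dt * (reduced_map(xa, params) - xa)
    x[active] <- pmax(xa + step, 0)
    active[active] <- abs(step) >= tol
  }
  if (any(active)) {
    warning(sum(active), " path(s) did not converge within t_relax",
            call. = FALSE)
    attr(x, "unconverged") <- which(active)
  }
  x
}

# per-path Gaussian increments: path i's stream depends only on (seed, i)
path_noise <- function(seed, path_ids, n_steps) {
  eps1 <- matrix(NA_real_, length(path_ids), n_steps)
  eps2 <- matrix(NA_real_, length(path_ids), n_steps)
  for (r in seq_along(path_ids)) {
    set.seed(seed + path_ids[r])
    z <- stats::rnorm(2L * n_steps)
    eps1[r, ] <- z[seq_len(n_steps)]
    eps2[r, ] <- z[n_steps + seq_len(n_steps)]
  }
  list(eps1 = eps1, eps2 = eps2)
}

#' Simulate the stochastic ensemble
#'
#' Per path: draw `TGFb1(0) ~ U(0, tgfb1_max)` (THBS1 and FMOD start at 0),
#' relax TGF-beta-1 deterministically to `tgfb1_bar`, then run the
#' Euler-Maruyama scheme on the two Ornstein-Uhlenbeck equations
#' \deqn{dX = (\bar{X}(\bar{T}) - X)dt + \sigma dB(t)} for `t_stationary`,
#' clamping negative excursions to zero. The terminal `(thbs1, fmod)` of
#' each path is returned together with its `tgfb1_bar`.
#'
#' The ensemble is reproducible bit-for-bit from `cfg$seed`; the fraction of
#' clamped steps is recorded so the (stated-negligible) clamping bias can be
#' checked.
#'
#' @param params A [core_params()] object.
#' @param cfg An [sde_config()].
#' @return An `ensemble` object: list with `samples` (data frame `path_id`,
#'   `tgfb1_bar`, `thbs1`, `fmod`), `clamped_fraction`, `config`, `params`.
#' @export
simulate_ensemble <- function(params, cfg = sde_config()) {
  stopifnot(inherits(params, "core_params"), inherits(cfg, "sde_config"))
  n <- cfg$n_paths
  dt <- cfg$dt
  n_steps <- ceiling(cfg$t_stationary / dt)
  sqdt <- sqrt(dt)
  # initial TGF-beta-1 draws: one substream per path (stream offset 0)
  t0 <- vapply(seq_len(n), function(i) {
    set.seed(cfg$seed + i)
    stats::runif(1, 0, cfg$tgfb1_max)
  }, 0)
  tbar <- relax_tgfb1(t0, params, cfg)
  m1 <- steady_thbs1(as.numeric(tbar), params)
  m2 <- steady_fmod(as.numeric(tbar), params)
  th <- numeric(n); fm <- numeric(n)
  clamped1 <- 0; clamped2 <- 0
  block <- 1000L
  for (b in seq(1L, n, by = block)) {
    ids <- b:min(b + block - 1L, n)
    # fixed offset keeps noise substreams disjoint from the initial-value
    # substreams and independent of n_paths
    nz <- path_noise(cfg$seed + 536870912L, ids, n_steps)
    x1 <- rep(0, length(ids)); x2 <- rep(0, length(ids))
    mm1 <- m1[ids]; mm2 <- m2[ids]
    for (k in seq_len(n_steps)) {
      x1 <- x1 + dt * (mm1 - x1) + cfg$sigma1 * sqdt * nz$eps1[, k]
      x2 <- x2 + dt * (mm2 - x2) + cfg$sigma2 * sqdt * nz$eps2[, k]
      clamped1 <- clamped1 + sum(x1 < 0)
      clamped2 <- clamped2 + sum(x2 < 0)
      x1 <- pmax(x1, 0); x2 <- pmax(x2, 0)
    }
    th[ids] <- x1; fm[ids] <- x2
  }
  samples <- data.frame(path_id = seq_len(n), tgfb1_bar = as.numeric(tbar),
                        thbs1 = th, fmod = fm)
  structure(list(samples = samples,
                 clamped_fraction = (clamped1 + clamped2) / (2 * n * n_steps),
                 clamped_fraction_thbs1 = clamped1 / (n * n_steps),
                 clamped_fraction_fmod = clamped2 / (n * n_steps),
                 config = cfg, params = params),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: %d paths (seed %d)\n",
              nrow(x$samples), x$config$seed))
  cat(sprintf("  sigma1 = %.3g, sigma2 = %.3g, tgfb1_max = %.3g\n",
              x$config$sigma1, x$config$sigma2, x$config$tgfb1_max))
  cat(sprintf("  basins: %d low / %d high; clamped step fraction %.3g\n",
              sum(x$samples$tgfb1_bar < 1e-6),
              sum(x$samples$tgfb1_bar >= 1e-6), x$clamped_fraction))
  invisible(x)
}

#' Write an ensemble's samples as TSV
#'
#' Columns `path_id`, `tgfb1_bar`, `thbs1`, `fmod`, numbers formatted with
#' 12 significant digits, locale-independent.
#'
#' @param x An `ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(x, path) {
  stopifnot(inherits(x, "ensemble"))
  df <- x$samples
  for (nm in c("tgfb1_bar", "thbs1", "fmod")) df[[nm]] <- format_num(df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# number of modes of a Gaussian KDE at bandwidth h (512-point grid over the
# sample range extended by 3 bandwidths)
kde_n_modes <- function(x, h) {
  d <- stats::density(x, bw = h, kernel = "gaussian", n = 512,
                      from = min(x) - 3 * h, to = max(x) + 3 * h)
  y <- d$y
  sum(diff(sign(diff(y))) < 0)
}

#' Silverman critical-bandwidth test of k-modality
#'
#' Tests the null hypothesis that a sample's density has at most `k` modes.
#' The critical bandwidth `h_crit` is the smallest Gaussian-kernel bandwidth
#' whose kernel density estimate has at most `k` modes (mode counts are
#' non-increasing in the bandwidth for a Gaussian kernel). The p-value is
#' the bootstrap proportion of variance-rescaled smoothed resamples whose
#' KDE at `h_crit` has more than `k` modes; small p rejects k-modality in
#' favor of more modes.
#'
#' @param samples Numeric sample (`length >= 10`, not all identical).
#' @param k Null mode count (`>= 1`).
#' @param n_boot Bootstrap replicates (default 999).
#' @param seed Integer seed for the bootstrap.
#' @return A `silverman_test` object: list with `p_value`, `h_crit`, `k`,
#'   `n_boot`, `seed`, `n`.
#' @export
silverman_test <- function(samples, k = 1, n_boot = 999, seed = 1) {
  x <- as.numeric(samples)
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need at least 10 samples", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate sample: all values identical", call. = FALSE)
  rng <- diff(range(x))
  # bracket the critical bandwidth, then bisect
  hi <- rng
  while (kde_n_modes(x, hi) > k) hi <- hi * 2
  lo <- hi / 1024
  while (kde_n_modes(x, lo) <= k && lo > 1e-12 * rng) lo <- lo / 2
  if (kde_n_modes(x, lo) <= k) {
    # already <= k modes at arbitrarily small bandwidth
    h_crit <- lo
  } else {
    for (i in 1:60) {
      mid <- sqrt(lo * hi)
      if (kde_n_modes(x, mid) <= k) hi <- mid else lo <- mid
      if (hi / lo < 1 + 1e-9) break
    }
    h_crit <- hi
  }
  n <- length(x)
  xbar <- mean(x)
  scale <- 1 / sqrt(1 + h_crit^2 / s^2)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ystar <- xbar + scale * (x[idx] - xbar + h_crit * stats::rnorm(n))
    if (kde_n_modes(ystar, h_crit) > k) exceed <- exceed + 1L
  }
  structure(list(p_value = (1 + exceed) / (1 + n_boot), h_crit = h_crit,
                 k = k, n_boot = n_boot, seed = seed, n = n),
            class = "silverman_test")
}

#' @export
print.silverman_test <- function(x, ...) {
  cat(sprintf(
    "Silverman test of %d-modality: h_crit = %.4g, p = %.4g (n = %d, %d bootstraps)\n",
    x$k, x$h_crit, x$p_value, x$n, x$n_boot))
  invisible(x)
}

#' Write a Silverman test result as JSON
#'
#' @param x A `silverman_test` result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_silverman_json <- function(x, path) {
  stopifnot(inherits(x, "silverman_test"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
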