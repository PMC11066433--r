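#' Replicate-noise specification for synthetic datasets
#'
#' Multiplicative noise applied to noise-free model curves. The default
#' family is lognormal (expression measurements are positive and their
#' spread scales with the mean); `gaussian` applies `1 + cv * N(0,1)`
#' truncated at zero.
#'
#' @param family `"lognormal"` or `"gaussian"`.
#' @param cv Coefficient of variation (`>= 0`).
#' @param n_replicates Number of replicates (`>= 1`; the assays use N = 3).
#' @param seed Integer seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(family = c("lognormal", "gaussian"), cv = 0.05,
                       n_replicates = 3, seed = 1) {
  family <- match.arg(family)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(family = family, cv = cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# replicate matrix: one row per design point, columns are replicates
apply_noise <- function(mu, noise) {
  n <- length(mu) * noise$n_replicates
  m <- matrix(rep(mu, noise$n_replicates), ncol = noise$n_replicates)
  if (noise$cv == 0) return(m)
  if (noise$family == "lognormal") {
    sdlog <- sqrt(log(1 + noise$cv^2))
    m * matrix(stats::rlnorm(n, -sdlog^2 / 2, sdlog), nrow = nrow(m))
  } else {
    pmax(m * matrix(1 + noise$cv * stats::rnorm(n), nrow = nrow(m)), 0)
  }
}

#' Generate a synthetic dose-response dataset
#'
#' Replicated THBS1/FMOD observations on a TGF-beta-1 dose grid, generated
#' from the steady-state curves of `true_params` with multiplicative
#' replicate noise. Deterministic given `noise$seed`.
#'
#' @param true_params Generating [core_params()].
#' @param doses Non-negative, strictly increasing dose grid (default: the
#'   assay doses 0, 0.2, 0.8, 4 ng/mL).
#' @param noise A [noise_spec()].
#' @return A [dose_response_dataset()].
#' @export
gen_dose_response <- function(true_params = default_core_params(),
                              doses = c(0, 0.2, 0.8, 4),
                              noise = noise_spec()) {
  if (!length(doses)) stop("dose grid is empty", call. = FALSE)
  set.seed(noise$seed)
  th <- steady_thbs1(doses, true_params)
  fm <- steady_fmod(doses, true_params)
  dose_response_dataset(doses, apply_noise(th, noise),
                        apply_noise(fm, noise),
                        meta = sprintf("synthetic: %s cv=%g seed=%d",
                                       noise$family, noise$cv, noise$seed))
}

#' Generate a synthetic PDL series
#'
#' Replicated THBS1/FMOD/TGF-beta-1 observations over population doubling
#' levels from the endogenous steady-state curves of `true_ext`.
#'
#' @param true_ext Generating [extended_params()].
#' @param pdls PDL design points (default: the three culture stages 24, 36,
#'   47).
#' @param noise A [noise_spec()].
#' @return A [pdl_dataset()].
#' @export
gen_pdl_series <- function(true_ext = default_extended_params(),
                           pdls = c(24, 36, 47), noise = noise_spec()) {
  if (!length(pdls)) stop("pdl grid is empty", call. = FALSE)
  set.seed(noise$seed)
  p <- unlist(unclass(true_ext))
  cv <- endogenous_curves(pdls, p)
  pdl_dataset(pdls, apply_noise(cv$thbs1, noise),
              apply_noise(cv$fmod, noise), apply_noise(cv$tgfb1, noise),
              meta = sprintf("synthetic: %s cv=%g seed=%d",
                             noise$family, noise$cv, noise$seed))
}

#' Generate synthetic pathway time-course training data
#'
#' Simulates the network under `protocol`, samples the normalized
#' observables at the assay time points (default: 0, 0.25, 0.5, 1, 2, 8, 24,
#' 48 h — the eight-point design), and applies replicate noise.
#'
#' @param network A `reaction_network`.
#' @param protocol A [stimulus_protocol()] (default: 1x TGF-beta-1 dose).
#' @param times Observation times (h).
#' @param noise A [noise_spec()].
#' @param observables Which observables to include (default: the five
#'   training readouts; pSMAD2 is conventionally held out for validation).
#' @return A `timecourse_data` object: list with `times`, `obs` (list of
#'   time-by-replicate matrices), `protocol`, `noise`.
#' @export
gen_timecourse <- function(network,
                           protocol = stimulus_protocol(tgfb1_dose = 1),
                           times = c(0, 0.25, 0.5, 1, 2, 8, 24, 48),
                           noise = noise_spec(),
                           observables = c("pSMAD3", "cFos", "THBS1",
                                           "pAkt", "FMOD")) {
  stopifnot(inherits(network, "reaction_network"))
  protocol$t_grid <- times
  traj <- simulate_pathway(network, protocol, horizon = max(times))
  idx <- match(times, traj$times)
  set.seed(noise$seed)
  obs <- lapply(observables, function(ob) {
    mu <- traj$observables[idx, ob]
    apply_noise(mu, noise)
  })
  names(obs) <- observables
  structure(list(times = times, obs = obs, protocol = protocol,
                 noise = noise),
            class = "timecourse_data")
}

#' Write/read time-course training data as TSV
#'
#' Long format: `time`, `replicate`, one column per observable.
#'
#' @param x A `timecourse_data`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse_tsv <- function(x, path) {
  stopifnot(inherits(x, "timecourse_data"))
  nrep <- ncol(x$obs[[1]])
  df <- data.frame(time = rep(x$times, nrep),
                   replicate = rep(seq_len(nrep), each = length(x$times)))
  for (ob in names(x$obs)) df[[ob]] <- as.vector(x$obs[[ob]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic single-cell intensity population
#'
#' Draws `n_cells` terminal THBS1 values from the stochastic ensemble —
#' a synthetic stand-in for per-cell immunofluorescence intensities,
#' suitable as direct input to [silverman_test()].
#'
#' @param params A [core_params()].
#' @param cfg An [sde_config()]; its `n_paths` is overridden by `n_cells`.
#' @param n_cells Number of cells (`>= 1`).
#' @return Numeric vector of length `n_cells`.
#' @export
gen_cell_population <- function(params, cfg = sde_config(), n_cells = 1000) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  cfg$n_paths <- as.integer(n_cells)
  simulate_ensemble(params, cfg)$samples$thbs1
}
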