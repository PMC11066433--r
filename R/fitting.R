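#' Dose-response and PDL-series datasets
#'
#' `dose_response_dataset()` holds replicated THBS1/FMOD observations over a
#' strictly increasing TGF-beta-1 dose grid; `pdl_dataset()` holds replicated
#' THBS1/FMOD/TGF-beta-1 observations over population doubling levels.
#' Observation matrices are dose (or PDL) by replicate.
#'
#' @param doses Strictly increasing TGF-beta-1 doses (assay units).
#' @param thbs1_obs,fmod_obs,tgfb1_obs Observation matrices, rows aligned
#'   with `doses`/`pdls`, one column per replicate, all values `>= 0`.
#' @param meta Optional character note (e.g. normalization provenance).
#' @return A `dose_response_dataset` / `pdl_dataset` object.
#' @export
dose_response_dataset <- function(doses, thbs1_obs, fmod_obs, meta = "") {
  thbs1_obs <- as.matrix(thbs1_obs); fmod_obs <- as.matrix(fmod_obs)
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing",
                                  call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (nrow(thbs1_obs) != length(doses) || nrow(fmod_obs) != length(doses))
    stop("observation matrices must have one row per dose", call. = FALSE)
  if (any(thbs1_obs < 0) || any(fmod_obs < 0))
    stop("negative observations are not allowed", call. = FALSE)
  structure(list(doses = as.numeric(doses), thbs1_obs = thbs1_obs,
                 fmod_obs = fmod_obs, meta = meta),
            class = "dose_response_dataset")
}

#' @rdname dose_response_dataset
#' @param pdls Strictly increasing population doubling levels.
#' @export
pdl_dataset <- function(pdls, thbs1_obs, fmod_obs, tgfb1_obs, meta = "") {
  thbs1_obs <- as.matrix(thbs1_obs); fmod_obs <- as.matrix(fmod_obs)
  tgfb1_obs <- as.matrix(tgfb1_obs)
  if (any(diff(pdls) <= 0)) stop("pdls must be strictly increasing",
                                 call. = FALSE)
  if (any(pdls < 0)) stop("pdls must be >= 0", call. = FALSE)
  for (m in list(thbs1_obs, fmod_obs, tgfb1_obs)) {
    if (nrow(m) != length(pdls))
      stop("observation matrices must have one row per pdl", call. = FALSE)
    if (any(m < 0)) stop("negative observations are not allowed",
                         call. = FALSE)
  }
  structure(list(pdls = as.numeric(pdls), thbs1_obs = thbs1_obs,
                 fmod_obs = fmod_obs, tgfb1_obs = tgfb1_obs, meta = meta),
            class = "pdl_dataset")
}

#' Read/write replicated datasets as CSV
#'
#' Long format with header `dose,replicate,thbs1,fmod` (dose-response) or
#' `pdl,replicate,thbs1,fmod,tgfb1` (PDL series).
#'
#' @param x A dataset object.
#' @param path CSV file path.
#' @return `write_*` return `path` invisibly; `read_*` return the dataset.
#' @export
write_dataset_csv <- function(x, path) {
  if (inherits(x, "dose_response_dataset")) {
    df <- data.frame(
      dose = rep(x$doses, ncol(x$thbs1_obs)),
      replicate = rep(seq_len(ncol(x$thbs1_obs)), each = length(x$doses)),
      thbs1 = as.vector(x$thbs1_obs), fmod = as.vector(x$fmod_obs))
  } else if (inherits(x, "pdl_dataset")) {
    df <- data.frame(
      pdl = rep(x$pdls, ncol(x$thbs1_obs)),
      replicate = rep(seq_len(ncol(x$thbs1_obs)), each = length(x$pdls)),
      thbs1 = as.vector(x$thbs1_obs), fmod = as.vector(x$fmod_obs),
      tgfb1 = as.vector(x$tgfb1_obs))
  } else stop("unsupported dataset class", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  wide <- function(col, key) {
    m <- tapply(df[[col]], list(df[[key]], df$replicate), identity)
    m[order(as.numeric(rownames(m))), , drop = FALSE]
  }
  if ("pdl" %in% names(df)) {
    pdls <- sort(unique(df$pdl))
    pdl_dataset(pdls, wide("thbs1", "pdl"), wide("fmod", "pdl"),
                wide("tgfb1", "pdl"))
  } else {
    doses <- sort(unique(df$dose))
    dose_response_dataset(doses, wide("thbs1", "dose"), wide("fmod", "dose"))
  }
}

# bounded Levenberg-Marquardt least squares with a deterministic multi-start
# over Hill exponents; residual_fn(par) returns the residual vector
lm_multistart <- function(residual_fn, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = residual_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-14, ptol = 1e-14)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("least-squares optimization failed from every start",
                          call. = FALSE)
  best
}

new_fit_result <- function(estimates, residual_ss, n_obs, converged, start,
                           lower, upper) {
  structure(list(estimates = estimates, residual_ss = residual_ss,
                 n_obs = n_obs, converged = converged, start = start,
                 lower = lower, upper = upper),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nonlinear least-squares fit\n")
  est <- x$estimates
  cat(paste(sprintf("  %-6s = %.6g", names(est), est), collapse = "\n"), "\n")
  cat(sprintf("  residual SS = %.6g over %d observations (%s)\n",
              x$residual_ss, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the steady-state dose-response curves
#'
#' Jointly fits the THBS1 Hill curve `A1 * d^na/(d^na + Ka)` and the FMOD
#' repression curve `A2 * Kb/(d^nb + Kb)` to replicated observations by
#' pooled least squares (each replicate contributes its own residual).
#' Optimization is bounded Levenberg-Marquardt from a deterministic set of
#' starts (the documented default start plus a small ladder of Hill-exponent
#' starts, which makes noise-free recovery robust to the steep small-dose
#' region).
#'
#' @param data A [dose_response_dataset()].
#' @param start Optional named start vector
#'   (`a_d1`, `Ka`, `na`, `b_d2`, `Kb`, `nb`).
#' @param lower,upper Bounds; defaults: amplitudes (1e-6, 100],
#'   half-saturations (1e-6, 1e3], exponents [0.5, 6].
#' @return A `fit_result` with estimates `a_d1`, `Ka`, `na`, `b_d2`, `Kb`,
#'   `nb`.
#' @export
fit_dose_response <- function(data, start = NULL, lower = NULL, upper = NULL) {
  stopifnot(inherits(data, "dose_response_dataset"))
  d <- data$doses
  if (length(d) < 4)
    stop("under-determined: need >= 4 distinct doses for six parameters",
         call. = FALSE)
  nrep <- ncol(data$thbs1_obs)
  dm <- rep(d, nrep)
  y1 <- as.vector(data$thbs1_obs); y2 <- as.vector(data$fmod_obs)
  if (is.null(lower)) lower <- c(a_d1 = 1e-6, Ka = 1e-6, na = 0.5,
                                 b_d2 = 1e-6, Kb = 1e-6, nb = 0.5)
  if (is.null(upper)) upper <- c(a_d1 = 100, Ka = 1e3, na = 6,
                                 b_d2 = 100, Kb = 1e3, nb = 6)
  resid_fn <- function(p) {
    c(p[["a_d1"]] * dm^p[["na"]] / (dm^p[["na"]] + p[["Ka"]]) - y1,
      p[["b_d2"]] * p[["Kb"]] / (dm^p[["nb"]] + p[["Kb"]]) - y2)
  }
  med <- stats::median(d[d > 0])
  starts <- if (!is.null(start)) list(start) else {
    lapply(c(1, 1.5, 2, 3), function(n0)
      c(a_d1 = max(y1), Ka = med^n0, na = n0,
        b_d2 = max(y2), Kb = med^n0, nb = n0))
  }
  starts <- lapply(starts, function(s) pmin(pmax(s[names(lower)], lower),
                                            upper))
  fit <- lm_multistart(resid_fn, starts, lower, upper)
  new_fit_result(stats::setNames(fit$par, names(lower)), fit$deviance,
                 2L * length(dm), fit$info %in% 1:4, starts[[1]],
                 lower, upper)
}

# endogenous observables at given PDLs for a named parameter vector
endogenous_curves <- function(pdls, p) {
  th <- p[["alpha"]] * pdls / (pdls + p[["Kalpha"]])
  fm <- p[["beta"]] * p[["Kbeta"]] / (pdls + p[["Kbeta"]])
  tg <- p[["gamma"]] * (th / (th + p[["K1t"]])) * (p[["K2t"]] / (fm + p[["K2t"]]))
  list(thbs1 = th, fmod = fm, tgfb1 = tg)
}

#' Fit the endogenous (PDL) steady-state model
#'
#' Jointly fits the PDL curves for THBS1 (`alpha PDL/(PDL+Kalpha)`), FMOD
#' (`beta Kbeta/(PDL+Kbeta)`) and TGF-beta-1 (the production term with the
#' two PDL curves substituted) to replicated observations by pooled least
#' squares.
#'
#' @param data A [pdl_dataset()] with at least 3 distinct PDL values.
#' @param start Optional named start
#'   (`alpha`, `Kalpha`, `beta`, `Kbeta`, `gamma`, `K1t`, `K2t`).
#' @param lower,upper Bounds (same default families as
#'   [fit_dose_response()]).
#' @return A `fit_result` with the seven endogenous parameters.
#' @export
fit_endogenous <- function(data, start = NULL, lower = NULL, upper = NULL) {
  stopifnot(inherits(data, "pdl_dataset"))
  pdls <- data$pdls
  if (length(unique(pdls)) < 3)
    stop("under-determined: need >= 3 distinct PDL values", call. = FALSE)
  nrep <- ncol(data$thbs1_obs)
  pm <- rep(pdls, nrep)
  y1 <- as.vector(data$thbs1_obs); y2 <- as.vector(data$fmod_obs)
  y3 <- as.vector(data$tgfb1_obs)
  if (is.null(lower)) lower <- c(alpha = 1e-6, Kalpha = 1e-6,
                                 beta = 1e-6, Kbeta = 1e-6,
                                 gamma = 1e-6, K1t = 1e-6, K2t = 1e-6)
  if (is.null(upper)) upper <- c(alpha = 100, Kalpha = 1e3,
                                 beta = 100, Kbeta = 1e3,
                                 gamma = 100, K1t = 1e3, K2t = 1e3)
  resid_fn <- function(p) {
    cv <- endogenous_curves(pm, p)
    c(cv$thbs1 - y1, cv$fmod - y2, cv$tgfb1 - y3)
  }
  med <- stats::median(pdls)
  starts <- if (!is.null(start)) list(start) else {
    lapply(c(0.5, 1, 2), function(f)
      c(alpha = max(y1), Kalpha = f * med, beta = max(y2), Kbeta = f * med,
        gamma = max(y3), K1t = f * max(y1) / 2, K2t = f * max(y2) / 2))
  }
  starts <- lapply(starts, function(s) pmin(pmax(s[names(lower)], lower),
                                            upper))
  fit <- lm_multistart(resid_fn, starts, lower, upper)
  new_fit_result(stats::setNames(fit$par, names(lower)), fit$deviance,
                 3L * length(pm), fit$info %in% 1:4, starts[[1]],
                 lower, upper)
}

#' Profile the residual sum of squares along one parameter
#'
#' Refits all other parameters at each grid value of the named parameter and
#' returns the profiled residual sum of squares; an identifiability
#' diagnostic. The profile minimum coincides with the joint estimate.
#'
#' @param result A `fit_result` from [fit_dose_response()] or
#'   [fit_endogenous()].
#' @param data The dataset the fit used.
#' @param parameter Name of the profiled parameter.
#' @param grid Numeric grid of values for the profiled parameter.
#' @return Data frame with columns `value` and `residual_ss`.
#' @export
residual_profile <- function(result, data, parameter, grid) {
  stopifnot(inherits(result, "fit_result"))
  if (!parameter %in% names(result$estimates))
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  est <- result$estimates
  if (min(grid) > est[[parameter]] || max(grid) < est[[parameter]])
    warning("profile grid does not cover the estimate", call. = FALSE)
  fitter <- if (inherits(data, "dose_response_dataset")) fit_dose_response
            else fit_endogenous
  ss <- vapply(grid, function(v) {
    start <- est; start[[parameter]] <- v
    lo <- result$lower; up <- result$upper
    lo[[parameter]] <- v; up[[parameter]] <- v
    fitter(data, start = start, lower = lo, upper = up)$residual_ss
  }, 0)
  data.frame(value = grid, residual_ss = ss)
}

#' Write a fit result as JSON
#'
#' @param x A `fit_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  stopifnot(inherits(x, "fit_result"))
  jsonlite::write_json(
    list(estimates = as.list(x$estimates), residual_ss = x$residual_ss,
         n_obs = x$n_obs, converged = x$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
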