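#' One-parameter bifurcation scan of the reduced switch
#'
#' Computes the fixed-point set at every value of a scanned parameter
#' (`"K1"`, `"K2"` or `"gamma"`, the latter meaning the lumped production
#' ratio `c/d3`) and locates fold (saddle-node) points, i.e. parameter
#' values where the nonzero fixed-point count changes by two, by bisection
#' between adjacent grid values.
#'
#' @param params Base [core_params()] object.
#' @param param_name One of `"K1"`, `"K2"`, `"gamma"`.
#' @param lo,hi Scan range (`lo < hi`, both `> 0`).
#' @param n_points Number of grid values (`>= 2`); the grid is log-spaced.
#' @param fold_tol Bisection tolerance on fold location.
#' @param ... Passed to [find_fixed_points()].
#' @return A `bifurcation_diagram`: list with `param_name`, `param_values`,
#'   `branches` (list of `fixed_point_set`) and `fold_points` (numeric).
#' @export
scan_parameter <- function(params, param_name, lo, hi, n_points = 512,
                           fold_tol = 1e-7, ...) {
  stopifnot(inherits(params, "core_params"))
  if (!param_name %in% c("K1", "K2", "gamma"))
    stop("unknown param_name '", param_name,
         "'; valid names: K1, K2, gamma", call. = FALSE)
  if (lo >= hi || lo <= 0) stop("need 0 < lo < hi", call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  grid <- exp(seq(log(lo), log(hi), length.out = n_points))
  at <- function(v) {
    p <- params
    if (param_name == "gamma") p$c <- v * p$d3 else p[[param_name]] <- v
    p
  }
  branches <- lapply(grid, function(v) find_fixed_points(at(v), ...))
  counts <- vapply(branches, function(b) length(b$points), 0L)
  folds <- numeric(0)
  for (i in seq_len(n_points - 1)) {
    if (counts[i] != counts[i + 1]) {
      a <- grid[i]; b <- grid[i + 1]
      ca <- counts[i]
      while (b - a > fold_tol * max(1, a)) {
        m <- (a + b) / 2
        cm <- length(find_fixed_points(at(m), ...)$points)
        if (cm == ca) a <- m else b <- m
      }
      folds <- c(folds, (a + b) / 2)
    }
  }
  structure(list(param_name = param_name, param_values = grid,
                 branches = branches, fold_points = folds,
                 params = params),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation scan of %s over [%.4g, %.4g] (%d points)\n",
              x$param_name, min(x$param_values), max(x$param_values),
              length(x$param_values)))
  if (length(x$fold_points))
    cat("  fold points:", paste(signif(x$fold_points, 6), collapse = ", "),
        "\n")
  else cat("  no fold points detected\n")
  invisible(x)
}

#' Flatten a bifurcation diagram to a data frame
#'
#' @param x A `bifurcation_diagram`.
#' @param ... Unused.
#' @return Data frame with columns `param_value`, `tgfb1`, `thbs1`, `fmod`,
#'   `stability`.
#' @export
as.data.frame.bifurcation_diagram <- function(x, ...) {
  out <- Map(function(v, b) {
    df <- as.data.frame(b)
    df$param_value <- v
    df
  }, x$param_values, x$branches)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("param_value", "tgfb1", "thbs1", "fmod", "stability")]
}

#' Saddle-node value of the endogenous production rate gamma
#'
#' Along the gamma axis the reduced map factorizes as
#' `f(T) = gamma * g(T)` with `g` independent of gamma, so the nonzero
#' branch exists exactly for `gamma >= min_{T>0} T / g(T)`. The fold is
#' found by bounded 1-D minimization of `T/g(T)` on a log scale, to relative
#' tolerance `tol`.
#'
#' @param params A [core_params()] object whose `K1`, `K2` (and Hill arms)
#'   define `g`; its `c/d3` value is irrelevant to the result.
#' @param interval Search interval for `T` (log-minimized inside it).
#' @param tol Relative tolerance of the minimizer.
#' @return The fold value `gamma*` (scalar, with attribute `T_fold`, the
#'   TGF-beta-1 level at the fold).
#' @export
saddle_node_gamma <- function(params, interval = c(1e-8, 1e3), tol = 1e-6) {
  stopifnot(inherits(params, "core_params"))
  g <- function(T) reduced_map(T, params) / (params$c / params$d3)
  obj <- function(logT) { T <- exp(logT); T / g(T) }
  o <- stats::optimize(obj, log(interval), tol = tol / 4)
  Tf <- exp(o$minimum)
  span <- diff(log(interval))
  if (min(abs(o$minimum - log(interval))) < 1e-3 * span)
    stop("fold search hit the interval boundary; widen 'interval'",
         call. = FALSE)
  structure(o$objective, T_fold = Tf)
}

#' Saddle-node value of the THBS1 half-saturation constant K1
#'
#' Along the K1 axis the fixed-point condition `T = c/d3 * TH/(TH+K1) * g2`
#' solves for `K1` explicitly on the nonzero branch:
#' `K1(T) = TH(T) * ((c/d3) g2(T)/T - 1)`, so the branch exists exactly for
#' `K1 <= max_{T>0} K1(T)`. The fold is found by bounded 1-D maximization on
#' a log scale.
#'
#' @inheritParams saddle_node_gamma
#' @return The fold value `K1*` (with attribute `T_fold`). If the branch
#'   does not exist for any positive `K1` the returned value is negative.
#' @export
saddle_node_k1 <- function(params, interval = c(1e-8, 1e3), tol = 1e-6) {
  stopifnot(inherits(params, "core_params"))
  k1_of <- function(T) {
    TH <- steady_thbs1(T, params)
    FM <- steady_fmod(T, params)
    g2 <- params$K2 / (FM + params$K2)
    TH * ((params$c / params$d3) * g2 / T - 1)
  }
  o <- stats::optimize(function(logT) -k1_of(exp(logT)), log(interval),
                       tol = tol / 4)
  structure(-o$objective, T_fold = exp(o$minimum))
}

#' Choose the production scale that places the K1 fold at a given location
#'
#' The imaging-scale bifurcation scans are run at a production ratio `c/d3`
#' that places the saddle-node along `K1` at a chosen value (default 15, so
#' that `K1 = 14` sits just inside the bistable region and small `K1` is
#' deep in the monostable high regime). Returns `params` with `c` set
#' accordingly.
#'
#' @param params A [core_params()] object (its `K2`, Hill arms are kept).
#' @param k1_fold Desired fold location along `K1`.
#' @return A [core_params()] object.
#' @export
calibrate_cd3_for_k1_fold <- function(params = default_core_params(),
                                      k1_fold = 15) {
  f <- function(cd3) {
    p <- params; p$c <- cd3 * p$d3
    as.numeric(saddle_node_k1(p)) - k1_fold
  }
  cd3 <- stats::uniroot(f, c(1e-3, 1e3), tol = 1e-10)$root
  params$c <- cd3 * params$d3
  params
}

#' Two-parameter bistability map over (K1, K2)
#'
#' Counts the stable steady states (the zero state included) of the reduced
#' switch on a grid of `(K1, K2)` values. Cells with count `>= 2` form the
#' bistable region. An asymmetry summary reports, for the middle row and
#' column of the grid, the extent of the bistable interval along each axis.
#'
#' @param params Base [core_params()] object (its `c/d3` sets the production
#'   scale).
#' @param k1_range,k2_range Positive ranges for `K1` and `K2`.
#' @param n_k1,n_k2 Grid sizes.
#' @param ... Passed to [find_fixed_points()].
#' @return A `bistability_map`: list with `k1_grid`, `k2_grid`,
#'   `state_count` (matrix, rows = K1, columns = K2), `asymmetry`, `params`.
#' @export
bistability_map <- function(params, k1_range = c(0.05, 20),
                            k2_range = c(0.05, 20),
                            n_k1 = 101, n_k2 = 101, ...) {
  stopifnot(inherits(params, "core_params"))
  if (any(c(k1_range, k2_range) <= 0)) stop("ranges must be positive",
                                            call. = FALSE)
  k1_grid <- exp(seq(log(k1_range[1]), log(k1_range[2]), length.out = n_k1))
  k2_grid <- exp(seq(log(k2_range[1]), log(k2_range[2]), length.out = n_k2))
  cnt <- matrix(NA_integer_, n_k1, n_k2)
  p <- params
  for (i in seq_len(n_k1)) {
    p$K1 <- k1_grid[i]
    for (j in seq_len(n_k2)) {
      p$K2 <- k2_grid[j]
      cnt[i, j] <- n_stable(find_fixed_points(p, ...))
    }
  }
  mid_i <- ceiling(n_k1 / 2); mid_j <- ceiling(n_k2 / 2)
  bi_row <- k2_grid[cnt[mid_i, ] >= 2]  # K2 extent at fixed (middle) K1
  bi_col <- k1_grid[cnt[, mid_j] >= 2]  # K1 extent at fixed (middle) K2
  asym <- list(
    k1_fixed = k1_grid[mid_i],
    k2_bistable_extent = if (length(bi_row)) range(bi_row) else NULL,
    k2_fixed = k2_grid[mid_j],
    k1_bistable_extent = if (length(bi_col)) range(bi_col) else NULL)
  structure(list(k1_grid = k1_grid, k2_grid = k2_grid, state_count = cnt,
                 asymmetry = asym, params = params),
            class = "bistability_map")
}

#' @export
print.bistability_map <- function(x, ...) {
  cat(sprintf("Bistability map: %d x %d grid, stable-state counts %s\n",
              length(x$k1_grid), length(x$k2_grid),
              paste(sort(unique(as.vector(x$state_count))), collapse = "/")))
  frac <- mean(x$state_count >= 2)
  cat(sprintf("  bistable fraction of grid: %.1f%%\n", 100 * frac))
  invisible(x)
}

#' Export bifurcation results as plain text
#'
#' `write_bifurcation_tsv()` writes the flattened branch table
#' (`param_value`, `tgfb1`, `thbs1`, `fmod`, `stability`);
#' `write_bistability_tsv()` writes the long-format `(k1, k2, stable_count)`
#' grid; `write_folds_json()` writes the fold locations.
#'
#' @param x A `bifurcation_diagram` or `bistability_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bifurcation_tsv <- function(x, path) {
  stopifnot(inherits(x, "bifurcation_diagram"))
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) format_num(col) else col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bifurcation_tsv
#' @export
write_bistability_tsv <- function(x, path) {
  stopifnot(inherits(x, "bistability_map"))
  df <- expand.grid(k1 = x$k1_grid, k2 = x$k2_grid, KEEP.OUT.ATTRS = FALSE)
  df$stable_count <- as.vector(x$state_count)
  df$k1 <- format_num(df$k1); df$k2 <- format_num(df$k2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bifurcation_tsv
#' @export
write_folds_json <- function(x, path) {
  stopifnot(inherits(x, "bifurcation_diagram"))
  jsonlite::write_json(
    list(param_name = x$param_name, fold_points = x$fold_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# locale-independent fixed significant-digit formatting for text outputs
format_num <- function(x, digits = 12) {
  formatC(x, digits = digits, format = "g")
}
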