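#' Right-hand side of the core switch ODEs
#'
#' The core network couples THBS1 (activated by TGF-beta-1 through a Hill
#' term, positive arm), FMOD (repressed by TGF-beta-1, negative arm) and
#' TGF-beta-1 (produced when THBS1 is present and FMOD is absent, decayed
#' linearly):
#' \deqn{d[THBS1]/dt = a T^{na}/(T^{na}+Ka) - d_1 [THBS1]}
#' \deqn{d[FMOD]/dt  = b Kb/(T^{nb}+Kb) - d_2 [FMOD]}
#' \deqn{d[TGFb1]/dt = c \frac{[THBS1]}{[THBS1]+K_1}\frac{K_2}{[FMOD]+K_2}
#'   - d_3 T}
#' with \eqn{T = [TGFb1]}.
#'
#' @param state Numeric vector `c(thbs1, fmod, tgfb1)`, all `>= 0`.
#' @param params A [core_params()] object.
#' @return Numeric vector of the three time-derivatives, named as `state`.
#' @export
core_rhs <- function(state, params) {
  stopifnot(inherits(params, "core_params"))
  state <- as_system_state(state)
  TH <- state[["thbs1"]]; FM <- state[["fmod"]]; TG <- state[["tgfb1"]]
  p <- params
  c(thbs1 = p$a * TG^p$na / (TG^p$na + p$Ka) - p$d1 * TH,
    fmod  = p$b * p$Kb / (TG^p$nb + p$Kb)   - p$d2 * FM,
    tgfb1 = p$c * (TH / (TH + p$K1)) * (p$K2 / (FM + p$K2)) - p$d3 * TG)
}

as_system_state <- function(state) {
  if (length(state) != 3L)
    stop("state must have 3 components (thbs1, fmod, tgfb1)", call. = FALSE)
  state <- as.numeric(state)
  nms <- c("thbs1", "fmod", "tgfb1")
  for (i in 1:3) {
    if (!is.finite(state[i]))
      stop("state component '", nms[i], "' is not finite", call. = FALSE)
    if (state[i] < 0)
      stop("state component '", nms[i], "' is negative", call. = FALSE)
  }
  names(state) <- nms
  state
}

check_dose <- function(tgfb1) {
  if (any(!is.finite(tgfb1)) || any(tgfb1 < 0))
    stop("tgfb1 must be finite and >= 0", call. = FALSE)
  invisible(tgfb1)
}

#' Steady-state THBS1 and FMOD levels as functions of TGF-beta-1
#'
#' Closed-form steady states of the fast arms:
#' `steady_thbs1` returns \eqn{(a/d_1)\,T^{na}/(T^{na}+Ka)} (non-decreasing),
#' `steady_fmod` returns \eqn{(b/d_2)\,Kb/(T^{nb}+Kb)} (non-increasing).
#'
#' @param tgfb1 TGF-beta-1 level(s), `>= 0` (vectorized).
#' @param params A [core_params()] object.
#' @return Numeric vector of steady levels.
#' @export
steady_thbs1 <- function(tgfb1, params = default_core_params()) {
  stopifnot(inherits(params, "core_params"))
  check_dose(tgfb1)
  (params$a / params$d1) * tgfb1^params$na / (tgfb1^params$na + params$Ka)
}

#' @rdname steady_thbs1
#' @export
steady_fmod <- function(tgfb1, params = default_core_params()) {
  stopifnot(inherits(params, "core_params"))
  check_dose(tgfb1)
  (params$b / params$d2) * params$Kb / (tgfb1^params$nb + params$Kb)
}

#' Reduced scalar TGF-beta-1 steady-state map
#'
#' Substituting the steady THBS1 and FMOD arms into the TGF-beta-1 production
#' term collapses the system to one scalar map
#' \deqn{f(T) = (c/d_3)\,\frac{\bar{TH}(T)}{\bar{TH}(T)+K_1}\,
#'   \frac{K_2}{\bar{F}(T)+K_2},}
#' whose fixed points `T = f(T)` are exactly the TGF-beta-1 steady states of
#' the full three-variable system.
#'
#' @inheritParams steady_thbs1
#' @return `reduced_map`: the map value(s); `reduced_map_deriv`: the
#'   derivative \eqn{f'(T)} (closed form).
#' @export
reduced_map <- function(tgfb1, params = default_core_params()) {
  TH <- steady_thbs1(tgfb1, params)
  FM <- steady_fmod(tgfb1, params)
  (params$c / params$d3) * (TH / (TH + params$K1)) *
    (params$K2 / (FM + params$K2))
}

#' @rdname reduced_map
#' @export
reduced_map_deriv <- function(tgfb1, params = default_core_params()) {
  stopifnot(inherits(params, "core_params"))
  check_dose(tgfb1)
  p <- params
  T <- tgfb1
  A1 <- p$a / p$d1; A2 <- p$b / p$d2
  u <- T^p$na; v <- T^p$nb
  TH <- A1 * u / (u + p$Ka)
  FM <- A2 * p$Kb / (v + p$Kb)
  # dTH/dT and dFM/dT
  dTH <- A1 * p$Ka * p$na * ifelse(T > 0, u / T, ifelse(p$na == 1, 1, 0)) /
    (u + p$Ka)^2
  dFM <- -A2 * p$Kb * p$nb * ifelse(T > 0, v / T, ifelse(p$nb == 1, 1, 0)) /
    (v + p$Kb)^2
  g1 <- TH / (TH + p$K1)
  g2 <- p$K2 / (FM + p$K2)
  dg1 <- p$K1 / (TH + p$K1)^2 * dTH
  dg2 <- -p$K2 / (FM + p$K2)^2 * dFM
  (p$c / p$d3) * (dg1 * g2 + g1 * dg2)
}

#' Jacobian of the core ODEs at a state
#'
#' @param state Numeric state vector `c(thbs1, fmod, tgfb1)`.
#' @param params A [core_params()] object.
#' @return A 3x3 matrix.
#' @export
core_jacobian <- function(state, params) {
  stopifnot(inherits(params, "core_params"))
  state <- as_system_state(state)
  p <- params
  TH <- state[["thbs1"]]; FM <- state[["fmod"]]; TG <- state[["tgfb1"]]
  u <- TG^p$na; v <- TG^p$nb
  dthdT <- p$a * p$Ka * p$na * ifelse(TG > 0, u / TG, ifelse(p$na == 1, 1, 0)) /
    (u + p$Ka)^2
  dfmdT <- -p$b * p$Kb * p$nb * ifelse(TG > 0, v / TG, ifelse(p$nb == 1, 1, 0)) /
    (v + p$Kb)^2
  g2 <- p$K2 / (FM + p$K2)
  dtgdTH <- p$c * g2 * p$K1 / (TH + p$K1)^2
  dtgdFM <- -p$c * (TH / (TH + p$K1)) * p$K2 / (FM + p$K2)^2
  matrix(c(-p$d1, 0,      dthdT,
           0,     -p$d2,  dfmdT,
           dtgdTH, dtgdFM, -p$d3),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("thbs1", "fmod", "tgfb1"),
                         c("thbs1", "fmod", "tgfb1")))
}

#' Classify the stability of a TGF-beta-1 fixed point
#'
#' In `reduced` mode the scalar criterion is used: the point is stable iff
#' `f'(T) < 1` where `f` is [reduced_map()]. In `jacobian` mode the 3x3
#' Jacobian of the full system is evaluated and the point is stable iff all
#' eigenvalues have negative real part. A derivative within `marginal_tol`
#' of 1 is labeled `"marginal"` with a warning (fold vicinity).
#'
#' @param tgfb1 The fixed-point TGF-beta-1 value.
#' @param params A [core_params()] object.
#' @param mode `"reduced"` or `"jacobian"`.
#' @param marginal_tol Half-width of the marginal band around `f'(T) = 1`.
#' @return A `fixed_point` object: list with `state` (named 3-vector),
#'   `tgfb1`, `stability`, `slope` and (jacobian mode) `eigenvalues`.
#' @export
classify_stability <- function(tgfb1, params, mode = c("reduced", "jacobian"),
                               marginal_tol = 1e-6) {
  mode <- match.arg(mode)
  check_dose(tgfb1)
  st <- c(thbs1 = steady_thbs1(tgfb1, params),
          fmod = steady_fmod(tgfb1, params),
          tgfb1 = tgfb1)
  slope <- reduced_map_deriv(tgfb1, params)
  eig <- NULL
  if (mode == "reduced") {
    if (abs(slope - 1) < marginal_tol) {
      warning("map derivative within tolerance of 1; fold vicinity",
              call. = FALSE)
      stability <- "marginal"
    } else {
      stability <- if (slope < 1) "stable" else "unstable"
    }
  } else {
    eig <- eigen(core_jacobian(st, params), only.values = TRUE)$values
    mre <- max(Re(eig))
    if (abs(mre) < marginal_tol) {
      warning("leading eigenvalue within tolerance of 0; fold vicinity",
              call. = FALSE)
      stability <- "marginal"
    } else {
      stability <- if (mre < 0) "stable" else "unstable"
    }
  }
  structure(list(state = st, tgfb1 = unname(tgfb1), stability = stability,
                 slope = unname(slope), eigenvalues = eig),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point: tgfb1 = %.6g (%s, slope %.4g)\n",
              x$tgfb1, x$stability, x$slope))
  invisible(x)
}

#' Find all TGF-beta-1 fixed points of the reduced map
#'
#' Locates every root of `T - reduced_map(T)` inside `search_interval` by
#' sign-change bracketing on a dense grid (log-spaced near the origin, where
#' the map is extremely steep, plus a linear tail) followed by Newton
#' refinement of each bracket; brackets where Newton stalls fall back to
#' bisection (`uniroot`) and are flagged. The trivial zero state
#' `(THBS1, FMOD, TGFb1) = (0, b/d2, 0)` is always included; for `na > 1`
#' the map is superlinear at the origin, so the zero state is stable.
#'
#' @param params A [core_params()] object.
#' @param search_interval Range of TGF-beta-1 scanned for nonzero roots. The
#'   upper bound must exceed `c/d3` (the supremum of the map).
#' @param tol Residual tolerance `|T - f(T)|` for accepted roots.
#' @param n_grid Number of bracketing grid points.
#' @param mode Stability mode passed to [classify_stability()].
#' @return A `fixed_point_set`: list with `points` (list of `fixed_point`,
#'   ordered by increasing `tgfb1`), `params`, `search_interval`,
#'   `newton_fallback` (logical, any bisection fallback used).
#' @export
find_fixed_points <- function(params, search_interval = NULL, tol = 1e-10,
                              n_grid = 4096, mode = "reduced") {
  stopifnot(inherits(params, "core_params"))
  sup <- params$c / params$d3
  if (is.null(search_interval)) search_interval <- c(0, 2 * sup + 1)
  if (search_interval[1] > search_interval[2])
    stop("search_interval is inverted", call. = FALSE)
  if (search_interval[2] <= sup)
    stop("search_interval upper bound must exceed c/d3 = ", signif(sup, 4),
         call. = FALSE)
  lo <- max(search_interval[1], 1e-13)
  hi <- search_interval[2]
  # log-spaced portion near zero plus linear tail
  grid <- sort(unique(c(
    exp(seq(log(lo), log(hi), length.out = ceiling(n_grid / 2))),
    seq(lo, hi, length.out = floor(n_grid / 2)))))
  res <- grid - reduced_map(grid, params)
  roots <- numeric(0)
  fallback <- FALSE
  sgn <- sign(res)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0 | res[-length(res)] == 0)
  fn <- function(T) T - reduced_map(T, params)
  fp <- function(T) 1 - reduced_map_deriv(T, params)
  for (i in idx) {
    a <- grid[i]; b <- grid[i + 1]
    # Newton from the midpoint, confined to the bracket
    x <- (a + b) / 2
    ok <- FALSE
    for (it in 1:100) {
      fx <- fn(x)
      if (abs(fx) < tol) { ok <- TRUE; break }
      d <- fp(x)
      if (!is.finite(d) || d == 0) break
      xn <- x - fx / d
      if (!is.finite(xn) || xn <= a || xn >= b) break
      if (abs(xn - x) < .Machine$double.eps * max(1, abs(x)) && abs(fx) < 1e3 * tol) {
        x <- xn; ok <- abs(fn(x)) < 1e3 * tol; break
      }
      x <- xn
    }
    if (!ok) {
      x <- stats::uniroot(fn, c(a, b), tol = .Machine$double.eps^0.75)$root
      fallback <- TRUE
    }
    roots <- c(roots, x)
  }
  roots <- roots[!duplicated(signif(roots, 9))]
  roots <- sort(c(0, roots[roots > 1e-12]))
  pts <- lapply(roots, classify_stability, params = params, mode = mode)
  structure(list(points = pts, params = params,
                 search_interval = search_interval,
                 newton_fallback = fallback),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("Fixed point set: %d point(s) on [%.3g, %.3g]\n",
              length(x$points), x$search_interval[1], x$search_interval[2]))
  for (p in x$points)
    cat(sprintf("  tgfb1 = %-12.6g thbs1 = %-10.4g fmod = %-10.4g %s\n",
                p$tgfb1, p$state[["thbs1"]], p$state[["fmod"]], p$stability))
  invisible(x)
}

#' Extract a data frame from a fixed-point set
#'
#' @param x A `fixed_point_set`.
#' @param ... Unused.
#' @return A data frame with columns `tgfb1`, `thbs1`, `fmod`, `stability`,
#'   `slope`.
#' @export
as.data.frame.fixed_point_set <- function(x, ...) {
  data.frame(
    tgfb1 = vapply(x$points, function(p) p$tgfb1, 0),
    thbs1 = vapply(x$points, function(p) p$state[["thbs1"]], 0),
    fmod = vapply(x$points, function(p) p$state[["fmod"]], 0),
    stability = vapply(x$points, function(p) p$stability, ""),
    slope = vapply(x$points, function(p) p$slope, 0))
}

#' Count stable states in a fixed-point set
#' @param x A `fixed_point_set`.
#' @return Integer count of points labeled stable.
#' @export
n_stable <- function(x) {
  sum(vapply(x$points, function(p) p$stability == "stable", FALSE))
}

#' Integrate the core ODEs deterministically
#'
#' Explicit forward-Euler integration of the full three-variable system
#' (matching the convention of the stochastic scheme), with non-negativity
#' clamping of the state after every step. An `adaptive` method using
#' `deSolve::ode` (lsoda) is also available.
#'
#' @param initial State vector `c(thbs1, fmod, tgfb1)`.
#' @param params A [core_params()] object.
#' @param t_end Integration horizon (`> 0`).
#' @param dt Output/Euler step (`> 0`).
#' @param method `"euler"` (default) or `"adaptive"`.
#' @return A data frame with columns `time`, `thbs1`, `fmod`, `tgfb1`.
#' @export
simulate_deterministic <- function(initial, params, t_end, dt = 0.01,
                                   method = c("euler", "adaptive")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "core_params"))
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be > 0", call. = FALSE)
  x0 <- as_system_state(initial)
  times <- seq(0, t_end, by = dt)
  if (method == "adaptive") {
    out <- deSolve::ode(
      y = x0, times = times, parms = NULL,
      func = function(t, y, parms) list(core_rhs(pmax(y, 0), params)))
    df <- as.data.frame(out)
    names(df) <- c("time", "thbs1", "fmod", "tgfb1")
    return(df)
  }
  n <- length(times)
  traj <- matrix(NA_real_, n, 3, dimnames = list(NULL, names(x0)))
  x <- x0
  traj[1, ] <- x
  for (i in 2:n) {
    x <- pmax(x + dt * core_rhs(x, params), 0)
    if (any(!is.finite(x)))
      stop("integration diverged (non-finite state); use a smaller dt",
           call. = FALSE)
    traj[i, ] <- x
  }
  data.frame(time = times, traj)
}
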