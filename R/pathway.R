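#' Reduced TGF-beta / VEGF crosstalk reaction network
#'
#' Builds the default reduced mechanistic network linking TGF-beta receptor
#' signaling to THBS1 and VEGF receptor signaling to FMOD:
#' latent TGF-beta-1 is activated by THBS1 (positive feedback), active
#' TGF-beta-1 binds its receptor unless sequestered by FMOD, receptor
#' activity phosphorylates SMAD2 and SMAD3, the phospho-SMADs assemble with
#' SMAD4 into the transcriptional trimer (reaction `trimer_form`), SMAD7 is
#' induced and inactivates the receptor (negative feedback), and THBS1
#' transcription is an AND gate of the SMAD trimer and AP-1 (c-Fos). On the
#' VEGF side, VEGFR drives the Raf-MEK-ERK cascade, ERK activates a lumped
#' FMOD transcription factor, and FMOD transcription is repressed by pAkt;
#' PI3K-Akt is driven by the active TGF-beta receptor (the crosstalk arm).
#'
#' Every reaction is a named rate law of the form
#' `k * prod(linear factors) * prod(Hill activations) * prod(repressions)`;
#' mass balance is carried by an explicit stoichiometry, and the SMAD2,
#' SMAD3, SMAD4, Raf, MEK, ERK, Akt, PI3K, FMOD-TF and receptor pools are
#' conserved by construction (checked by [audit_conservation()]).
#' SMAD totals default to the ELISA concentrations
#' (SMAD2 0.060 nM, SMAD3 0.38 nM, SMAD4 0.0044 nM).
#'
#' @param parameters Named numeric overrides of rate parameters.
#' @param init Named numeric overrides of initial species values.
#' @param settle If `TRUE` (default), the unstimulated network is integrated
#'   to its resting state and that state is used as the initial condition, so
#'   a zero-dose simulation is flat.
#' @param settle_time Horizon (h) of the settling integration.
#' @return A `reaction_network` object.
#' @export
build_reduced_network <- function(parameters = NULL, init = NULL,
                                  settle = TRUE, settle_time = 2000) {
  species <- c(
    TGFb_lat = 0.05, TGFb_act = 0, TGFBR = 0.1, TGFBR_act = 0,
    SMAD2 = 0.060, pSMAD2 = 0, SMAD3 = 0.38, pSMAD3 = 0,
    SMAD4 = 0.0044, S234 = 0, SMAD7 = 0, AP1 = 0,
    THBS1 = 0, FMOD = 0, FMOD_TGFb = 0,
    VEGF = 0.05, VEGFR = 0.1, VEGFR_act = 0,
    Raf = 0.1, Raf_act = 0, MEK = 0.1, MEK_act = 0,
    ERK = 0.1, ERK_act = 0, FTF = 0.05, FTF_act = 0,
    PI3K = 0.1, PI3K_act = 0, Akt = 0.1, pAkt = 0)

  params <- c(
    k_lsyn = 0.01, k_ldeg = 0.1, k_actb = 2e-7, k_act = 0.5,
    k_on = 50, k_off = 0.2, k_s7i = 20, k_adeg = 1,
    k_seq = 2, k_seqr = 0.2,
    k_p2 = 30, k_dp2 = 1, k_p3 = 30, k_dp3 = 1,
    k13 = 2, K_t2 = 0.001, K_t3 = 0.01, k13r = 1,
    k_s7syn = 0.06, K_s7 = 0.001, k_s7deg = 0.3,
    k_ap1 = 0.5, K_ap1 = 0.01, k_ap1deg = 0.5,
    k_th = 0.3, K_gs = 0.002, K_ga = 0.3, k_thdeg = 0.05,
    k_von = 10, k_voff = 0.5,
    k_raf = 20, k_rafi = 1, k_mek = 20, k_meki = 1,
    k_erk = 20, k_erki = 1, k_ftf = 20, k_ftfi = 1,
    k_fm = 0.08, K_ftf = 0.005, K_akt = 0.005, n_akt = 2, k_fmdeg = 0.08,
    k_pi = 20, k_pii = 1, k_akt = 20, k_akti = 1)

  rxn <- function(name, k, stoich, factors = character(),
                  hill = list(), repress = list()) {
    list(name = name, k = k, stoich = stoich, factors = factors,
         hill = hill, repress = repress)
  }
  h <- function(species, K, n = 1) list(species = species, K = K, n = n)

  reactions <- list(
    rxn("lat_synth", "k_lsyn", c(TGFb_lat = 1)),
    rxn("lat_deg", "k_ldeg", c(TGFb_lat = -1), "TGFb_lat"),
    rxn("lat_act_basal", "k_actb", c(TGFb_lat = -1, TGFb_act = 1),
        "TGFb_lat"),
    rxn("lat_act_thbs1", "k_act", c(TGFb_lat = -1, TGFb_act = 1),
        c("TGFb_lat", "THBS1")),
    rxn("recep_bind", "k_on", c(TGFb_act = -1, TGFBR = -1, TGFBR_act = 1),
        c("TGFb_act", "TGFBR")),
    rxn("recep_unbind", "k_off", c(TGFBR_act = -1, TGFBR = 1, TGFb_act = 1),
        "TGFBR_act"),
    rxn("recep_inact_smad7", "k_s7i", c(TGFBR_act = -1, TGFBR = 1),
        c("TGFBR_act", "SMAD7")),
    rxn("act_deg", "k_adeg", c(TGFb_act = -1), "TGFb_act"),
    rxn("fmod_seq", "k_seq", c(TGFb_act = -1, FMOD = -1, FMOD_TGFb = 1),
        c("TGFb_act", "FMOD")),
    rxn("fmod_seq_rev", "k_seqr", c(FMOD_TGFb = -1, TGFb_act = 1, FMOD = 1),
        "FMOD_TGFb"),
    rxn("smad2_phos", "k_p2", c(SMAD2 = -1, pSMAD2 = 1),
        c("TGFBR_act", "SMAD2")),
    rxn("smad2_dephos", "k_dp2", c(pSMAD2 = -1, SMAD2 = 1), "pSMAD2"),
    rxn("smad3_phos", "k_p3", c(SMAD3 = -1, pSMAD3 = 1),
        c("TGFBR_act", "SMAD3")),
    rxn("smad3_dephos", "k_dp3", c(pSMAD3 = -1, SMAD3 = 1), "pSMAD3"),
    # trimer assembly: linear in the scarce SMAD4, saturating in the
    # phospho-SMADs (present in excess)
    rxn("trimer_form", "k13",
        c(pSMAD2 = -1, pSMAD3 = -1, SMAD4 = -1, S234 = 1), "SMAD4",
        hill = list(h("pSMAD2", "K_t2"), h("pSMAD3", "K_t3"))),
    rxn("trimer_diss", "k13r",
        c(S234 = -1, pSMAD2 = 1, pSMAD3 = 1, SMAD4 = 1), "S234"),
    rxn("smad7_synth", "k_s7syn", c(SMAD7 = 1),
        hill = list(h("S234", "K_s7"))),
    rxn("smad7_deg", "k_s7deg", c(SMAD7 = -1), "SMAD7"),
    rxn("ap1_synth", "k_ap1", c(AP1 = 1), hill = list(h("pSMAD3", "K_ap1"))),
    rxn("ap1_deg", "k_ap1deg", c(AP1 = -1), "AP1"),
    # AND gate: SMAD trimer and AP-1 are both required
    rxn("thbs1_synth", "k_th", c(THBS1 = 1),
        hill = list(h("S234", "K_gs"), h("AP1", "K_ga"))),
    rxn("thbs1_deg", "k_thdeg", c(THBS1 = -1), "THBS1"),
    rxn("vegfr_bind", "k_von", c(VEGF = -1, VEGFR = -1, VEGFR_act = 1),
        c("VEGF", "VEGFR")),
    rxn("vegfr_unbind", "k_voff", c(VEGFR_act = -1, VEGFR = 1, VEGF = 1),
        "VEGFR_act"),
    rxn("raf_act", "k_raf", c(Raf = -1, Raf_act = 1),
        c("VEGFR_act", "Raf")),
    rxn("raf_inact", "k_rafi", c(Raf_act = -1, Raf = 1), "Raf_act"),
    rxn("mek_act", "k_mek", c(MEK = -1, MEK_act = 1), c("Raf_act", "MEK")),
    rxn("mek_inact", "k_meki", c(MEK_act = -1, MEK = 1), "MEK_act"),
    rxn("erk_act", "k_erk", c(ERK = -1, ERK_act = 1), c("MEK_act", "ERK")),
    rxn("erk_inact", "k_erki", c(ERK_act = -1, ERK = 1), "ERK_act"),
    rxn("ftf_act", "k_ftf", c(FTF = -1, FTF_act = 1), c("ERK_act", "FTF")),
    rxn("ftf_inact", "k_ftfi", c(FTF_act = -1, FTF = 1), "FTF_act"),
    rxn("fmod_synth", "k_fm", c(FMOD = 1),
        hill = list(h("FTF_act", "K_ftf")),
        repress = list(h("pAkt", "K_akt", "n_akt"))),
    rxn("fmod_deg", "k_fmdeg", c(FMOD = -1), "FMOD"),
    rxn("pi3k_act", "k_pi", c(PI3K = -1, PI3K_act = 1),
        c("TGFBR_act", "PI3K")),
    rxn("pi3k_inact", "k_pii", c(PI3K_act = -1, PI3K = 1), "PI3K_act"),
    rxn("akt_phos", "k_akt", c(Akt = -1, pAkt = 1), c("PI3K_act", "Akt")),
    rxn("akt_dephos", "k_akti", c(pAkt = -1, Akt = 1), "pAkt"))

  conserved <- list(
    SMAD2 = c(SMAD2 = 1, pSMAD2 = 1, S234 = 1),
    SMAD3 = c(SMAD3 = 1, pSMAD3 = 1, S234 = 1),
    SMAD4 = c(SMAD4 = 1, S234 = 1),
    TGFBR = c(TGFBR = 1, TGFBR_act = 1),
    VEGFR = c(VEGFR = 1, VEGFR_act = 1),
    Raf = c(Raf = 1, Raf_act = 1),
    MEK = c(MEK = 1, MEK_act = 1),
    ERK = c(ERK = 1, ERK_act = 1),
    FTF = c(FTF = 1, FTF_act = 1),
    PI3K = c(PI3K = 1, PI3K_act = 1),
    Akt = c(Akt = 1, pAkt = 1))

  observables <- list(
    pSMAD3 = c(pSMAD3 = 1, S234 = 1),
    cFos = c(AP1 = 1),
    THBS1 = c(THBS1 = 1),
    pAkt = c(pAkt = 1),
    FMOD = c(FMOD = 1),
    pSMAD2 = c(pSMAD2 = 1, S234 = 1))

  if (!is.null(parameters)) {
    bad <- setdiff(names(parameters), names(params))
    if (length(bad)) stop("unknown parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    params[names(parameters)] <- parameters
  }
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(species))
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    species[names(init)] <- init
  }

  net <- new_reaction_network(species, params, reactions, conserved,
                              observables)
  if (settle) {
    net$species <- settle_network(net, settle_time)
  }
  net
}

#' Construct a reaction network from explicit components
#'
#' Lower-level constructor used by [build_reduced_network()]; also handy for
#' small test networks. Each reaction is a list with `name`, `k` (parameter
#' name), `stoich` (named numeric), `factors` (species entering the rate
#' linearly), and optional `hill` / `repress` term lists
#' (`list(species =, K =, n =)` with `K`, `n` naming parameters or `n = 1`).
#'
#' @param species Named numeric initial values.
#' @param parameters Named numeric rate parameters.
#' @param reactions List of reaction descriptors.
#' @param conserved Named list of conservation pools (named weight vectors).
#' @param observables Named list of observable weight vectors.
#' @return A `reaction_network`.
#' @export
reaction_network <- function(species, parameters, reactions,
                             conserved = list(), observables = list()) {
  new_reaction_network(species, parameters, reactions, conserved,
                       observables)
}

new_reaction_network <- function(species, params, reactions, conserved,
                                 observables) {
  net <- structure(list(species = species, parameters = params,
                        reactions = reactions, conserved = conserved,
                        observables = observables),
                   class = "reaction_network")
  audit_conservation(net)
  net$rates_fun <- compile_rates(net)
  net$stoich <- stoich_matrix(net)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions, %d parameters\n",
              length(x$species), length(x$reactions), length(x$parameters)))
  cat("  conserved pools:", paste(names(x$conserved), collapse = ", "), "\n")
  cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  invisible(x)
}

stoich_matrix <- function(net) {
  sp <- names(net$species)
  S <- matrix(0, length(sp), length(net$reactions),
              dimnames = list(sp, vapply(net$reactions, `[[`, "", "name")))
  for (j in seq_along(net$reactions)) {
    st <- net$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Audit the conservation laws of a reaction network
#'
#' Checks that every declared conserved pool is annihilated by the
#' stoichiometry of every reaction (left/right multiset balance).
#'
#' @param net A `reaction_network`.
#' @return `TRUE` invisibly; stops with the offending pool/reaction pair
#'   otherwise.
#' @export
audit_conservation <- function(net) {
  for (pool in names(net$conserved)) {
    w <- net$conserved[[pool]]
    bad <- setdiff(names(w), names(net$species))
    if (length(bad)) stop("pool '", pool, "' references unknown species ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (r in net$reactions) {
      st <- r$stoich
      common <- intersect(names(st), names(w))
      if (length(common) && abs(sum(w[common] * st[common])) > 1e-12)
        stop("reaction '", r$name, "' violates conservation of pool '",
             pool, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# generate a fast rate-evaluation function: rates_fun(y, p) -> numeric vector
compile_rates <- function(net) {
  sp <- names(net$species)
  pn <- names(net$parameters)
  si <- function(s) paste0("y[", match(s, sp), "]")
  pi <- function(s) paste0("p[", match(s, pn), "]")
  terms <- vapply(net$reactions, function(r) {
    e <- pi(r$k)
    for (f in r$factors) e <- paste0(e, " * ", si(f))
    for (hl in r$hill) {
      x <- si(hl$species); K <- pi(hl$K)
      n <- if (identical(hl$n, 1) || identical(hl$n, 1L)) NULL else pi(hl$n)
      e <- if (is.null(n))
        paste0(e, " * (", x, " / (", x, " + ", K, "))")
      else
        paste0(e, " * (", x, "^", n, " / (", x, "^", n, " + ", K, "^", n,
               "))")
    }
    for (hl in r$repress) {
      x <- si(hl$species); K <- pi(hl$K)
      n <- if (identical(hl$n, 1) || identical(hl$n, 1L)) NULL else pi(hl$n)
      e <- if (is.null(n))
        paste0(e, " * (", K, " / (", x, " + ", K, "))")
      else
        paste0(e, " * (", K, "^", n, " / (", x, "^", n, " + ", K, "^", n,
               "))")
    }
    e
  }, "")
  body <- paste0("function(y, p) c(", paste(terms, collapse = ",\n"), ")")
  eval(parse(text = body)[[1]])
}

settle_network <- function(net, settle_time = 2000) {
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(as.vector(net$stoich %*% net$rates_fun(y, net$parameters)))
  }
  out <- deSolve::ode(y = net$species, times = c(0, settle_time), func = rhs,
                      parms = NULL, rtol = 1e-8, atol = 1e-10)
  y <- pmax(out[nrow(out), -1], 0)
  stats::setNames(as.numeric(y), names(net$species))
}

#' Stimulus and intervention protocol
#'
#' @param tgfb1_dose Exogenous active TGF-beta-1 bolus added at `t = 0`, in
#'   multiples of the reference dose (1x = 0.16 nM, the 4 ng/mL assay dose).
#' @param vegf_dose VEGF level as a multiple of the resting VEGF pool.
#' @param washout_time Optional time (h) at which the extracellular active
#'   TGF-beta-1 is removed (set to zero), emulating a medium wash.
#' @param inhibitor_events List of `list(target = <reaction name>,
#'   time = <h>, fraction = <residual activity in [0,1]>)`; from `time` on,
#'   the target reaction's rate is scaled by `fraction`.
#' @param knockdowns List of `list(pool = <conserved pool name>,
#'   fraction = <remaining fraction in [0,1]>)`; scales the initial values of
#'   every species in the pool.
#' @param t_grid Observation times (h).
#' @return A `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(tgfb1_dose = 0, vegf_dose = 1,
                              washout_time = NULL, inhibitor_events = list(),
                              knockdowns = list(),
                              t_grid = seq(0, 48, by = 0.5)) {
  for (ev in inhibitor_events) {
    if (ev$time < 0) stop("inhibitor event time must be >= 0", call. = FALSE)
    if (ev$fraction < 0 || ev$fraction > 1)
      stop("inhibitor residual fraction must be in [0, 1]", call. = FALSE)
  }
  for (kd in knockdowns)
    if (kd$fraction < 0 || kd$fraction > 1)
      stop("knockdown fraction must be in [0, 1]", call. = FALSE)
  if (!is.null(washout_time) && washout_time < 0)
    stop("washout_time must be >= 0", call. = FALSE)
  structure(list(tgfb1_dose = tgfb1_dose, vegf_dose = vegf_dose,
                 washout_time = washout_time,
                 inhibitor_events = inhibitor_events,
                 knockdowns = knockdowns, t_grid = t_grid),
            class = "stimulus_protocol")
}

REFERENCE_TGFB1_BOLUS <- 0.16  # nM; 4 ng/mL at ~25 kDa

#' Simulate the pathway network under a protocol
#'
#' Applies the protocol (initial bolus, knockdown pool scaling, washout and
#' inhibitor events as integration breakpoints) and integrates the network
#' with `deSolve::ode` (lsoda) piecewise between events.
#'
#' @param network A `reaction_network`.
#' @param protocol A [stimulus_protocol()].
#' @param horizon Final time (h); must cover all event times.
#' @param rtol,atol Solver tolerances.
#' @return A `trajectory_set`: list with `times`, `species` (matrix), and
#'   `observables` (matrix of mapped, min-max normalized readouts; a readout
#'   that is constant over the horizon is left unnormalized and flagged in
#'   `constant_observables`).
#' @export
simulate_pathway <- function(network, protocol = stimulus_protocol(),
                             horizon = max(protocol$t_grid),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(protocol, "stimulus_protocol"))
  ev_times <- c(vapply(protocol$inhibitor_events, `[[`, 0, "time"),
                protocol$washout_time)
  if (length(ev_times) && max(unlist(ev_times)) > horizon)
    stop("horizon does not cover all protocol event times", call. = FALSE)
  y <- network$species
  # knockdowns scale the initial pools (siRNA pretreatment convention)
  for (kd in protocol$knockdowns) {
    if (!kd$pool %in% names(network$conserved))
      stop("unknown knockdown pool '", kd$pool, "'", call. = FALSE)
    members <- names(network$conserved[[kd$pool]])
    y[members] <- y[members] * kd$fraction
  }
  if ("VEGF" %in% names(y)) y["VEGF"] <- y["VEGF"] * protocol$vegf_dose
  if ("TGFb_act" %in% names(y))
    y["TGFb_act"] <- y["TGFb_act"] +
      protocol$tgfb1_dose * REFERENCE_TGFB1_BOLUS

  t_grid <- sort(unique(c(protocol$t_grid, 0, horizon)))
  t_grid <- t_grid[t_grid <= horizon]
  breaks <- sort(unique(c(0, unlist(ev_times), horizon)))
  rx_names <- vapply(network$reactions, `[[`, "", "name")
  mult <- rep(1, length(rx_names))
  out_t <- numeric(0)
  out_y <- NULL
  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    # apply events scheduled at t0
    if (!is.null(protocol$washout_time) &&
        isTRUE(all.equal(t0, protocol$washout_time)) &&
        "TGFb_act" %in% names(y))
      y["TGFb_act"] <- 0
    for (ev in protocol$inhibitor_events) {
      if (isTRUE(all.equal(t0, ev$time))) {
        j <- match(ev$target, rx_names)
        if (is.na(j)) stop("unknown inhibitor target reaction '",
                           ev$target, "'", call. = FALSE)
        mult[j] <- mult[j] * ev$fraction
      }
    }
    seg_t <- sort(unique(c(t0, t_grid[t_grid >= t0 & t_grid <= t1], t1)))
    m <- mult
    rhs <- function(t, yy, parms) {
      yy <- pmax(yy, 0)
      list(as.vector(network$stoich %*%
                       (m * network$rates_fun(yy, network$parameters))))
    }
    seg <- deSolve::ode(y = y, times = seg_t, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
    if (attr(seg, "istate")[1] < 0)
      stop(sprintf("solver failure on interval [%g, %g]", t0, t1),
           call. = FALSE)
    y <- pmax(seg[nrow(seg), -1], 0)
    keep <- seg[, 1] %in% t_grid
    out_t <- c(out_t, seg[keep, 1])
    out_y <- rbind(out_y, seg[keep, -1, drop = FALSE])
  }
  # at an event time report the post-event state (input drops are visible at
  # the event time itself)
  last <- !duplicated(out_t, fromLast = TRUE)
  species <- out_y[last, , drop = FALSE][order(out_t[last]), , drop = FALSE]
  out_t <- sort(out_t[last])
  colnames(species) <- names(network$species)
  obs_raw <- vapply(network$observables, function(w)
    as.vector(species[, names(w), drop = FALSE] %*% w),
    numeric(length(out_t)))
  if (length(out_t) == 1) obs_raw <- matrix(obs_raw, nrow = 1,
                                            dimnames = list(NULL,
                                              names(network$observables)))
  const <- apply(obs_raw, 2, function(v) diff(range(v)) < 1e-12)
  obs <- obs_raw
  for (j in which(!const)) obs[, j] <- normalize_minmax(obs_raw[, j])
  structure(list(times = out_t, species = species, observables = obs,
                 observables_raw = obs_raw,
                 constant_observables = names(which(const)),
                 protocol = protocol),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d time points over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  cat("  observables:", paste(colnames(x$observables), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a trajectory set as TSV
#'
#' Columns: `time`, all species, then normalized observables (prefixed
#' `obs_`).
#'
#' @param x A `trajectory_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(x, path) {
  stopifnot(inherits(x, "trajectory_set"))
  df <- data.frame(time = x$times, x$species,
                   stats::setNames(as.data.frame(x$observables),
                                   paste0("obs_", colnames(x$observables))))
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) format_num(col) else col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; affine-invariant, attains both 0 and 1.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Normalized vector.
#' @export
normalize_minmax <- function(x) {
  r <- range(x)
  if (diff(r) == 0)
    stop("degenerate normalization: series is constant", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Time-integral signaling metric
#'
#' Trapezoidal integral of one species (or observable) trajectory over the
#' simulated horizon — the metric used to rank reaction sensitivities
#' (default target species THBS1).
#'
#' @param traj A `trajectory_set`.
#' @param species Species or observable name.
#' @param normalized If `TRUE` integrate the normalized observable, else the
#'   raw species trajectory (default).
#' @return Scalar integral.
#' @export
integral_metric <- function(traj, species = "THBS1", normalized = FALSE) {
  stopifnot(inherits(traj, "trajectory_set"))
  t <- traj$times
  if (length(t) < 2) stop("need at least two time points", call. = FALSE)
  y <- if (species %in% colnames(traj$species) && !normalized)
    traj$species[, species]
  else if (species %in% colnames(traj$observables))
    (if (normalized) traj$observables else traj$observables_raw)[, species]
  else stop("unknown species/observable '", species, "'", call. = FALSE)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Finite-difference sensitivity analysis
#'
#' Log-log sensitivity coefficients `S_y = d ln M / d ln y_j` of the
#' integral metric `M` (default: the THBS1 time integral under TGF-beta-1
#' stimulation) with respect to each reaction rate constant (`target =
#' "reaction"`) or each nonzero initial species value (`target = "species"`),
#' by forward finite differences with a 1% perturbation.
#'
#' @param network A `reaction_network`.
#' @param protocol Stimulation protocol (default: 1x TGF-beta-1 dose).
#' @param metric_species Species whose time integral is the metric.
#' @param perturbation Relative perturbation (default 0.01).
#' @param target `"reaction"` or `"species"`.
#' @param horizon Simulation horizon (h).
#' @return A `sensitivity_matrix`: data frame with columns `target` and
#'   `coefficient`, ordered as in the network; attributes record the metric
#'   and perturbation.
#' @export
sensitivity_analysis <- function(network,
                                 protocol = stimulus_protocol(tgfb1_dose = 1),
                                 metric_species = "THBS1",
                                 perturbation = 0.01,
                                 target = c("reaction", "species"),
                                 horizon = 48) {
  target <- match.arg(target)
  base_traj <- simulate_pathway(network, protocol, horizon = horizon)
  M0 <- integral_metric(base_traj, metric_species)
  if (M0 <= 0)
    stop("baseline metric is zero; sensitivity coefficients undefined",
         call. = FALSE)
  if (target == "reaction") {
    names_out <- vapply(network$reactions, `[[`, "", "name")
    coefs <- vapply(seq_along(network$reactions), function(j) {
      net2 <- network
      kname <- network$reactions[[j]]$k
      net2$parameters[kname] <- net2$parameters[kname] * (1 + perturbation)
      # recompiled indices unchanged; rates_fun reads parameters at call time
      M1 <- integral_metric(
        simulate_pathway(net2, protocol, horizon = horizon), metric_species)
      (log(M1) - log(M0)) / log(1 + perturbation)
    }, 0)
  } else {
    nz <- names(network$species)[network$species > 0]
    names_out <- nz
    coefs <- vapply(nz, function(s) {
      net2 <- network
      net2$species[s] <- net2$species[s] * (1 + perturbation)
      M1 <- integral_metric(
        simulate_pathway(net2, protocol, horizon = horizon), metric_species)
      (log(M1) - log(M0)) / log(1 + perturbation)
    }, 0)
  }
  structure(data.frame(target = names_out, coefficient = coefs,
                       row.names = NULL),
            class = c("sensitivity_matrix", "data.frame"),
            metric = metric_species, perturbation = perturbation,
            mode = target)
}

#' Estimate pathway parameters by differential evolution
#'
#' Minimizes the sum of squared differences between the network's normalized
#' observables and replicated training observations using the rand/1/bin
#' differential-evolution scheme with greedy selection (the per-generation
#' best objective is therefore non-increasing). `n_runs` independent seeded
#' runs are performed (seeds `seed + 1 .. seed + n_runs`), mirroring the
#' multi-start calibration practice of signaling models.
#'
#' @param network A `reaction_network` whose parameters are the fixed
#'   baseline.
#' @param training A `timecourse_data` object (see [gen_timecourse()]): list
#'   with `times`, `obs` (list of time-by-replicate matrices named by
#'   observable) and `protocol`.
#' @param free Character vector of free parameter names.
#' @param lower,upper Named bounds for every free parameter (required).
#' @param n_runs Number of independent DE runs.
#' @param de_options List: `np` (population size; default `10 * dimension`),
#'   `F` (differential weight, 0.8), `CR` (crossover, 0.9), `generations`
#'   (default 100).
#' @param seed Base seed.
#' @return A `de_fit` object: list of runs, each with `par`, `objective`,
#'   `trace` (best objective per generation), `seed`; plus `best` (index of
#'   the best run).
#' @export
estimate_parameters <- function(network, training, free, lower, upper,
                                n_runs = 30, de_options = list(), seed = 1) {
  stopifnot(inherits(network, "reaction_network"))
  if (!all(free %in% names(network$parameters)))
    stop("free parameters must name network parameters", call. = FALSE)
  if (!all(free %in% names(lower)) || !all(free %in% names(upper)))
    stop("bounds are required for every free parameter", call. = FALSE)
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)
  d <- length(free)
  opts <- utils::modifyList(list(np = 10 * d, F = 0.8, CR = 0.9,
                                 generations = 100), de_options)
  objective <- function(theta) {
    net2 <- network
    net2$parameters[free] <- theta
    tr <- try(simulate_pathway(net2, training$protocol,
                               horizon = max(training$times),
                               rtol = 1e-6, atol = 1e-8), silent = TRUE)
    if (inherits(tr, "try-error")) return(1e10)
    sse <- 0
    idx <- match(training$times, tr$times)
    for (ob in names(training$obs)) {
      sim <- tr$observables[idx, ob]
      sse <- sse + sum((training$obs[[ob]] - sim)^2)
    }
    if (!is.finite(sse)) 1e10 else sse
  }
  runs <- lapply(seq_len(n_runs), function(r) {
    de_rand1bin(objective, lower, upper, np = opts$np, Fw = opts$F,
                CR = opts$CR, generations = opts$generations,
                seed = seed + r)
  })
  best <- which.min(vapply(runs, `[[`, 0, "objective"))
  structure(list(runs = runs, best = best, free = free), class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  objs <- vapply(x$runs, `[[`, 0, "objective")
  cat(sprintf("Differential-evolution fit: %d run(s), objective %.4g - %.4g\n",
              length(objs), min(objs), max(objs)))
  cat("  best run:", x$best, "\n")
  invisible(x)
}

# rand/1/bin differential evolution with greedy (elitist) selection
de_rand1bin <- function(fn, lower, upper, np, Fw, CR, generations, seed) {
  set.seed(seed)
  d <- length(lower)
  pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  trace <- numeric(generations)
  for (g in seq_len(generations)) {
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3)
      v <- pop[idx[1], ] + Fw * (pop[idx[2], ] - pop[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      jr <- sample.int(d, 1)
      cross <- stats::runif(d) < CR
      cross[jr] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      cu <- fn(u)
      if (cu <= cost[i]) { pop[i, ] <- u; cost[i] <- cu }
    }
    trace[g] <- min(cost)
  }
  b <- which.min(cost)
  list(par = stats::setNames(pop[b, ], names(lower)), objective = cost[b],
       trace = trace, seed = seed)
}

#' Serialize a reaction network to YAML
#'
#' Writes species, parameters, rate-law descriptors and conserved pools;
#' [read_network_yaml()] reconstructs an identical network (identical
#' trajectories).
#'
#' @param net A `reaction_network`.
#' @param path YAML file path.
#' @return `path` / the network, invisibly.
#' @export
write_network_yaml <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  x <- list(
    species = as.list(net$species),
    parameters = as.list(net$parameters),
    reactions = lapply(net$reactions, function(r)
      list(name = r$name, k = r$k, stoich = as.list(r$stoich),
           factors = as.list(r$factors),
           hill = r$hill, repress = r$repress)),
    conserved = lapply(net$conserved, as.list),
    observables = lapply(net$observables, as.list))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  unl <- function(l) stats::setNames(as.numeric(unlist(l)), names(l))
  reactions <- lapply(x$reactions, function(r)
    list(name = r$name, k = r$k, stoich = unl(r$stoich),
         factors = as.character(unlist(r$factors)),
         hill = lapply(r$hill, function(h)
           list(species = h$species, K = h$K, n = h$n)),
         repress = lapply(r$repress, function(h)
           list(species = h$species, K = h$K, n = h$n))))
  new_reaction_network(unl(x$species), unl(x$parameters), reactions,
                       lapply(x$conserved, unl), lapply(x$observables, unl))
}

#' Write differential-evolution results as JSON lines
#'
#' One JSON object per run: `seed`, `objective`, `parameters`.
#'
#' @param x A `de_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_de_jsonl <- function(x, path) {
  stopifnot(inherits(x, "de_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in x$runs) {
    writeLines(jsonlite::toJSON(
      list(seed = r$seed, objective = r$objective,
           parameters = as.list(r$par)),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
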