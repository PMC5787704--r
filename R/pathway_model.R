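#' @useDynLib smadtier
#' @importFrom Rcpp sourceCpp
NULL

# species order must match src/pathway_rhs.c
.species <- c("L", "Rs", "Re", "Cs", "Ce", "S2c", "S2n", "pS2c", "pS2n",
              "S4c", "S4n", "Gc", "Gn", "Fm", "Fp")

.ode_par_names <- c("ka", "ki_R", "krec_R", "pr", "kdeg_R", "ki_C", "kdeg_C",
                    "kphos", "kon", "koff", "kin_s2", "kex_s2", "kin_ps2",
                    "kex_ps2", "kin_s4", "kex_s4", "kin_g", "kex_g",
                    "kdephos", "ktx_b", "ktx", "kdeg_m", "ktl", "kdeg_p",
                    "kfb", "rho", "fb_scale")

.pool_par_names <- c("S2_tot", "S4_tot")

.obs_par_names <- c("obs_scale_s2", "obs_offset_s2",
                    "obs_scale_s4", "obs_offset_s4")

#' Construct a validated pathway parameter set
#'
#' Kinetic rates use minutes; the extracellular ligand is in pM; intracellular
#' species are in arbitrary concentration units that the observation scale and
#' offset map onto the measured nuclear-to-cytoplasmic (nuc/cyt) SMAD ratios.
#' The nuclear/cytoplasmic volume ratio is absorbed into the import/export
#' rates. `rho` is the dimensionless cells-to-medium scaling coupling cellular
#' ligand uptake to depletion of the medium; `fb_scale` multiplies both basal
#' and induced feedback transcription (1 = wild type).
#'
#' @param x named numeric vector covering all kinetic, pool and observation
#'   parameters (see [default_parameters()] for the full name set).
#' @return object of class `pathway_parameters` (a named numeric vector).
#' @export
pathway_parameters <- function(x) {
  needed <- c(.ode_par_names, .pool_par_names, .obs_par_names)
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  x <- x[needed]
  if (any(!is.finite(x))) stop("non-finite parameter values")
  if (any(x[c(.ode_par_names, .pool_par_names)] < 0))
    stop("rates and pools must be >= 0")
  if (x["obs_scale_s2"] <= 0 || x["obs_scale_s4"] <= 0)
    stop("observation scale must be > 0")
  structure(x, class = "pathway_parameters")
}

#' Default pathway parameter set
#'
#' A reference parameterization of the receptor/SMAD/feedback model chosen to
#' reproduce the hallmark population-average dynamics of TGF-beta/SMAD
#' signaling in MCF10A-like epithelial cells: a dominant first nuc/cyt SMAD2
#' peak near 60 min followed by adaptation to a dose-dependent plateau;
#' cell-mediated medium depletion of a 25 pM TGF-beta stimulus completed
#' (<= 5% remaining) within 20 h and of 5 pM within about 10 h; early
#' refractoriness to restimulation at 5 pM that resolves by 8 h; no added
#' response to replenishing a 100 pM stimulus; and increased peak and late
#' amplitudes when transcription of the negative feedback is blocked.
#'
#' @return a [pathway_parameters()] object.
#' @export
default_parameters <- function() {
  pathway_parameters(c(
    ka       = 1.2e-3,  # pM^-1 min^-1
    ki_R     = 0.0333,
    krec_R   = 0.03,
    pr       = 0.0075,
    kdeg_R   = 0.003,
    ki_C     = 0.2,
    kdeg_C   = 0.005,
    kphos    = 0.03,
    kon      = 1.0,
    koff     = 0.016,
    kin_s2   = 0.006,
    kex_s2   = 0.008,
    kin_ps2  = 0.03,
    kex_ps2  = 0.003,
    kin_s4   = 0.005,
    kex_s4   = 0.005,
    kin_g    = 0.05,
    kex_g    = 0.001,
    kdephos  = 0.1,
    ktx_b    = 0.001,
    ktx      = 0.08,
    kdeg_m   = 0.04,
    ktl      = 0.06,
    kdeg_p   = 0.008,
    kfb      = 15.0,
    rho      = 4.4,
    fb_scale = 1.0,
    S2_tot   = 1.2,
    S4_tot   = 1.0,
    obs_scale_s2  = 1.0,
    obs_offset_s2 = 0.0,
    obs_scale_s4  = 1.0,
    obs_offset_s4 = 0.0
  ))
}

#' Define a stimulus protocol
#'
#' Events are applied at their stated times during simulation:
#' `ligand_set` REPLACES the extracellular ligand concentration with `dose`
#' (replenishment semantics, as when medium TGF-beta is restored to its
#' initial concentration); `receptor_inhibit` zeroes the SMAD2
#' phosphorylation flux from that time onward (SB431542 analog);
#' `transcription_inhibit` zeroes feedback transcription (DRB analog).
#'
#' @param horizon_min simulation horizon in minutes.
#' @param events data.frame with columns `time` (min), `kind`
#'   (`"ligand_set"`, `"receptor_inhibit"`, `"transcription_inhibit"`) and
#'   `dose` (pM; only used for `ligand_set`).
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(horizon_min, events = NULL) {
  if (is.null(events))
    events <- data.frame(time = numeric(0), kind = character(0),
                         dose = numeric(0))
  stopifnot(is.data.frame(events),
            all(c("time", "kind") %in% names(events)))
  if (!"dose" %in% names(events)) events$dose <- NA_real_
  kinds <- c("ligand_set", "receptor_inhibit", "transcription_inhibit")
  if (!all(events$kind %in% kinds))
    stop("unknown event kind; must be one of ",
         paste(kinds, collapse = ", "))
  if (nrow(events) > 0) {
    if (any(diff(events$time) <= 0))
      stop("event times must be strictly ascending")
    if (any(events$time < 0) || any(events$time > horizon_min))
      stop("event times must lie within [0, horizon]")
    lig <- events$kind == "ligand_set"
    if (any(lig & (is.na(events$dose) | events$dose < 0)))
      stop("ligand_set events need dose >= 0")
  }
  structure(list(horizon_min = horizon_min, events = events),
            class = "stimulus_protocol")
}

#' Single-step stimulus protocol
#' @param dose_pM ligand dose applied at t = 0 (pM).
#' @param horizon_min horizon (min), default 24 h.
#' @export
step_protocol <- function(dose_pM, horizon_min = 1440) {
  ev <- if (dose_pM > 0)
    data.frame(time = 0, kind = "ligand_set", dose = dose_pM)
  else NULL
  stimulus_protocol(horizon_min, ev)
}

#' Restimulation protocol (ligand replenished at a later time)
#' @param dose_pM dose applied at t = 0 and again at `restim_min`.
#' @param restim_min time of the second stimulus (min).
#' @param horizon_min horizon (min).
#' @export
restim_protocol <- function(dose_pM, restim_min, horizon_min = 1440) {
  if (restim_min <= 0)
    return(step_protocol(dose_pM, horizon_min))
  stimulus_protocol(horizon_min, data.frame(
    time = c(0, restim_min), kind = "ligand_set",
    dose = c(dose_pM, dose_pM)))
}

# pre-stimulus steady state: integrate 48 h with zero ligand from nominal
# pools (robust to parameter pathologies, unlike an algebraic solve)
.steady_state <- function(params) {
  y0 <- stats::setNames(numeric(length(.species)), .species)
  re_frac <- params[["ki_R"]] /
    (params[["krec_R"]] + params[["kdeg_R"]] + 1e-12)
  rs0 <- params[["pr"]] /
    (params[["kdeg_R"]] * (1 + re_frac) + 1e-12)
  y0["Rs"] <- rs0
  y0["Re"] <- rs0 * re_frac
  y0["S2c"] <- params[["S2_tot"]]
  y0["S4c"] <- params[["S4_tot"]]
  y0["Fm"] <- params[["fb_scale"]] * params[["ktx_b"]] /
    (params[["kdeg_m"]] + 1e-12)
  y0["Fp"] <- params[["ktl"]] * y0["Fm"] / (params[["kdeg_p"]] + 1e-12)
  out <- .integrate_segment(y0, c(0, 1440, 2880), params,
                            sb = 0, drb = 0)
  stats::setNames(as.numeric(out[nrow(out), .species]), .species)
}

.integrate_segment <- function(y0, times, params, sb, drb,
                               control = list()) {
  p <- c(as.numeric(params[.ode_par_names]), sb, drb)
  out <- deSolve::lsoda(y = y0, times = times, func = "pathway_derivs",
                        parms = p, dllname = "smadtier",
                        initfunc = "pathway_init",
                        rtol = control$rtol %||% 1e-8,
                        atol = control$atol %||% 1e-10,
                        hmax = control$hmax %||% Inf, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         ") for segment starting at t = ", times[1])
  colnames(out) <- c("time", .species)
  out
}

#' Simulate the pathway model under a stimulus protocol
#'
#' The system is initialized at its pre-stimulus steady state (zero ligand),
#' so the baseline observable is flat. Integration is restarted at every
#' protocol event.
#'
#' @param params a [pathway_parameters()] object.
#' @param protocol a [stimulus_protocol()].
#' @param times output time grid (min) within the protocol horizon; default
#'   5-min frames over the horizon.
#' @param control optional integrator settings: list with any of `rtol`
#'   (default 1e-8), `atol` (1e-10), `hmax` (maximum step size, min).
#' @return object of class `pathway_simulation`: list with `time`, `species`
#'   (matrix, one column per species), `observables` (matrix with columns
#'   `ratio_s2`, `ratio_s4`, `receptor_fc`, `fb_mrna_fc`), `params`,
#'   `protocol`.
#' @export
simulate_pathway <- function(params, protocol, times = NULL,
                             control = list()) {
  stopifnot(inherits(params, "pathway_parameters"),
            inherits(protocol, "stimulus_protocol"))
  if (is.null(times))
    times <- seq(0, protocol$horizon_min, by = 5)
  if (min(times) < 0 || max(times) > protocol$horizon_min)
    stop("output grid must lie within the protocol horizon")
  times <- sort(unique(times))

  y <- .steady_state(params)
  ev <- protocol$events
  breaks <- sort(unique(c(0, ev$time, protocol$horizon_min)))
  sb <- 0; drb <- 0
  rows <- vector("list", length(breaks))
  t_prev <- 0
  # apply any event at t = 0 before the first segment
  for (seg in seq_along(breaks)) {
    t_here <- breaks[seg]
    hit <- which(ev$time == t_here)
    for (h in hit) {
      kind <- ev$kind[h]
      if (kind == "ligand_set") y["L"] <- ev$dose[h]
      else if (kind == "receptor_inhibit") sb <- 1
      else if (kind == "transcription_inhibit") drb <- 1
    }
    t_next <- if (seg < length(breaks)) breaks[seg + 1] else NA
    grid <- times[times >= t_here & (is.na(t_next) | times <= t_next)]
    if (is.na(t_next)) { # final point; record state at horizon if requested
      if (length(grid) > 0 && !(length(grid) == 1 && grid == t_prev)) {
        seg_times <- unique(c(t_here, grid))
        out <- .integrate_segment(y, seg_times, params, sb, drb, control)
        rows[[seg]] <- out[out[, "time"] %in% grid, , drop = FALSE]
      } else if (length(grid) == 1) {
        rows[[seg]] <- matrix(c(t_here, y), nrow = 1,
                              dimnames = list(NULL, c("time", .species)))
      }
      break
    }
    seg_times <- unique(c(t_here, grid, t_next))
    out <- .integrate_segment(y, seg_times, params, sb, drb, control)
    keep <- out[, "time"] %in% grid & out[, "time"] < t_next
    rows[[seg]] <- out[keep, , drop = FALSE]
    y <- stats::setNames(as.numeric(out[nrow(out), .species]), .species)
    t_prev <- t_next
  }
  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(tab[, "time"]), , drop = FALSE]
  tab <- tab[order(tab[, "time"]), , drop = FALSE]
  sp <- tab[, .species, drop = FALSE]

  if (min(sp) < -1e-6)
    stop("negative concentration beyond tolerance (min = ", min(sp), ")")
  sp[sp < 0] <- 0

  nuc2 <- sp[, "S2n"] + sp[, "pS2n"] + sp[, "Gn"]
  cyt2 <- sp[, "S2c"] + sp[, "pS2c"] + sp[, "Gc"]
  nuc4 <- sp[, "S4n"] + sp[, "Gn"]
  cyt4 <- sp[, "S4c"] + sp[, "Gc"]
  rec  <- sp[, "Rs"] + sp[, "Re"] + sp[, "Cs"] + sp[, "Ce"]
  obs <- cbind(
    ratio_s2 = params[["obs_scale_s2"]] * nuc2 / cyt2 +
      params[["obs_offset_s2"]],
    ratio_s4 = params[["obs_scale_s4"]] * nuc4 / cyt4 +
      params[["obs_offset_s4"]],
    receptor_fc = rec / rec[1],
    fb_mrna_fc = sp[, "Fm"] / max(sp[1, "Fm"], 1e-300)
  )
  structure(list(time = tab[, "time"], species = sp, observables = obs,
                 params = params, protocol = protocol),
            class = "pathway_simulation")
}

#' Total SMAD pools over time (conservation check helper)
#' @param sim a `pathway_simulation`.
#' @return matrix with columns `S2_total`, `S4_total`.
#' @export
smad_totals <- function(sim) {
  sp <- sim$species
  cbind(
    S2_total = sp[, "S2c"] + sp[, "S2n"] + sp[, "pS2c"] + sp[, "pS2n"] +
      sp[, "Gc"] + sp[, "Gn"],
    S4_total = sp[, "S4c"] + sp[, "S4n"] + sp[, "Gc"] + sp[, "Gn"]
  )
}

#' Time until the medium ligand falls below a fraction of its initial value
#'
#' @param sim a `pathway_simulation` whose protocol contains at least one
#'   `ligand_set` event with positive dose.
#' @param fraction threshold fraction of the post-stimulus ligand
#'   concentration, in (0, 1).
#' @return earliest time (min) with ligand <= fraction x initial dose, linearly
#'   interpolated between frames; `Inf` if never reached within the horizon.
#' @export
ligand_depletion_time <- function(sim, fraction = 0.05) {
  stopifnot(inherits(sim, "pathway_simulation"),
            fraction > 0, fraction < 1)
  ev <- sim$protocol$events
  lig <- ev[ev$kind == "ligand_set" & ev$dose > 0, , drop = FALSE]
  if (nrow(lig) == 0)
    stop("protocol contains no ligand event")
  t0 <- lig$time[1]
  l0 <- lig$dose[1]
  thr <- fraction * l0
  idx <- which(sim$time >= t0)
  tt <- sim$time[idx]
  ll <- sim$species[idx, "L"]
  below <- which(ll <= thr)
  if (length(below) == 0) return(Inf)
  k <- below[1]
  if (k == 1) return(tt[1])
  # linear interpolation between the bracketing frames
  t1 <- tt[k - 1]; t2 <- tt[k]; l1 <- ll[k - 1]; l2 <- ll[k]
  if (l1 == l2) return(t2)
  t1 + (l1 - thr) / (l1 - l2) * (t2 - t1)
}

#' Added response to ligand replenishment (refractoriness probe)
#'
#' Simulates a single-stimulus protocol and a restimulated protocol in which
#' the medium ligand is replenished to `dose` at `restim_min`, and returns the
#' added area under the nuc/cyt SMAD2 curve of the restimulated relative to
#' the single-stimulus simulation over the post-restimulation window.
#'
#' @param params a [pathway_parameters()] object.
#' @param dose stimulus dose (pM).
#' @param restim_min time of ligand replenishment (min).
#' @param horizon_min simulation horizon (min).
#' @return added response (trapezoid-integrated ratio difference,
#'   dimensionless x min).
#' @export
refractory_response <- function(params, dose, restim_min,
                                horizon_min = 1440) {
  stopifnot(restim_min >= 0, restim_min <= horizon_min)
  times <- seq(0, horizon_min, by = 5)
  base <- simulate_pathway(params, step_protocol(dose, horizon_min), times)
  rest <- simulate_pathway(params,
                           restim_protocol(dose, restim_min, horizon_min),
                           times)
  post <- times >= restim_min
  d <- rest$observables[post, "ratio_s2"] - base$observables[post, "ratio_s2"]
  tt <- times[post]
  sum(diff(tt) * (d[-1] + d[-length(d)]) / 2)
}

#' Write / read a parameter table (flat two-column TSV)
#'
#' Round-trips exactly at 17 significant digits.
#' @param params a [pathway_parameters()] object.
#' @param path file path.
#' @export
write_parameters <- function(params, path) {
  df <- data.frame(name = names(params),
                   value = sprintf("%.17g", as.numeric(params)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character"))
  pathway_parameters(stats::setNames(as.numeric(df$value), df$name))
}

#' Write / read a stimulus protocol as a YAML config
#' @param protocol a [stimulus_protocol()].
#' @param path file path.
#' @export
write_protocol <- function(protocol, path) {
  ev <- protocol$events
  events <- lapply(seq_len(nrow(ev)), function(i) {
    e <- list(time = ev$time[i], kind = ev$kind[i])
    if (!is.na(ev$dose[i])) e$dose <- ev$dose[i]
    e
  })
  yaml::write_yaml(list(horizon_min = protocol$horizon_min,
                        events = events), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  ev <- do.call(rbind, lapply(cfg$events, function(e)
    data.frame(time = e$time, kind = e$kind,
               dose = if (is.null(e$dose)) NA_real_ else e$dose)))
  stimulus_protocol(cfg$horizon_min, ev)
}
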