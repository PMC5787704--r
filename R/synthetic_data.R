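#' Configuration for the synthetic trajectory generator
#'
#' Describes an artificial live-cell imaging experiment: cells stimulated
#' with one of several TGF-beta doses respond according to one of six latent
#' signaling classes, with log-normally varying protein levels, slow
#' per-cell drift, multiplicative measurement noise, Poisson-placed cell
#' divisions and spatial positions.
#'
#' @param n_cells total number of cells (split evenly across doses).
#' @param doses_pM stimulus doses; each cell carries one dose label.
#' @param proportions per-dose class proportions: a list (one numeric
#'   vector per dose, each summing to 1) or NULL to use
#'   [default_class_proportions()].
#' @param mode `"ode"` (trajectories from the pathway model via
#'   [default_subpopulations()]) or `"phenomenological"` (parametric
#'   pulse-plus-plateau curves; fast, independent of the ODE machinery).
#' @param noise a [noise_spec()] for protein-pool variation.
#' @param meas_sd multiplicative log-normal measurement noise per frame
#'   (log-space sd).
#' @param drift_sd,drift_tau per-cell smooth log-scale drift
#'   (Ornstein-Uhlenbeck sd and correlation time in min); emulates slow
#'   cell-state fluctuations and drives gradual sister-cell divergence.
#' @param frame_min frame interval (min), default 5.
#' @param horizon_min track length (min), default 1440 (24 h).
#' @param division_rate expected divisions per cell per day.
#' @param lineage if TRUE, each dividing cell gains a sister track sharing
#'   its class, pool multipliers and drift history up to the division time.
#' @param field_px width/height of the imaging field (pixels).
#' @param spatial `"uniform"` or `"clustered"` (Thomas-style parent-
#'   offspring point process).
#' @param seed integer seed governing all sampling streams.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 600,
                             doses_pM = c(1, 2.5, 5, 25, 100),
                             proportions = NULL,
                             mode = c("phenomenological", "ode"),
                             noise = noise_spec(0.15, 0.25),
                             meas_sd = 0.15,
                             drift_sd = 0.10, drift_tau = 240,
                             frame_min = 5, horizon_min = 1440,
                             division_rate = 0.7, lineage = FALSE,
                             field_px = c(1344, 1024),
                             spatial = c("uniform", "clustered"),
                             seed = 1L) {
  mode <- match.arg(mode)
  spatial <- match.arg(spatial)
  if (is.null(proportions))
    proportions <- lapply(doses_pM, default_class_proportions)
  stopifnot(length(proportions) == length(doses_pM))
  for (p in proportions) {
    if (abs(sum(p) - 1) > 1e-8) stop("class proportions must sum to 1")
    if (any(p < 0)) stop("class proportions must be >= 0")
  }
  stopifnot(n_cells >= 1, meas_sd >= 0, division_rate >= 0,
            frame_min > 0, horizon_min >= 300)
  structure(list(n_cells = n_cells, doses_pM = doses_pM,
                 proportions = proportions, mode = mode, noise = noise,
                 meas_sd = meas_sd, drift_sd = drift_sd,
                 drift_tau = drift_tau, frame_min = frame_min,
                 horizon_min = horizon_min,
                 division_rate = division_rate, lineage = lineage,
                 field_px = field_px, spatial = spatial,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# class-specific phenomenological curve: baseline + first pulse + plateau
# ramp; classes ordered so that E and the late plateau increase with class
.phenom_table <- function() {
  data.frame(
    class = 1:6,
    b = 0.75,
    Ep = c(0.15, 0.50, 0.90, 1.30, 1.70, 2.20),
    tau_p = c(70, 65, 60, 60, 55, 55),
    plateau = c(0.04, 0.10, 0.18, 0.45, 0.65, 0.95),
    tau_L = 75)
}

.phenom_curve <- function(time, class_id, amp_mult, plateau_mult) {
  p <- .phenom_table()[class_id, ]
  pulse <- p$Ep * amp_mult * (time / p$tau_p) * exp(1 - time / p$tau_p)
  ramp <- p$plateau * plateau_mult * (1 - exp(-time / p$tau_L))
  p$b + pulse + ramp
}

# discrete Ornstein-Uhlenbeck sample path (stationary start optional)
.ou_path <- function(n, dt, sd, tau, start = NULL) {
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- if (is.null(start)) stats::rnorm(1, 0, sd) else start
  for (i in seq_len(n - 1))
    x[i + 1] <- a * x[i] + stats::rnorm(1, 0, innov_sd)
  x
}

#' Generate a synthetic single-cell trajectory population
#'
#' Per cell: a latent signaling class is drawn from the dose-specific
#' proportions; the noise-free trajectory comes from the class's
#' subpopulation model (ode mode) or its phenomenological curve; protein
#' pool multipliers are sampled via [sample_pools()]; a slow per-cell
#' log-scale drift and iid multiplicative measurement noise are applied;
#' divisions follow a Poisson process; positions are simulated in the
#' imaging field. In lineage mode, dividing cells gain a sister track that
#' is identical up to the division time and diverges afterwards (the drift
#' processes decouple at division).
#'
#' @param cfg a [synthetic_config()].
#' @return a [trajectory_set()]; `cells` records the ground truth
#'   (`true_class`, pool multipliers, `sister_of`, division time).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  time <- seq(0, cfg$horizon_min, by = cfg$frame_min)
  nt <- length(time)
  n_dose <- length(cfg$doses_pM)
  per_dose <- rep(cfg$n_cells %/% n_dose, n_dose)
  extra <- cfg$n_cells - sum(per_dose)
  if (extra > 0) per_dose[seq_len(extra)] <- per_dose[seq_len(extra)] + 1

  subpops <- if (cfg$mode == "ode") default_subpopulations() else NULL

  withr::with_seed(cfg$seed, {
    rows <- list()
    cells <- list()
    divisions <- list()
    positions <- list()
    cell_no <- 0

    base_curve <- function(class_id, mult, dose) {
      if (cfg$mode == "ode") {
        sp <- subpops[[class_id]]
        pars <- scaled_parameters(sp$base_params, sp$scalings * mult)
        sim <- simulate_pathway(pars, step_protocol(dose, cfg$horizon_min),
                                time)
        sim$observables[, "ratio_s2"]
      } else {
        amp <- sqrt(mult[["receptor"]] * mult[["smad2"]])
        pla <- sqrt(mult[["receptor"]] / mult[["feedback"]])
        .phenom_curve(time, class_id, amp, pla)
      }
    }

    make_positions <- function(n) {
      if (cfg$spatial == "uniform") {
        cbind(x = stats::runif(n, 0, cfg$field_px[1]),
              y = stats::runif(n, 0, cfg$field_px[2]))
      } else {
        n_par <- max(1, round(n / 8))
        px <- stats::runif(n_par, 0, cfg$field_px[1])
        py <- stats::runif(n_par, 0, cfg$field_px[2])
        pick <- sample.int(n_par, n, replace = TRUE)
        cbind(x = pmin(pmax(px[pick] + stats::rnorm(n, 0, 60), 0),
                       cfg$field_px[1]),
              y = pmin(pmax(py[pick] + stats::rnorm(n, 0, 60), 0),
                       cfg$field_px[2]))
      }
    }

    for (d in seq_len(n_dose)) {
      nd <- per_dose[d]
      if (nd == 0) next
      dose <- cfg$doses_pM[d]
      classes <- sample.int(6, nd, replace = TRUE,
                            prob = cfg$proportions[[d]])
      mult <- sample_pools(cfg$noise, nd)
      pos <- make_positions(nd)
      n_div <- stats::rpois(nd, cfg$division_rate * cfg$horizon_min / 1440)

      for (i in seq_len(nd)) {
        cell_no <- cell_no + 1
        id <- sprintf("c%05d", cell_no)
        clean <- base_curve(classes[i], mult[i, ], dose)
        drift <- if (cfg$drift_sd > 0)
          .ou_path(nt, cfg$frame_min, cfg$drift_sd, cfg$drift_tau)
        else numeric(nt)
        meas <- if (cfg$meas_sd > 0)
          stats::rnorm(nt, 0, cfg$meas_sd) - cfg$meas_sd^2 / 2
        else numeric(nt)
        ratio <- clean * exp(drift - cfg$drift_sd^2 / 2) * exp(meas)
        div_t <- if (n_div[i] > 0)
          sort(round(stats::runif(n_div[i], cfg$frame_min,
                                  cfg$horizon_min - cfg$frame_min) /
                       cfg$frame_min) * cfg$frame_min)
        else numeric(0)
        rows[[id]] <- ratio
        cells[[id]] <- data.frame(
          cell_id = id, dose_pM = dose, true_class = classes[i],
          mult_receptor = mult[i, "receptor"],
          mult_smad2 = mult[i, "smad2"], mult_smad4 = mult[i, "smad4"],
          mult_feedback = mult[i, "feedback"],
          mult_dephos = mult[i, "dephos"],
          sister_of = NA_character_)
        positions[[id]] <- data.frame(cell_id = id,
                                      x = pos[i, 1], y = pos[i, 2])
        if (length(div_t) > 0)
          divisions[[id]] <- data.frame(cell_id = id, time = div_t)

        # lineage mode: one sister per first division, identical history
        if (cfg$lineage && length(div_t) > 0) {
          td <- div_t[1]
          k <- which(time >= td)[1]
          cell_no <- cell_no + 1
          sid <- sprintf("c%05d", cell_no)
          drift2 <- drift
          if (k < nt && cfg$drift_sd > 0)
            drift2[k:nt] <- .ou_path(nt - k + 1, cfg$frame_min,
                                     cfg$drift_sd, cfg$drift_tau,
                                     start = drift[k])
          meas2 <- meas
          if (k < nt && cfg$meas_sd > 0)
            meas2[k:nt] <- stats::rnorm(nt - k + 1, 0, cfg$meas_sd) -
              cfg$meas_sd^2 / 2
          ratio2 <- clean * exp(drift2 - cfg$drift_sd^2 / 2) * exp(meas2)
          ratio2[seq_len(k - 1)] <- ratio[seq_len(k - 1)]
          rows[[sid]] <- ratio2
          cinfo <- cells[[id]]
          cinfo$cell_id <- sid
          cinfo$sister_of <- id
          cells[[sid]] <- cinfo
          positions[[sid]] <- data.frame(
            cell_id = sid,
            x = min(max(pos[i, 1] + stats::rnorm(1, 0, 15), 0),
                    cfg$field_px[1]),
            y = min(max(pos[i, 2] + stats::rnorm(1, 0, 15), 0),
                    cfg$field_px[2]))
          divisions[[sid]] <- data.frame(cell_id = sid, time = td)
        }
      }
    }

    ratio <- do.call(rbind, rows)
    cells_df <- do.call(rbind, cells)
    rownames(cells_df) <- NULL
    div_df <- if (length(divisions) > 0) {
      d <- do.call(rbind, divisions); rownames(d) <- NULL; d
    } else data.frame(cell_id = character(0), time = numeric(0))
    pos_df <- do.call(rbind, positions)
    rownames(pos_df) <- NULL
    trajectory_set(time, ratio, cells_df, div_df, pos_df)
  })
}

#' Generate synthetic population-median fitting datasets
#'
#' Simulates each protocol with the given parameters, reads off the
#' requested observable at the observation times and applies multiplicative
#' Gaussian noise, emulating median time courses of dose responses,
#' restimulations, inhibitor treatments and receptor/mRNA fold changes.
#'
#' @param params a [pathway_parameters()] generating set.
#' @param specs data.frame with columns `name`, `observable` (one of
#'   `ratio_s2`, `ratio_s4`, `receptor_fc`, `fb_mrna_fc`) and a list-column
#'   `protocol` of [stimulus_protocol()] objects, plus optional `times`
#'   list-column (defaults to every 30 min over the horizon).
#' @param noise_sd relative (multiplicative) noise level, e.g. 0.05.
#' @param seed integer seed.
#' @return list of `fit_dataset` objects (see [fit_dataset()]).
#' @export
generate_fit_datasets <- function(params, specs, noise_sd, seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(nrow(specs)), function(i) {
      prot <- specs$protocol[[i]]
      times <- if (!is.null(specs$times)) specs$times[[i]]
        else seq(0, prot$horizon_min, by = 30)
      sim <- simulate_pathway(params, prot, times)
      y <- sim$observables[, specs$observable[i]]
      sd_abs <- noise_sd * pmax(abs(y), 1e-12)
      obs <- y + stats::rnorm(length(y), 0, sd_abs)
      fit_dataset(name = specs$name[i],
                  observable = specs$observable[i], protocol = prot,
                  times = times, values = obs,
                  sd = if (noise_sd > 0) sd_abs else NULL)
    })
  })
}

#' Reference fitting-dataset design (dose series plus perturbations)
#'
#' The suite of population-median protocols used for population-average
#' calibration: nuc/cyt SMAD2 dose responses, a SMAD4 ratio course,
#' restimulation, receptor-inhibitor and transcription-inhibitor
#' treatments, and receptor/feedback-mRNA fold changes.
#'
#' @param horizon_min protocol horizon (min).
#' @return specification data.frame for [generate_fit_datasets()].
#' @export
reference_fit_design <- function(horizon_min = 1440) {
  doses <- c(1, 2.5, 5, 25, 100)
  specs <- data.frame(
    name = c(paste0("s2_dose_", doses), "s4_100", "restim_5_8h",
             "sb_100_2h", "drb_100", "receptor_100", "mrna_100"),
    observable = c(rep("ratio_s2", length(doses)), "ratio_s4", "ratio_s2",
                   "ratio_s2", "ratio_s2", "receptor_fc", "fb_mrna_fc"))
  protos <- c(
    lapply(doses, step_protocol, horizon_min = horizon_min),
    list(step_protocol(100, horizon_min),
         restim_protocol(5, 480, horizon_min),
         stimulus_protocol(horizon_min, data.frame(
           time = c(0, 120), kind = c("ligand_set", "receptor_inhibit"),
           dose = c(100, NA))),
         stimulus_protocol(horizon_min, data.frame(
           time = c(0, 0.01),
           kind = c("transcription_inhibit", "ligand_set"),
           dose = c(NA, 100))),
         step_protocol(100, horizon_min),
         step_protocol(100, horizon_min)))
  specs$protocol <- protos
  specs
}
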