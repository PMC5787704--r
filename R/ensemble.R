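#' Log-normal protein-level noise specification
#'
#' Cell-to-cell protein-level variation is modeled as the product of two
#' log-normal factors: a correlated factor shared by all signaling proteins
#' of a cell (global expression machinery) and an uncorrelated factor
#' specific to each protein (gene-intrinsic fluctuations). Both are
#' mean-preserving (the -sigma^2/2 correction is applied in log space).
#'
#' @param sigma_corr std of the shared log-factor (log space, >= 0).
#' @param sigma_uncorr std of the per-protein log-factor (log space, >= 0).
#' @export
noise_spec <- function(sigma_corr, sigma_uncorr) {
  stopifnot(sigma_corr >= 0, sigma_uncorr >= 0)
  structure(list(sigma_corr = sigma_corr, sigma_uncorr = sigma_uncorr),
            class = "noise_spec")
}

.pool_names <- c("receptor", "smad2", "smad4", "feedback", "dephos")

#' Apply subpopulation pool scalings to a parameter set
#'
#' Only protein-level quantities are rescaled; all kinetic rate constants
#' stay at their population-average values. `receptor` scales receptor
#' production (and thereby the steady-state receptor pool), `smad2`/`smad4`
#' the total SMAD pools, `feedback` the feedback expression strength (basal
#' and induced transcription together), and `dephos` the nuclear
#' dephosphorylation capacity.
#'
#' @param params a [pathway_parameters()] object.
#' @param scalings named numeric vector over
#'   `c("receptor","smad2","smad4","feedback","dephos")`; missing entries
#'   default to 1.
#' @return a rescaled [pathway_parameters()] object.
#' @export
scaled_parameters <- function(params, scalings) {
  s <- stats::setNames(rep(1, length(.pool_names)), .pool_names)
  s[names(scalings)] <- scalings
  q <- unclass(params)
  q["pr"] <- q["pr"] * s["receptor"]
  q["S2_tot"] <- q["S2_tot"] * s["smad2"]
  q["S4_tot"] <- q["S4_tot"] * s["smad4"]
  q["fb_scale"] <- q["fb_scale"] * s["feedback"]
  q["kdephos"] <- q["kdephos"] * s["dephos"]
  pathway_parameters(q)
}

#' Subpopulation model: shared kinetics, class-specific protein pools
#'
#' @param class_id signaling class id (1..k).
#' @param scalings named pool scalings (see [scaled_parameters()]), each
#'   within `bounds`.
#' @param base_params the shared population-average
#'   [pathway_parameters()].
#' @param bounds allowed scaling range, default `c(0.5, 2)` (the typical
#'   cell-to-cell variation of intracellular protein levels).
#' @export
subpopulation_model <- function(class_id, scalings, base_params,
                                bounds = c(0.5, 2)) {
  stopifnot(all(names(scalings) %in% .pool_names))
  s <- stats::setNames(rep(1, length(.pool_names)), .pool_names)
  s[names(scalings)] <- scalings
  if (any(s < bounds[1] - 1e-9) || any(s > bounds[2] + 1e-9))
    stop("pool scalings outside bounds [", bounds[1], ", ", bounds[2], "]")
  structure(list(class_id = as.integer(class_id), scalings = s,
                 base_params = base_params, bounds = bounds),
            class = "subpopulation_model")
}

#' Reference six-class subpopulation models
#'
#' Pool scalings for six signaling classes ordered by late-phase activity:
#' class 1 (minimal response: few receptors, strong feedback, high
#' dephosphorylation capacity) through class 6 (strong sustained response:
#' abundant receptors, weak feedback). All scalings lie within the 0.5-2x
#' range.
#'
#' @param base_params shared kinetics, default [default_parameters()].
#' @return list of six [subpopulation_model()] objects.
#' @export
default_subpopulations <- function(base_params = default_parameters()) {
  tab <- rbind(
    c(0.50, 0.90, 0.90, 2.00, 2.00),
    c(0.70, 1.00, 1.00, 1.60, 1.50),
    c(0.90, 1.00, 1.00, 1.40, 1.00),
    c(1.10, 1.00, 1.00, 0.80, 1.00),
    c(1.30, 1.10, 1.10, 0.65, 0.90),
    c(1.80, 1.30, 1.20, 0.50, 0.80))
  colnames(tab) <- .pool_names
  lapply(seq_len(nrow(tab)), function(i)
    subpopulation_model(i, tab[i, ], base_params))
}

#' Reference class proportions per dose
#'
#' Qualitative dose dependence of signaling-class membership: low doses
#' dominated by non-responding/transient classes 1-3, high doses by
#' sustained classes 4-6.
#'
#' @param dose_pM one of 1, 2.5, 5, 25, 100.
#' @return named numeric vector of six proportions summing to 1.
#' @export
default_class_proportions <- function(dose_pM) {
  tab <- rbind(
    `1`   = c(0.55, 0.25, 0.12, 0.05, 0.02, 0.01),
    `2.5` = c(0.35, 0.28, 0.18, 0.10, 0.06, 0.03),
    `5`   = c(0.20, 0.25, 0.22, 0.15, 0.11, 0.07),
    `25`  = c(0.06, 0.12, 0.17, 0.24, 0.23, 0.18),
    `100` = c(0.03, 0.07, 0.13, 0.25, 0.27, 0.25))
  key <- as.character(dose_pM)
  if (!key %in% rownames(tab)) stop("no reference proportions for dose ",
                                    dose_pM, " pM")
  stats::setNames(tab[key, ], paste0("class", 1:6))
}

#' Sample per-cell protein pool multipliers
#'
#' For each cell one shared factor exp(sigma_corr * z - sigma_corr^2/2) and
#' per-pool factors exp(sigma_uncorr * z_i - sigma_uncorr^2/2) are drawn
#' (z standard normal); the multiplier of a pool is their product, so pool
#' means are preserved.
#'
#' @param noise a [noise_spec()].
#' @param n number of cells.
#' @param seed integer seed (local RNG; does not disturb the global state).
#' @return n x 5 matrix of multipliers, columns
#'   `receptor, smad2, smad4, feedback, dephos`.
#' @export
sample_pools <- function(noise, n, seed = NULL) {
  stopifnot(n >= 1)
  runner <- function() {
    sc <- noise$sigma_corr
    su <- noise$sigma_uncorr
    shared <- exp(sc * stats::rnorm(n) - sc^2 / 2)
    spec <- matrix(exp(su * stats::rnorm(n * length(.pool_names)) -
                         su^2 / 2),
                   nrow = n)
    m <- shared * spec
    colnames(m) <- .pool_names
    m
  }
  if (is.null(seed)) runner() else withr::with_seed(seed, runner())
}

#' Simulate a heterogeneous single-cell population
#'
#' Members are assigned to subpopulations multinomially according to
#' `proportions`; each member is simulated with its subpopulation's scaled
#' pools further multiplied by sampled log-normal noise. A population
#' assembled from the class proportions observed at one dose may be
#' simulated at any other dose (cross-dose prediction).
#'
#' @param subpops list of [subpopulation_model()] objects.
#' @param proportions membership probabilities, one per subpopulation,
#'   summing to 1.
#' @param noise a [noise_spec()].
#' @param n number of cells.
#' @param dose_pM stimulus dose applied at t = 0.
#' @param seed integer seed; populations are bit-reproducible given the
#'   seed and configuration.
#' @param horizon_min,by_min simulation horizon and frame interval (min).
#' @return a [trajectory_set()]; `cells` carries `class_origin` and the
#'   sampled pool multipliers. Members whose simulation fails are dropped
#'   and counted (attribute `n_failed`; more than 5% failures is an error).
#' @export
simulate_population <- function(subpops, proportions, noise, n, dose_pM,
                                seed, horizon_min = 1440, by_min = 5) {
  stopifnot(length(proportions) == length(subpops), n >= 1)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  times <- seq(0, horizon_min, by = by_min)
  draws <- withr::with_seed(seed, {
    membership <- sample.int(length(subpops), n, replace = TRUE,
                             prob = proportions)
    mult <- sample_pools(noise, n)
    list(membership = membership, mult = mult)
  })
  membership <- draws$membership
  mult <- draws$mult
  ratio <- matrix(NA_real_, n, length(times))
  ok <- logical(n)
  for (i in seq_len(n)) {
    sp <- subpops[[membership[i]]]
    pars <- scaled_parameters(sp$base_params,
                              sp$scalings * mult[i, ])
    sim <- tryCatch(
      simulate_pathway(pars, step_protocol(dose_pM, horizon_min), times),
      error = function(e) NULL)
    if (!is.null(sim)) {
      ratio[i, ] <- sim$observables[, "ratio_s2"]
      ok[i] <- TRUE
    }
  }
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * n)
    stop(n_failed, " of ", n, " member simulations failed (> 5%)")
  ids <- sprintf("cell%05d", seq_len(n))[ok]
  cells <- data.frame(cell_id = ids, dose_pM = dose_pM,
                      class_origin = membership[ok])
  cells <- cbind(cells,
                 stats::setNames(as.data.frame(mult[ok, , drop = FALSE]),
                                 paste0("mult_", .pool_names)))
  ratio <- ratio[ok, , drop = FALSE]
  rownames(ratio) <- ids
  ts <- trajectory_set(times, ratio, cells)
  attr(ts, "n_failed") <- n_failed
  attr(ts, "seed") <- seed
  ts
}

#' Direct-ensemble baseline population
#'
#' The simpler comparator model: protein pools are sampled directly around
#' the population-average best fit (a single subpopulation with unit
#' scalings), without class-resolved subpopulation fitting.
#'
#' @inheritParams simulate_population
#' @param population_fit the population-average [pathway_parameters()].
#' @export
direct_ensemble_baseline <- function(population_fit, noise, n, dose_pM,
                                     seed, horizon_min = 1440, by_min = 5) {
  base <- subpopulation_model(1L, c(receptor = 1), population_fit)
  simulate_population(list(base), 1, noise, n, dose_pM, seed,
                      horizon_min, by_min)
}

#' Extract signaling features (E, L, E/L, T) from a trajectory
#'
#' E is the maximal nuc/cyt ratio within the first-peak window (default
#' 0-150 min), L the ratio at 300 min (nearest grid point), E/L the
#' adaptation ratio, and T the time of the overall maximum (earliest frame
#' on ties).
#'
#' @param values numeric vector or matrix (cells x frames) of ratios.
#' @param time frame times (min); must cover 300 min.
#' @param peak_window window for the first peak (min).
#' @return data.frame with columns `E`, `L`, `EL`, `T` (one row per cell).
#' @export
extract_features <- function(values, time, peak_window = c(0, 150)) {
  if (max(time) < 300) stop("trajectory must cover at least 300 min")
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  win <- time >= peak_window[1] & time <= peak_window[2]
  i300 <- which.min(abs(time - 300))
  E <- apply(values[, win, drop = FALSE], 1, max)
  L <- values[, i300]
  Tm <- time[apply(values, 1, which.max)]
  data.frame(E = E, L = L, EL = E / L, T = Tm,
             row.names = rownames(values))
}

#' Distance between two feature-distribution sets
#'
#' Each of the four features is binned on a common grid anchored at the
#' pooled 1st-99th percentiles (20 equal-width bins by default); the sum of
#' squared differences between the normalized histograms is accumulated
#' over features. A feature with zero variance in both sets contributes 0.
#'
#' @param sim_features,data_features data.frames from
#'   [extract_features()].
#' @param bins number of histogram bins per feature.
#' @return non-negative dissimilarity (0 for identical samples); symmetric
#'   in its arguments.
#' @export
feature_distribution_distance <- function(sim_features, data_features,
                                          bins = 20) {
  feats <- c("E", "L", "EL", "T")
  stopifnot(nrow(sim_features) > 0, nrow(data_features) > 0)
  total <- 0
  for (f in feats) {
    xs <- sim_features[[f]]
    xd <- data_features[[f]]
    pooled <- c(xs, xd)
    if (stats::sd(pooled) == 0) next   # degenerate in both sets
    rng <- stats::quantile(pooled, c(0.01, 0.99), names = FALSE)
    if (rng[1] == rng[2]) rng <- range(pooled)
    if (rng[1] == rng[2]) next
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    clamp <- function(v) pmin(pmax(v, rng[1]), rng[2])
    hs <- graphics::hist(clamp(xs), breaks = brk, plot = FALSE)$counts
    hd <- graphics::hist(clamp(xd), breaks = brk, plot = FALSE)$counts
    total <- total + sum((hs / sum(hs) - hd / sum(hd))^2)
  }
  total
}

#' Calibrate correlated/uncorrelated noise magnitudes on a score grid
#'
#' For every (sigma_corr, sigma_uncorr) pair a population of `n_per_point`
#' cells is simulated, features are extracted and scored against the data
#' features; the score surface is normalized by its maximum and the argmin
#' returned.
#'
#' @param subpops list of [subpopulation_model()] objects.
#' @param proportions class proportions for population assembly.
#' @param data_features data.frame from [extract_features()] on the
#'   reference data.
#' @param sigma_corr_grid,sigma_uncorr_grid grid values (log-space stds).
#' @param n_per_point cells per grid point (>= 100).
#' @param dose_pM stimulus dose.
#' @param seed integer seed.
#' @param horizon_min,by_min simulation grid passed to
#'   [simulate_population()].
#' @param bins histogram bins for the feature distance.
#' @return list with `surface` (data.frame sigma_corr, sigma_uncorr, score,
#'   score_norm), `optimum` (row of the surface with minimal score) and
#'   `noise` (the optimal [noise_spec()]).
#' @export
calibrate_noise <- function(subpops, proportions, data_features,
                            sigma_corr_grid, sigma_uncorr_grid,
                            n_per_point, dose_pM, seed,
                            horizon_min = 720, by_min = 5, bins = 20) {
  stopifnot(n_per_point >= 100,
            length(sigma_corr_grid) > 0, length(sigma_uncorr_grid) > 0)
  grid <- expand.grid(sigma_corr = sigma_corr_grid,
                      sigma_uncorr = sigma_uncorr_grid)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pop <- simulate_population(
      subpops, proportions,
      noise_spec(grid$sigma_corr[g], grid$sigma_uncorr[g]),
      n_per_point, dose_pM, seed = seed + g,
      horizon_min = horizon_min, by_min = by_min)
    fx <- extract_features(pop$ratio, pop$time)
    scores[g] <- feature_distribution_distance(fx, data_features,
                                               bins = bins)
  }
  grid$score <- scores
  grid$score_norm <- if (max(scores) > 0) scores / max(scores) else scores
  best <- which.min(scores)
  list(surface = grid, optimum = grid[best, ],
       noise = noise_spec(grid$sigma_corr[best], grid$sigma_uncorr[best]))
}

#' Class-transition matrix between two conditions
#'
#' @param labels_a,labels_b paired class labels of the same cells under two
#'   conditions (equal length).
#' @param k number of classes (default: max observed label).
#' @param min_prob transitions below this probability are set to 0 in the
#'   `masked` copy (display convention; the full matrix is also returned).
#' @return list with `P` (row-stochastic k x k matrix of
#'   P(class_b | class_a)) and `masked`.
#' @export
class_transitions <- function(labels_a, labels_b,
                              k = max(c(labels_a, labels_b)),
                              min_prob = 0.01) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  tab <- matrix(0, k, k,
                dimnames = list(paste0("from", 1:k), paste0("to", 1:k)))
  for (i in seq_along(labels_a))
    tab[labels_a[i], labels_b[i]] <- tab[labels_a[i], labels_b[i]] + 1
  rs <- rowSums(tab)
  P <- tab
  nonzero <- rs > 0
  P[nonzero, ] <- tab[nonzero, , drop = FALSE] / rs[nonzero]
  P[!nonzero, ] <- NA_real_
  masked <- P
  masked[!is.na(masked) & masked < min_prob] <- 0
  list(P = P, masked = masked)
}

#' Scale feedback expression strength in subpopulation models
#'
#' Multiplies the feedback expression strength of every subpopulation by
#' `fraction` (1 = wild type, 0 = complete feedback knock-out), leaving all
#' other pools and kinetics untouched.
#'
#' @param subpops list of [subpopulation_model()] objects.
#' @param fraction remaining feedback expression, in [0, 1].
#' @export
scale_feedback <- function(subpops, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  lapply(subpops, function(sp) {
    q <- unclass(sp$base_params)
    q["fb_scale"] <- q["fb_scale"] * fraction
    sp$base_params <- pathway_parameters(q)
    sp
  })
}

#' Entropy of a parameter's distribution across signaling classes
#'
#' For each independent fit and each parameter, the k per-class values are
#' converted to shares q_i = v_i / sum(v) and the Shannon entropy
#' H = -sum(q_i log2 q_i) is computed. A parameter whose level is identical
#' in all k classes attains the maximal entropy log2(k) (2.585 bits for
#' k = 6); concentration of the parameter in few classes lowers H.
#'
#' @param fits a single k x p matrix (classes x parameters) or a list of
#'   such matrices (one per independent fit).
#' @return matrix of entropies (bits), one row per fit, one column per
#'   parameter.
#' @export
parameter_entropy <- function(fits) {
  if (is.matrix(fits)) fits <- list(fits)
  ent <- function(v) {
    if (any(v < 0)) stop("parameter values must be >= 0")
    s <- sum(v)
    if (s == 0) stop("all-zero parameter column")
    q <- v / s
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  out <- t(vapply(fits, function(m) {
    if (nrow(m) < 2) stop("need k >= 2 classes")
    apply(m, 2, ent)
  }, numeric(ncol(fits[[1]]))))
  if (!is.null(colnames(fits[[1]]))) colnames(out) <- colnames(fits[[1]])
  out
}
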