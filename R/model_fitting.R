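#' A single fitting dataset (one observable under one protocol)
#'
#' @param name dataset label.
#' @param observable one of `"ratio_s2"`, `"ratio_s4"`, `"receptor_fc"`,
#'   `"fb_mrna_fc"`.
#' @param protocol a [stimulus_protocol()].
#' @param times observation times (min), within the protocol horizon.
#' @param values observed values (finite).
#' @param sd fixed measurement noise: scalar or per-point vector; `NULL`
#'   means the noise is estimated by likelihood profiling during fitting.
#' @export
fit_dataset <- function(name, observable, protocol, times, values,
                        sd = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            length(times) == length(values), all(is.finite(values)),
            min(times) >= 0, max(times) <= protocol$horizon_min)
  obs <- c("ratio_s2", "ratio_s4", "receptor_fc", "fb_mrna_fc")
  if (!observable %in% obs)
    stop("observable must be one of ", paste(obs, collapse = ", "))
  if (!is.null(sd)) {
    if (length(sd) == 1) sd <- rep(sd, length(values))
    stopifnot(length(sd) == length(values), all(sd > 0))
  }
  structure(list(name = name, observable = observable, protocol = protocol,
                 times = times, values = values, sd = sd),
            class = "fit_dataset")
}

.model_values <- function(params, ds) {
  sim <- simulate_pathway(params, ds$protocol, ds$times)
  sim$observables[, ds$observable]
}

#' Chi-square objective over a set of datasets
#'
#' Sum over data points of ((model - data)/sigma)^2. For datasets without a
#' fixed sigma the Gaussian likelihood is profiled: the optimal sigma is the
#' RMS residual and the dataset contributes N + N log(sigma_hat^2)
#' (the 2 N log sigma penalty evaluated at the profiled optimum).
#' Simulation failure yields `Inf` with the failing context recorded in
#' attribute `failures`.
#'
#' @param params a [pathway_parameters()] object.
#' @param datasets list of [fit_dataset()] objects.
#' @return chi-square value with attributes `N` (total points),
#'   `per_dataset` (named contributions) and `sigma_hat` (profiled sigmas,
#'   NA where fixed).
#' @export
chi_square <- function(params, datasets) {
  if (inherits(datasets, "fit_dataset")) datasets <- list(datasets)
  contrib <- numeric(length(datasets))
  sig <- rep(NA_real_, length(datasets))
  fails <- character(0)
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    m <- tryCatch(.model_values(params, ds), error = function(e) e)
    if (inherits(m, "error")) {
      fails <- c(fails, paste0(ds$name, ": ", conditionMessage(m)))
      contrib[i] <- Inf
      next
    }
    r <- m - ds$values
    if (!is.null(ds$sd)) {
      contrib[i] <- sum((r / ds$sd)^2)
    } else {
      n <- length(r)
      s2 <- mean(r^2)
      sig[i] <- sqrt(s2)
      contrib[i] <- if (s2 == 0) -Inf else n + n * log(s2)
    }
  }
  out <- sum(contrib)
  attr(out, "N") <- sum(vapply(datasets, function(d) length(d$values),
                               numeric(1)))
  attr(out, "per_dataset") <- stats::setNames(
    contrib, vapply(datasets, `[[`, character(1), "name"))
  attr(out, "sigma_hat") <- sig
  if (length(fails) > 0) attr(out, "failures") <- fails
  out
}

# weighted residual vector for Levenberg-Marquardt, with sigma fixed at the
# supplied values (profiled sigmas are updated between LM rounds)
.residual_vector <- function(params, datasets, sigmas) {
  unlist(lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    m <- tryCatch(.model_values(params, ds), error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, length(ds$values)))
    s <- if (!is.null(ds$sd)) ds$sd else sigmas[i]
    (m - ds$values) / s
  }))
}

.lm_local_fit <- function(start_log, datasets, base_params, free,
                          lower_log, upper_log, profile_rounds = 3) {
  par_from_log <- function(lp) {
    q <- unclass(base_params)
    q[free] <- exp(lp)
    pathway_parameters(q)
  }
  sigmas <- rep(1, length(datasets))
  needs_profile <- vapply(datasets, function(d) is.null(d$sd), logical(1))
  lp <- start_log
  rounds <- if (any(needs_profile)) profile_rounds else 1
  conv <- FALSE
  for (r in seq_len(rounds)) {
    if (any(needs_profile)) {
      cs <- chi_square(par_from_log(lp), datasets)
      sh <- attr(cs, "sigma_hat")
      sigmas[needs_profile] <- pmax(sh[needs_profile], 1e-8, na.rm = TRUE)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = lp,
        fn = function(p) .residual_vector(par_from_log(p), datasets,
                                          sigmas),
        lower = lower_log, upper = upper_log,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    lp <- fit$par
    conv <- fit$info %in% 1:4
  }
  final_params <- par_from_log(lp)
  chi <- chi_square(final_params, datasets)
  list(params = final_params, log_par = lp, chisq = as.numeric(chi),
       converged = conv)
}

#' Multistart chi-square fitting of the pathway model
#'
#' Latin-hypercube starting points in log-parameter space, each refined by
#' Levenberg-Marquardt least squares (with interleaved noise profiling for
#' datasets whose sigma is estimated). Results are sorted by chi-square;
#' the accepted ensemble collects fits within `threshold` of the best.
#'
#' @param datasets list of [fit_dataset()] objects.
#' @param base_params template parameters; entries not in `free` stay
#'   fixed.
#' @param free names of the parameters to optimize.
#' @param lower,upper named bounds on the free parameters (natural scale,
#'   finite and > 0: fitting happens in log space).
#' @param n_starts number of multistarts (>= 1).
#' @param seed integer seed determining the Latin-hypercube start matrix.
#' @param threshold accepted-ensemble width Delta chi-square, default 10.
#' @return object of class `fit_result`: list with `best` (parameters),
#'   `chisq`, `N`, `starts` (per-start data.frame), `accepted` (indices of
#'   fits within threshold), `ensemble` (their parameter sets), `seed`.
#' @export
multistart_fit <- function(datasets, base_params, free, lower, upper,
                           n_starts = 10, seed = 1L, threshold = 10) {
  stopifnot(n_starts >= 1, all(free %in% names(base_params)),
            all(free %in% names(lower)), all(free %in% names(upper)),
            all(lower[free] > 0), all(is.finite(upper[free])))
  llo <- log(lower[free])
  lhi <- log(upper[free])
  u <- withr::with_seed(seed, lhs::randomLHS(n_starts, length(free)))
  starts_log <- sweep(sweep(u, 2, lhi - llo, `*`), 2, llo, `+`)
  fits <- vector("list", n_starts)
  reasons <- character(0)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- .lm_local_fit(starts_log[s, ], datasets, base_params,
                               free, llo, lhi)
    if (is.null(fits[[s]]))
      reasons <- c(reasons, paste0("start ", s, ": optimizer failure"))
  }
  okidx <- which(!vapply(fits, is.null, logical(1)))
  if (length(okidx) == 0)
    stop("all starts failed: ", paste(reasons, collapse = "; "))
  chis <- vapply(fits[okidx], `[[`, numeric(1), "chisq")
  ord <- okidx[order(chis)]
  tab <- data.frame(start = ord,
                    chisq = vapply(fits[ord], `[[`, numeric(1), "chisq"),
                    converged = vapply(fits[ord], `[[`, logical(1),
                                       "converged"))
  best <- fits[[ord[1]]]
  accepted <- which(tab$chisq <= tab$chisq[1] + threshold)
  structure(list(best = best$params, chisq = best$chisq,
                 N = attr(chi_square(best$params, datasets), "N"),
                 starts = tab, accepted = accepted,
                 ensemble = lapply(fits[ord[accepted]], `[[`, "params"),
                 threshold = threshold, free = free, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: best chi-square", format(x$chisq), "on N =", x$N,
      "points;", length(x$accepted), "of", nrow(x$starts),
      "starts accepted (threshold", x$threshold, ")\n")
  invisible(x)
}

#' Fit subpopulation models to signaling-class median trajectories
#'
#' Each class median is fitted by rescaling only the signaling protein
#' pools (receptor, SMAD2, SMAD4, feedback expression strength,
#' dephosphorylation capacity) within `bounds` around the shared
#' population-average fit; every kinetic rate constant is left untouched,
#' so the k returned models differ only in protein levels.
#'
#' @param class_medians k x frames matrix of class-median nuc/cyt SMAD2
#'   ratios (all on one grid, one shared protocol).
#' @param time the shared time grid (min).
#' @param population_fit the shared [pathway_parameters()].
#' @param dose_pM the protocol (single step) all medians were observed
#'   under, default 100.
#' @param bounds allowed pool scaling range, default `c(0.5, 2)`.
#' @param pools which pools may vary (default all five).
#' @return list of [subpopulation_model()] objects with per-class `chisq`
#'   attribute (unweighted SSE) and attribute `total_chisq`; classes whose
#'   optimization failed carry `failed = TRUE`.
#' @export
fit_subpopulations <- function(class_medians, time, population_fit,
                               dose_pM = 100, bounds = c(0.5, 2),
                               pools = c("receptor", "smad2", "smad4",
                                         "feedback", "dephos")) {
  stopifnot(is.matrix(class_medians), all(pools %in% .pool_names))
  horizon <- max(time)
  prot <- step_protocol(dose_pM, horizon)
  k <- nrow(class_medians)
  out <- vector("list", k)
  total <- 0
  for (g in seq_len(k)) {
    target <- class_medians[g, ]
    resid <- function(lp) {
      s <- stats::setNames(rep(1, length(.pool_names)), .pool_names)
      s[pools] <- exp(lp)
      sim <- tryCatch(
        simulate_pathway(scaled_parameters(population_fit, s), prot, time),
        error = function(e) NULL)
      if (is.null(sim)) return(rep(1e6, length(target)))
      sim$observables[, "ratio_s2"] - target
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = rep(0, length(pools)), fn = resid,
                         lower = rep(log(bounds[1]), length(pools)),
                         upper = rep(log(bounds[2]), length(pools)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      sp <- subpopulation_model(g, stats::setNames(rep(1, length(pools)),
                                                   pools),
                                population_fit, bounds)
      sp$failed <- TRUE
      out[[g]] <- sp
      next
    }
    scal <- stats::setNames(exp(fit$par), pools)
    sp <- subpopulation_model(g, scal, population_fit, bounds)
    sp$chisq <- sum(resid(fit$par)^2)
    sp$failed <- FALSE
    total <- total + sp$chisq
    out[[g]] <- sp
  }
  attr(out, "total_chisq") <- total
  out
}
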