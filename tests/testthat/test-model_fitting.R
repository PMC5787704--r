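make_small_datasets <- function(params, noise_sd = 0, seed = 1) {
  specs <- data.frame(
    name = c("s2_5", "s2_100"),
    observable = "ratio_s2")
  specs$protocol <- list(step_protocol(5, 720), step_protocol(100, 720))
  specs$times <- list(seq(0, 720, 60), seq(0, 720, 60))
  generate_fit_datasets(params, specs, noise_sd, seed = seed)
}

test_that("chi-square reproduces its closed-form pieces", {
  p <- default_parameters()
  ds <- make_small_datasets(p, noise_sd = 0)
  # data generated exactly by params, fixed sigma -> zero
  for (d in seq_along(ds)) ds[[d]]$sd <- rep(0.05, length(ds[[d]]$values))
  expect_equal(as.numeric(chi_square(p, ds)), 0, tolerance = 1e-12)

  # one point off by 2 sigma contributes exactly 4
  ds2 <- ds
  ds2[[1]]$values[3] <- ds2[[1]]$values[3] + 2 * 0.05
  expect_equal(as.numeric(chi_square(p, ds2)), 4, tolerance = 1e-8)

  # profiled sigma equals the RMS residual of the dataset
  ds3 <- make_small_datasets(p, noise_sd = 0.05, seed = 3)
  for (d in seq_along(ds3)) ds3[[d]]$sd <- NULL
  cs <- chi_square(p, ds3)
  sim <- simulate_pathway(p, ds3[[1]]$protocol, ds3[[1]]$times)
  rms <- sqrt(mean((sim$observables[, "ratio_s2"] - ds3[[1]]$values)^2))
  expect_equal(attr(cs, "sigma_hat")[1], rms, tolerance = 1e-10)
  # the profiled contribution is N + N log sigma^2
  n <- length(ds3[[1]]$values)
  expect_equal(unname(attr(cs, "per_dataset")[1]), n + n * log(rms^2),
               tolerance = 1e-10)

  # invariant under dataset reordering
  expect_equal(as.numeric(chi_square(p, rev(ds3))),
               as.numeric(chi_square(p, ds3)))
  expect_equal(attr(chi_square(p, ds3), "N"), 2 * n)
})

test_that("multistart fitting recovers an identifiable observation scale
           and improves every start", {
  p <- default_parameters()
  q <- unclass(p)
  q["obs_scale_s2"] <- 1.37
  truth <- pathway_parameters(q)
  ds <- make_small_datasets(truth, noise_sd = 0)
  for (d in seq_along(ds)) ds[[d]]$sd <- rep(0.02, length(ds[[d]]$values))

  fit <- multistart_fit(
    ds, p, free = c("obs_scale_s2", "kphos"),
    lower = c(obs_scale_s2 = 0.3, kphos = 0.003),
    upper = c(obs_scale_s2 = 3, kphos = 0.3),
    n_starts = 5, seed = 7)

  # best fit at least as good as the truth (a feasible point)
  expect_lte(fit$chisq, as.numeric(chi_square(truth, ds)) + 1e-6)
  # scale recovered within 5 percent on noise-free data
  expect_lt(abs(fit$best[["obs_scale_s2"]] / 1.37 - 1), 0.05)
  # monotone improvement: every start ends at or below its start value
  u <- withr::with_seed(7, lhs::randomLHS(5, 2))
  llo <- log(c(0.3, 0.003)); lhi <- log(c(3, 0.3))
  for (srow in seq_len(5)) {
    lp <- llo + u[srow, ] * (lhi - llo)
    q0 <- unclass(p)
    q0[c("obs_scale_s2", "kphos")] <- exp(lp)
    start_chi <- as.numeric(chi_square(pathway_parameters(q0), ds))
    end_chi <- fit$starts$chisq[fit$starts$start == srow]
    expect_lte(end_chi, start_chi + 1e-6)
  }
  # the accepted-ensemble envelope contains the best trajectory pointwise
  sims <- sapply(fit$ensemble, function(pp)
    simulate_pathway(pp, ds[[2]]$protocol,
                     ds[[2]]$times)$observables[, "ratio_s2"])
  best <- simulate_pathway(fit$best, ds[[2]]$protocol,
                           ds[[2]]$times)$observables[, "ratio_s2"]
  expect_true(all(best >= apply(sims, 1, min) - 1e-9))
  expect_true(all(best <= apply(sims, 1, max) + 1e-9))
})

test_that("prediction band from a noisy refit covers the noise-free
           truth", {
  p <- default_parameters()
  ds <- make_small_datasets(p, noise_sd = 0.05, seed = 5)
  fit <- multistart_fit(
    ds, p, free = c("obs_scale_s2", "kphos"),
    lower = c(obs_scale_s2 = 0.3, kphos = 0.003),
    upper = c(obs_scale_s2 = 3, kphos = 0.3),
    n_starts = 4, seed = 2, threshold = 10)
  truth_curve <- simulate_pathway(p, ds[[2]]$protocol,
                                  ds[[2]]$times)$observables[, "ratio_s2"]
  sims <- sapply(fit$ensemble, function(pp)
    simulate_pathway(pp, ds[[2]]$protocol,
                     ds[[2]]$times)$observables[, "ratio_s2"])
  if (is.null(dim(sims))) sims <- matrix(sims, ncol = 1)
  lo <- apply(sims, 1, min) - 3 * 0.05 * truth_curve
  hi <- apply(sims, 1, max) + 3 * 0.05 * truth_curve
  covered <- mean(truth_curve >= lo & truth_curve <= hi)
  expect_gte(covered, 0.9)
})

test_that("subpopulation refits recover singly varied pools and freeze
           kinetics", {
  p <- default_parameters()
  time <- seq(0, 720, 10)
  # identical medians -> all scalings 1
  base <- simulate_pathway(p, step_protocol(100, 720),
                           time)$observables[, "ratio_s2"]
  fits <- fit_subpopulations(rbind(base, base), time, p)
  for (f in fits) expect_equal(unname(f$scalings), rep(1, 5),
                               tolerance = 1e-4)

  # per-pool recovery within 10 percent
  for (pool in c("receptor", "smad2", "feedback")) {
    s_true <- stats::setNames(1.5, pool)
    med <- simulate_pathway(scaled_parameters(p, s_true),
                            step_protocol(100, 720),
                            time)$observables[, "ratio_s2"]
    f1 <- fit_subpopulations(matrix(med, 1), time, p, pools = pool)
    expect_lt(abs(f1[[1]]$scalings[pool] / 1.5 - 1), 0.1)
  }

  # kinetic rates identical across returned models by construction
  sub <- fit_subpopulations(rbind(base, base * 1.1), time, p)
  kin <- names(default_parameters())[1:27]
  kin <- setdiff(kin, c("pr", "fb_scale", "kdephos"))
  for (k in kin)
    expect_identical(sub[[1]]$base_params[[k]], sub[[2]]$base_params[[k]])
})
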