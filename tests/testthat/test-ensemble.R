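test_that("pool multipliers follow the mean-preserving log-normal model", {
  # zero noise: all multipliers exactly 1
  m0 <- sample_pools(noise_spec(0, 0), 10, seed = 1)
  expect_true(all(m0 == 1))
  # no uncorrelated part: one shared multiplier per cell
  mc <- sample_pools(noise_spec(0.3, 0), 50, seed = 2)
  expect_true(all(abs(mc - mc[, 1]) < 1e-12))
  # closed-form CV at large n
  sc <- 0.2; su <- 0.3
  m <- sample_pools(noise_spec(sc, su), 1e5, seed = 3)
  cv_expected <- sqrt(exp(sc^2 + su^2) - 1)
  cv_sample <- sd(m[, "receptor"]) / mean(m[, "receptor"])
  expect_lt(abs(cv_sample / cv_expected - 1), 0.02)
  expect_lt(abs(mean(m[, "smad2"]) - 1), 0.02)
})

test_that("population simulation is reproducible, respects proportions and
           collapses under zero noise", {
  subpops <- default_subpopulations()[1:2]
  one <- simulate_population(subpops[1], 1, noise_spec(0, 0), 5, 100,
                             seed = 4, horizon_min = 360, by_min = 20)
  # single subpopulation, zero noise: identical members
  expect_true(all(apply(one$ratio, 2, function(v) diff(range(v)) == 0)))

  popA <- simulate_population(subpops, c(0.3, 0.7), noise_spec(0.1, 0.1),
                              60, 100, seed = 5, horizon_min = 360,
                              by_min = 20)
  popB <- simulate_population(subpops, c(0.3, 0.7), noise_spec(0.1, 0.1),
                              60, 100, seed = 5, horizon_min = 360,
                              by_min = 20)
  expect_identical(popA$ratio, popB$ratio)   # bit-identical given seed

  big <- simulate_population(subpops, c(0.3, 0.7), noise_spec(0.1, 0.1),
                             800, 100, seed = 6, horizon_min = 360,
                             by_min = 30)
  f1 <- mean(big$cells$class_origin == 1)
  # multinomial 99 percent bound at n = 800
  expect_lt(abs(f1 - 0.3), 2.58 * sqrt(0.3 * 0.7 / 800))
})

test_that("assembled pool distributions are unimodal and right-skewed", {
  subpops <- default_subpopulations()
  pop <- simulate_population(subpops, default_class_proportions(100),
                             noise_spec(0.15, 0.25), 1500, 100, seed = 8,
                             horizon_min = 300, by_min = 50)
  pools <- pop$cells$mult_receptor *
    sapply(pop$cells$class_origin,
           function(k) subpops[[k]]$scalings["receptor"])
  dens <- density(pools)
  peaks <- which(diff(sign(diff(dens$y))) == -2) + 1
  main <- dens$y[peaks] > 0.1 * max(dens$y)
  expect_equal(sum(main), 1)                 # one dominant mode
  sk <- mean((pools - mean(pools))^3) / sd(pools)^3
  expect_gt(sk, 0)                           # right-skewed
})

test_that("feature extraction follows its definitions and tie rules", {
  time <- seq(0, 600, 5)
  pulse <- 1.2 + 0.8 * (time / 60) * exp(1 - time / 60)
  f <- extract_features(pulse, time)
  expect_equal(f$T, 60)
  expect_equal(f$E, max(pulse))
  expect_equal(f$L, pulse[time == 300])
  expect_equal(f$EL, f$E / f$L)
  # constant trajectory: E = L, E/L = 1, earliest-frame tie rule for T
  fc <- extract_features(rep(2, length(time)), time)
  expect_equal(fc$E, 2)
  expect_equal(fc$L, 2)
  expect_equal(fc$EL, 1)
  expect_equal(fc$T, 0)
  expect_error(extract_features(pulse[time < 300], time[time < 300]),
               "300")
  # class 6 median exceeds class 1 in both E and L
  subpops <- default_subpopulations()
  meds <- t(sapply(subpops[c(1, 6)], function(sp) {
    pars <- scaled_parameters(sp$base_params, sp$scalings)
    simulate_pathway(pars, step_protocol(100, 600),
                     time)$observables[, "ratio_s2"]
  }))
  fm <- extract_features(meds, time)
  expect_gt(fm$E[2], fm$E[1])
  expect_gt(fm$L[2], fm$L[1])
})

test_that("feature-distribution distance is a proper dissimilarity score", {
  set.seed(10)
  mk <- function(mu) data.frame(E = rnorm(400, mu, 1),
                                L = rnorm(400, 1, 0.2),
                                EL = rnorm(400, 2, 0.3),
                                T = rnorm(400, 60, 10))
  a <- mk(3)
  expect_equal(feature_distribution_distance(a, a), 0)
  b <- mk(4)     # 1 SD apart in E
  c3 <- mk(6)    # 3 SD apart
  expect_equal(feature_distribution_distance(a, b),
               feature_distribution_distance(b, a))
  expect_gt(feature_distribution_distance(a, c3),
            feature_distribution_distance(a, b))
  # shuffling rows leaves the distance unchanged
  expect_equal(feature_distribution_distance(a[sample(400), ], b),
               feature_distribution_distance(a, b))
})

test_that("class transitions count correctly and mask rare transitions", {
  # identical labels: identity matrix
  P <- class_transitions(c(1, 2, 3, 1), c(1, 2, 3, 1), k = 3)$P
  expect_equal(unname(P), diag(3))
  # hand-built 6-cell example
  la <- c(1, 1, 1, 2, 2, 2)
  lb <- c(1, 2, 2, 2, 2, 1)
  tr <- class_transitions(la, lb, k = 2)
  expect_equal(unname(tr$P),
               matrix(c(1 / 3, 2 / 3, 1 / 3, 2 / 3), 2, byrow = TRUE))
  expect_equal(unname(rowSums(tr$P)), c(1, 1))
  # random labels: rows always sum to 1
  set.seed(2)
  tr2 <- class_transitions(sample(1:4, 100, TRUE),
                           sample(1:4, 100, TRUE))
  expect_equal(unname(rowSums(tr2$P)), rep(1, 4))
  expect_true(all(tr2$masked[tr2$masked > 0] >= 0.01))
  expect_error(class_transitions(1:3, 1:4), "equal length")
})

test_that("feedback scaling only rescales feedback expression", {
  subpops <- default_subpopulations()
  same <- scale_feedback(subpops, 1)
  for (i in seq_along(subpops))
    expect_identical(same[[i]]$base_params, subpops[[i]]$base_params)
  off <- scale_feedback(subpops, 0)
  expect_equal(off[[3]]$base_params[["fb_scale"]], 0)
  untouched <- setdiff(names(default_parameters()), "fb_scale")
  expect_identical(as.numeric(off[[3]]$base_params[untouched]),
                   as.numeric(subpops[[3]]$base_params[untouched]))
})

test_that("parameter entropy matches its analytic anchors", {
  m <- cbind(uniform = rep(2, 6), point = c(5, 0, 0, 0, 0, 0),
             two = c(3, 3, 0, 0, 0, 0))
  H <- parameter_entropy(m)
  expect_equal(unname(H[1, "uniform"]), log2(6))
  expect_equal(unname(H[1, "point"]), 0)
  expect_equal(unname(H[1, "two"]), 1)
  expect_error(parameter_entropy(cbind(rep(0, 6))), "all-zero")
  expect_error(parameter_entropy(matrix(1, 1, 2)), "k >= 2")
})

test_that("noise calibrated at 100 pM predicts feature distributions at
           2.5 pM without refitting", {
  subpops <- default_subpopulations()
  props <- default_class_proportions(100)
  true_noise <- noise_spec(0.15, 0.25)
  # synthetic truth at both doses
  d100 <- simulate_population(subpops, props, true_noise, 600, 100,
                              seed = 41, horizon_min = 600, by_min = 15)
  d2.5 <- simulate_population(subpops, props, true_noise, 600, 2.5,
                              seed = 42, horizon_min = 600, by_min = 15)
  fx100 <- extract_features(d100$ratio, d100$time)
  fx2.5 <- extract_features(d2.5$ratio, d2.5$time)
  grid <- c(0.05, 0.15, 0.3)
  cal <- calibrate_noise(subpops, props, fx100, grid, grid,
                         n_per_point = 300, dose_pM = 100, seed = 7,
                         horizon_min = 600, by_min = 15)
  # cross-dose prediction with the calibrated noise
  pred <- simulate_population(subpops, props, cal$noise, 600, 2.5,
                              seed = 43, horizon_min = 600, by_min = 15)
  fxp <- extract_features(pred$ratio, pred$time)
  cross <- feature_distribution_distance(fxp, fx2.5)
  expect_lt(cross / max(cal$surface$score),
            unname(quantile(cal$surface$score_norm, 0.25)))
})
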