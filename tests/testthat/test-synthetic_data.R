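test_that("generator collapses to identical trajectories without noise and
           is bit-reproducible", {
  cfg <- synthetic_config(n_cells = 6, doses_pM = 100,
                          proportions = list(c(0, 0, 0, 0, 0, 1)),
                          noise = noise_spec(0, 0), meas_sd = 0,
                          drift_sd = 0, division_rate = 0,
                          horizon_min = 600, seed = 3)
  ts <- generate_population(cfg)
  expect_true(all(apply(ts$ratio, 2, function(v) diff(range(v)) == 0)))

  cfg2 <- synthetic_config(n_cells = 25, seed = 9, lineage = TRUE,
                           division_rate = 1)
  a <- generate_population(cfg2)
  b <- generate_population(cfg2)
  expect_identical(a$ratio, b$ratio)
  expect_identical(a$cells, b$cells)
  expect_identical(a$positions, b$positions)
})

test_that("ode and phenomenological modes agree in the rank order of class
           feature medians", {
  feats <- lapply(c("ode", "phenomenological"), function(mode) {
    cfg <- synthetic_config(n_cells = 90, doses_pM = 100,
                            proportions = list(rep(1 / 6, 6)),
                            mode = mode, meas_sd = 0.02, drift_sd = 0.02,
                            noise = noise_spec(0.05, 0.05),
                            division_rate = 0, horizon_min = 600,
                            seed = 12)
    ts <- generate_population(cfg)
    f <- extract_features(ts$ratio, ts$time)
    sapply(split(f, ts$cells$true_class), function(g)
      c(E = median(g$E), L = median(g$L)))
  })
  expect_equal(order(feats[[1]]["E", ]), order(feats[[2]]["E", ]))
  expect_equal(order(feats[[1]]["L", ]), order(feats[[2]]["L", ]))
})

test_that("clustering the generated set recovers the latent classes when
           separation dominates the within-class spread", {
  cfg <- synthetic_config(n_cells = 150, noise = noise_spec(0.03, 0.03),
                          meas_sd = 0.01, drift_sd = 0.01, seed = 11)
  ts <- generate_population(cfg)
  thin <- thin_trajectories(ts, 3)
  D <- dissimilarity_matrix(thin, cdtw_config(max_run = 2))
  lab <- ts$cells$true_class
  within <- mean(D[outer(lab, lab, "==") & upper.tri(D)])
  between <- mean(D[outer(lab, lab, "!=") & upper.tri(D)])
  expect_gt(between / within, 5)
  cm <- hierarchical_classes(D, 6, thin)
  expect_gt(mclust::adjustedRandIndex(cm$labels, lab), 0.8)
})

test_that("lineage mode produces sisters that share their history", {
  cfg <- synthetic_config(n_cells = 40, doses_pM = 100, seed = 6,
                          lineage = TRUE, division_rate = 1.5)
  ts <- generate_population(cfg)
  sis <- ts$cells[!is.na(ts$cells$sister_of), ]
  expect_gt(nrow(sis), 0)
  for (i in seq_len(min(5, nrow(sis)))) {
    a <- sis$cell_id[i]
    b <- sis$sister_of[i]
    td <- ts$divisions$time[ts$divisions$cell_id == a][1]
    pre <- ts$time < td
    expect_identical(ts$ratio[a, pre], ts$ratio[b, pre])
    # shared pool multipliers
    expect_identical(sis$mult_receptor[i],
                     ts$cells$mult_receptor[ts$cells$cell_id == b])
  }
})

test_that("synthetic fit datasets calibrate chi-square correctly", {
  p <- default_parameters()
  specs <- data.frame(name = c("a", "b"), observable = "ratio_s2")
  specs$protocol <- list(step_protocol(25, 720), step_protocol(100, 720))
  specs$times <- list(seq(0, 720, 30), seq(0, 720, 30))

  exact <- generate_fit_datasets(p, specs, noise_sd = 0, seed = 1)
  for (d in exact) {
    sim <- simulate_pathway(p, d$protocol, d$times)
    expect_equal(d$values, unname(sim$observables[, "ratio_s2"]))
  }

  noisy <- generate_fit_datasets(p, specs, noise_sd = 0.05, seed = 2)
  cs <- chi_square(p, noisy)
  N <- attr(cs, "N")
  expect_gt(as.numeric(cs) / N, 0.5)
  expect_lt(as.numeric(cs) / N, 1.5)
})

test_that("trajectory CSV round trip is value-exact and validation names
           offenders", {
  cfg <- synthetic_config(n_cells = 12, doses_pM = c(5, 100), seed = 2,
                          division_rate = 1, horizon_min = 400)
  ts <- generate_population(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(ts, f)
  back <- read_trajectories(f)
  expect_equal(back$ratio, ts$ratio)
  expect_equal(back$time, ts$time)
  expect_equal(back$cells$dose_pM, ts$cells$dose_pM)

  # negative ratio: error names the cell and row
  df <- read.csv(f)
  bad_cell <- df$cell_id[1]
  df$ratio[3] <- -1
  g <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, g, row.names = FALSE)
  expect_error(read_trajectories(g), bad_cell)

  # missing value at a division frame is interpolated and flagged
  df2 <- read.csv(f)
  div_rows <- which(df2$division_flag == 1)
  if (length(div_rows) > 0) {
    df2$ratio[div_rows[1]] <- NA
    h <- withr::local_tempfile(fileext = ".csv")
    write.csv(df2, h, row.names = FALSE)
    got <- read_trajectories(h)
    rep_cells <- attr(got, "load_report")$interpolated_cells
    expect_equal(rep_cells, df2$cell_id[div_rows[1]])
    cell <- df2$cell_id[div_rows[1]]
    t_at <- df2$time_min[div_rows[1]]
    k <- which(got$time == t_at)
    mid <- (got$ratio[cell, k - 1] + got$ratio[cell, k + 1]) / 2
    expect_equal(unname(got$ratio[cell, k]), unname(mid))
  }

  # missing required column
  df3 <- read.csv(f)[, c("cell_id", "time_min")]
  j <- withr::local_tempfile(fileext = ".csv")
  write.csv(df3, j, row.names = FALSE)
  expect_error(read_trajectories(j), "ratio")
})

test_that("dissimilarity and class-model writers round-trip", {
  ts <- two_group_set()
  D <- dissimilarity_matrix(ts)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dissimilarity(D, f)
  D2 <- read_dissimilarity(f)
  expect_equal(unname(D2), unname(D), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(rownames(D2), rownames(D))

  cm <- hierarchical_classes(D, 2, ts)
  lf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  write_class_model(cm, lf, mf)
  lab <- read.csv(lf)
  expect_equal(lab$class, unname(cm$labels))
  med <- read.csv(mf)
  expect_equal(med$time_min, cm$time)

  man <- withr::local_tempfile(fileext = ".json")
  write_manifest("cluster", list(k = 2, seed = 1), "in.csv",
                 c(lf, mf), man)
  parsed <- jsonlite::read_json(man)
  expect_equal(parsed$command, "cluster")
  expect_equal(parsed$config$k, 2L)
})
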