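test_that("cDTW equals the exhaustive admissible-path minimum on short
           series", {
  set.seed(42)
  for (trial in 1:120) {
    n <- sample(2:8, 1)
    m <- sample(2:8, 1)
    mr <- sample(0:3, 1)
    x <- round(runif(n), 3)
    y <- round(runif(m), 3)
    o <- brute_force_cdtw(x, y, mr)
    d <- suppressWarnings(
      cdtw_distance(x, y, cdtw_config(max_run = mr, normalize = FALSE)))
    if (is.infinite(o$cost)) {
      expect_true(is.infinite(d))
    } else {
      expect_equal(d, o$cost, tolerance = 1e-12)
      dn <- cdtw_distance(x, y, cdtw_config(max_run = mr,
                                            normalize = TRUE))
      expect_equal(dn, o$cost / o$len, tolerance = 1e-12)
    }
  }
})

test_that("cDTW basic identities hold", {
  set.seed(3)
  x <- runif(30)
  y <- runif(30)
  expect_equal(cdtw_distance(x, x), 0)
  # max_run 0 on equal lengths forces the diagonal: mean pointwise |x - y|
  expect_equal(cdtw_distance(x, y, cdtw_config(max_run = 0)),
               mean(abs(x - y)))
  # symmetric step pattern
  expect_equal(cdtw_distance(x, y), cdtw_distance(y, x))
  # relaxing the constraint never increases the distance
  for (i in 1:20) {
    a <- runif(sample(10:25, 1))
    b <- runif(sample(10:25, 1))
    d_tight <- suppressWarnings(
      cdtw_distance(a, b, cdtw_config(max_run = 2, normalize = FALSE)))
    d_loose <- suppressWarnings(
      cdtw_distance(a, b, cdtw_config(max_run = 6, normalize = FALSE)))
    expect_lte(d_loose, d_tight + 1e-12)
  }
  # infinity sentinel when the constraint admits no path
  expect_warning(
    d <- cdtw_distance(c(1, 2), runif(9), cdtw_config(max_run = 1)),
    "admissible")
  expect_true(is.infinite(d))
})

test_that("cDTW absorbs a 3-frame temporal shift better than the pointwise
           distance", {
  t_idx <- 1:60
  pulse <- exp(-(t_idx - 20)^2 / 18)
  shifted <- exp(-(t_idx - 23)^2 / 18)
  d_cdtw <- cdtw_distance(pulse, shifted, cdtw_config(max_run = 4))
  d_point <- mean(abs(pulse - shifted))
  expect_lt(d_cdtw, d_point)
})

test_that("dissimilarity matrices are consistent with pairwise calls and
           permutation-equivariant", {
  ts <- two_group_set()
  D <- dissimilarity_matrix(ts)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
  cfg <- cdtw_config()
  for (pair in list(c(1, 2), c(1, 8), c(4, 9)))
    expect_equal(D[pair[1], pair[2]],
                 cdtw_distance(ts$ratio[pair[1], ], ts$ratio[pair[2], ],
                               cfg))
  perm <- c(3, 1, 2, 7, 10, 4, 5, 9, 8, 6)
  D2 <- dissimilarity_matrix(ts[perm])
  expect_equal(unname(D2), unname(D[perm, perm]), ignore_attr = TRUE)
  # duplicated trajectory gives a zero off-diagonal entry
  ts2 <- ts[c(1, 1, 5)]
  D3 <- dissimilarity_matrix(ts2)
  expect_equal(D3[1, 2], 0)
})

test_that("hierarchical classes separate two groups and order classes by
           late-phase level", {
  ts <- two_group_set()
  D <- dissimilarity_matrix(ts)
  cm <- hierarchical_classes(D, 2, ts)
  expect_equal(unname(cm$labels), ts$cells$group)
  # class 1 must be the weaker late responder
  expect_lt(mean(cm$medians[1, ts$time >= 300]),
            mean(cm$medians[2, ts$time >= 300]))
  # k = n: every class a singleton equal to its member
  cm_n <- hierarchical_classes(D, n_cells(ts), ts)
  expect_equal(sort(unname(table(cm_n$labels))), rep(1L, n_cells(ts)),
               ignore_attr = TRUE)
  one <- names(cm_n$labels)[cm_n$labels == 3]
  expect_equal(unname(cm_n$medians[3, ]), unname(ts$ratio[one, ]))
  expect_error(hierarchical_classes(D, n_cells(ts) + 1, ts), "exceed")
})

test_that("jump statistic peaks at the true cluster number on separated
           data", {
  # 3 tight clusters with separation >= 10x the within spread
  set.seed(9)
  centers <- c(0, 5, 11)
  series <- lapply(rep(centers, each = 6), function(cc)
    cc + 0.05 * runif(40))
  D <- dissimilarity_matrix(series)
  js <- jump_statistic(D, 2:8)
  expect_equal(js$k[which.max(js$J)], 3)
  expect_true(3 %in% attr(js, "candidates"))
  # identical trajectories: degenerate dispersion is flagged
  same <- lapply(1:5, function(i) rep(1, 20))
  Ds <- dissimilarity_matrix(same)
  js2 <- jump_statistic(Ds, 2:3)
  expect_true(attr(js2, "degenerate"))
})

test_that("silhouette scores match hand-computed values and edge rules", {
  # 5-point hand dissimilarity, groups {1,2} and {3,4,5}
  D <- matrix(c(
    0, 1, 8, 9, 10,
    1, 0, 7, 8, 9,
    8, 7, 0, 2, 2,
    9, 8, 2, 0, 2,
    10, 9, 2, 2, 0), 5, 5, byrow = TRUE)
  lab <- c(1, 1, 2, 2, 2)
  s <- silhouette_scores(D, lab)
  a1 <- 1; b1 <- mean(c(8, 9, 10))
  expect_equal(unname(s[1]), (b1 - a1) / max(a1, b1))
  a3 <- mean(c(2, 2)); b3 <- mean(c(8, 7))
  expect_equal(unname(s[3]), (b3 - a3) / max(a3, b3))
  # equidistant point scores zero
  De <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3)
  expect_equal(unname(silhouette_scores(De, c(1, 1, 2))[3]), 0)
  # singleton group member scores 0 and is flagged
  s2 <- silhouette_scores(D, c(1, 2, 2, 2, 3))
  expect_equal(unname(s2[5]), 0)
  expect_length(attr(s2, "singletons"), 2)
  # two tight far groups: all scores near 1
  ts <- two_group_set()
  Dg <- dissimilarity_matrix(ts)
  expect_true(all(silhouette_scores(Dg, ts$cells$group) > 0.9))
})

test_that("class mapping recovers its own references and proportions", {
  ts <- two_group_set()
  D <- dissimilarity_matrix(ts)
  cm <- hierarchical_classes(D, 2, ts)
  # a class median maps to its own class (median mode)
  expect_equal(unname(map_to_classes(cm$medians, cm$time, cm)), c(1, 2))
  # a stored member maps to its own class (nearest-neighbor mode)
  got <- map_to_classes(ts$ratio[7, ], ts$time, cm, mode = "nearest",
                        member_ratio = ts$ratio)
  expect_equal(got, unname(cm$labels[7]))
  # known mixture proportions are reproduced within multinomial error
  set.seed(4)
  n <- 300
  pick <- sample(1:2, n, replace = TRUE, prob = c(0.3, 0.7))
  noisy <- cm$medians[pick, ] * matrix(exp(rnorm(n * length(cm$time),
                                                 0, 0.01)),
                                       n)
  mapped <- unname(map_to_classes(noisy, cm$time, cm))
  expect_lt(abs(mean(mapped == 1) - 0.3), 0.08)
  expect_equal(mapped, pick)
})
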