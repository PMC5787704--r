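#' Local cell-density scores
#'
#' Weighted sum of all neighbors within `radius` of each cell, with a
#' bell-shaped (Gaussian) kernel: score(c) = sum over neighbors within the
#' radius of exp(-d^2 / (2 w^2)), self excluded. Translation- and
#' rotation-invariant in the positions.
#'
#' @param x,y cell positions (pixels or micrometers; default radius of
#'   200 px corresponds to 640 um at the reference magnification).
#' @param radius neighborhood radius (same unit as positions).
#' @param kernel_width Gaussian kernel width w; default radius/3.
#' @return numeric vector of per-cell density scores.
#' @export
density_score <- function(x, y, radius = 200, kernel_width = radius / 3) {
  stopifnot(length(x) == length(y), radius > 0, kernel_width > 0)
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- exp(-d^2 / (2 * kernel_width^2))
  w[d > radius] <- 0
  diag(w) <- 0
  stats::setNames(as.numeric(rowSums(w)), names(x))
}

.equal_freq_bins <- function(v, bins) {
  br <- stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 8)
  br <- unique(br)
  if (length(br) < 2) stop("variable has no spread")
  br[1] <- -Inf
  br[length(br)] <- Inf
  cut(v, br, labels = FALSE, include.lowest = TRUE)
}

.entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual-information fraction between a covariate and the SMAD ratio
#'
#' Both variables are discretized by equal-frequency binning; the plug-in
#' mutual information is normalized by the sum of the marginal entropies,
#' MI / (H(X) + H(Y)), giving the fraction of signaling heterogeneity
#' explainable by the covariate. The fraction lies in [0, 0.5]; identical
#' variables attain 0.5, independent variables approach 0 (up to plug-in
#' estimator bias at finite n).
#'
#' @param x covariate values (e.g. time since last division, density
#'   score).
#' @param y per-cell nuc/cyt ratio values at one time point.
#' @param bins number of equal-frequency bins per variable (default 8).
#' @return the mutual-information fraction (dimensionless).
#' @export
mutual_information_fraction <- function(x, y, bins = 8) {
  stopifnot(length(x) == length(y))
  if (length(x) < bins) stop("fewer samples than bins")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("need at least 2 distinct values per variable")
  bx <- .equal_freq_bins(x, bins)
  by <- .equal_freq_bins(y, bins)
  joint <- table(bx, by)
  hx <- .entropy(table(bx))
  hy <- .entropy(table(by))
  hxy <- .entropy(joint)
  mi <- hx + hy - hxy
  mi / (hx + hy)
}

#' Mutual-information fraction over all pairs of time points
#'
#' The pairwise-over-time variant used for density covariates: entry (i, j)
#' is the MI fraction between covariate at time i and ratio at time j.
#'
#' @param x_mat cells x time matrix of covariate values.
#' @param y_mat cells x time matrix of ratio values.
#' @param bins equal-frequency bins per variable.
#' @return matrix of MI fractions, `ncol(x_mat)` x `ncol(y_mat)`.
#' @export
mutual_information_grid <- function(x_mat, y_mat, bins = 8) {
  stopifnot(nrow(x_mat) == nrow(y_mat))
  out <- matrix(NA_real_, ncol(x_mat), ncol(y_mat))
  for (i in seq_len(ncol(x_mat)))
    for (j in seq_len(ncol(y_mat)))
      out[i, j] <- mutual_information_fraction(x_mat[, i], y_mat[, j],
                                               bins)
  out
}

# identify sister pairs: cells sharing an identical division time
# (backward-tracked sister tracks are duplicated before division)
.sister_pairs <- function(ts) {
  div <- ts$divisions
  if (is.null(div) || nrow(div) == 0) stop("no division events")
  sp <- list()
  for (t0 in unique(div$time)) {
    ids <- unique(div$cell_id[div$time == t0])
    if (length(ids) < 2) next
    # pair cells whose tracks agree exactly before the division frame
    pre <- which(ts$time < t0)
    if (length(pre) == 0) next
    remaining <- ids
    while (length(remaining) >= 2) {
      a <- remaining[1]
      rest <- remaining[-1]
      same <- vapply(rest, function(b)
        isTRUE(all.equal(ts$ratio[a, pre], ts$ratio[b, pre],
                         check.attributes = FALSE, tolerance = 1e-12)),
        logical(1))
      if (any(same)) {
        b <- rest[which(same)[1]]
        sp[[length(sp) + 1]] <- list(a = a, b = b, t0 = t0)
        remaining <- setdiff(remaining, c(a, b))
      } else remaining <- rest
    }
  }
  if (length(sp) == 0) stop("no sister pairs found")
  sp
}

#' Sister-cell divergence after division
#'
#' Quantifies how quickly sister cells diverge: cDTW distances of paired
#' SMAD2 time courses are computed in a sliding window after the division
#' (sister pairs) or after an anchor time at which two unrelated cells
#' happened to have matching nuc/cyt ratios (control pairs). Both are
#' normalized per window by the mean cDTW distance of random cell pairs.
#' The effect size is the control-normalized minus the sister-normalized
#' score per time since alignment; its 95% CI comes from bootstrapping over
#' pairs.
#'
#' @param ts a [trajectory_set()] with division events.
#' @param window sliding window length (min), default 120.
#' @param step window step (min), default one frame (5 min).
#' @param n_boot bootstrap replicates for the CI, default 200.
#' @param seed integer seed for control-pair and random-pair sampling.
#' @param boot_seed separate seed for the bootstrap resampling (default
#'   `seed + 1`); changing it alters only the confidence intervals, never
#'   the point effect sizes.
#' @param control_tol relative tolerance for ratio matching of control
#'   pairs, default 2%; doubled (with a warning) while fewer than
#'   `min_controls` control pairs are found.
#' @param n_random random pairs per window for normalization.
#' @param max_offset largest time-since-alignment evaluated (min).
#' @param cfg [cdtw_config()] used for the window distances.
#' @param min_controls minimum acceptable number of control pairs.
#' @return object of class `pair_divergence`: data.frame with
#'   `offset_min`, `effect`, `lo`, `hi`, `n_sister`, `n_control`.
#' @export
sister_divergence <- function(ts, window = 120, step = 5, n_boot = 200,
                              seed = 1L, boot_seed = seed + 1,
                              control_tol = 0.02,
                              n_random = 1000, max_offset = 600,
                              cfg = cdtw_config(), min_controls = 20) {
  stopifnot(window >= 2 * (ts$time[2] - ts$time[1]))
  pairs <- .sister_pairs(ts)
  dt <- ts$time[2] - ts$time[1]
  nt <- length(ts$time)
  ids <- rownames(ts$ratio)
  n <- length(ids)
  win_frames <- round(window / dt)
  offsets <- seq(0, max_offset, by = step)

  withr::with_seed(seed, {
    # control pairs: unrelated cells with matching ratio at an anchor
    # time, anchors spread uniformly over post-stimulus frames that leave
    # room for at least one window
    post <- which(ts$time > 0 & ts$time <= max(ts$time) - window)
    controls <- list()
    tol <- control_tol
    tries <- 0
    while (length(controls) < min_controls && tries < 4) {
      if (tries > 0) {
        tol <- tol * 2
        warning("widening control matching tolerance to ", tol)
      }
      controls <- list()
      for (f in sample(post, min(length(post), 60))) {
        v <- ts$ratio[, f]
        ord <- order(v)
        found <- 0
        for (q in sample(seq_len(n - 1))) {
          a <- ord[q]; b <- ord[q + 1]
          if (abs(v[a] - v[b]) <= tol * abs(v[a])) {
            sis_a <- ts$cells$sister_of[match(ids[a], ts$cells$cell_id)]
            sis_b <- ts$cells$sister_of[match(ids[b], ts$cells$cell_id)]
            unrelated <- !(identical(sis_a, ids[b]) ||
                             identical(sis_b, ids[a]))
            if (unrelated) {
              controls[[length(controls) + 1]] <-
                list(a = ids[a], b = ids[b], t0 = ts$time[f])
              found <- found + 1
              if (found >= 5) break   # cap per anchor frame
            }
          }
        }
        if (length(controls) >= 8 * min_controls) break
      }
      tries <- tries + 1
    }
    if (length(controls) < 2) stop("too few control pairs")

    pair_scores <- function(plist) {
      # matrix: pairs x offsets of cDTW in the window centered `offset`
      # minutes after the pair's alignment time (division or anchor);
      # windows reaching outside the track are skipped
      half <- win_frames %/% 2
      t(vapply(plist, function(p) {
        k0 <- which.min(abs(ts$time - p$t0))
        vapply(offsets, function(off) {
          i1 <- k0 + round(off / dt) - half
          i2 <- i1 + win_frames
          if (i1 < 1 || i2 > nt) return(NA_real_)
          cdtw_distance(ts$ratio[p$a, i1:i2], ts$ratio[p$b, i1:i2], cfg)
        }, numeric(1))
      }, numeric(length(offsets))))
    }

    rnd_idx <- cbind(sample.int(n, n_random, replace = TRUE),
                     sample.int(n, n_random, replace = TRUE))
    rnd_idx <- rnd_idx[rnd_idx[, 1] != rnd_idx[, 2], , drop = FALSE]
    rnd_t0 <- sample(ts$time[post], nrow(rnd_idx), replace = TRUE)
    random_pairs <- lapply(seq_len(nrow(rnd_idx)), function(i)
      list(a = ids[rnd_idx[i, 1]], b = ids[rnd_idx[i, 2]],
           t0 = rnd_t0[i]))

    S <- pair_scores(pairs)
    C <- pair_scores(controls)
    R <- pair_scores(random_pairs)
    rnorm_off <- colMeans(R, na.rm = TRUE)

    eff <- function(si, ci) {
      s <- colMeans(S[si, , drop = FALSE], na.rm = TRUE) / rnorm_off
      c <- colMeans(C[ci, , drop = FALSE], na.rm = TRUE) / rnorm_off
      c - s
    }
    point <- eff(seq_len(nrow(S)), seq_len(nrow(C)))
    boot <- withr::with_seed(boot_seed, replicate(n_boot, eff(
      sample.int(nrow(S), replace = TRUE),
      sample.int(nrow(C), replace = TRUE))))
    lo <- apply(boot, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(boot, 1, stats::quantile, probs = 0.975, na.rm = TRUE)

    out <- data.frame(offset_min = offsets, effect = point,
                      lo = lo, hi = hi,
                      n_sister = colSums(!is.na(S)),
                      n_control = colSums(!is.na(C)))
    keep <- out$n_sister > 0 & out$n_control > 0
    structure(out[keep, ], class = c("pair_divergence", "data.frame"),
              n_random = nrow(rnd_idx))
  })
}
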