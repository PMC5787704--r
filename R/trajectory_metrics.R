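#' Construct a set of single-cell trajectories
#'
#' The universal currency of the pipeline: per-cell nuc/cyt SMAD ratio time
#' courses on a shared uniform time grid, with optional division times and
#' spatial positions.
#'
#' @param time numeric vector of frame times (min), strictly increasing and
#'   uniformly spaced (default frame interval 5 min).
#' @param ratio numeric matrix, one row per cell, one column per frame;
#'   rownames are cell ids. All values finite and > 0.
#' @param cells data.frame with one row per cell; must contain `cell_id`
#'   matching the rownames of `ratio` and a `dose_pM` column; further
#'   columns (true class, pool multipliers, lineage) are carried along.
#' @param divisions optional data.frame (`cell_id`, `time`) of division
#'   events, times within the grid range.
#' @param positions optional data.frame (`cell_id`, `x`, `y`) of cell
#'   positions (pixels) at the stimulus frame.
#' @return object of class `trajectory_set`.
#' @export
trajectory_set <- function(time, ratio, cells, divisions = NULL,
                           positions = NULL) {
  stopifnot(is.numeric(time), is.matrix(ratio),
            ncol(ratio) == length(time))
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-8 * max(abs(dt)))
      stop("time grid must be uniformly spaced")
  }
  if (!all(is.finite(ratio)) || any(ratio <= 0))
    stop("ratio values must be finite and > 0")
  stopifnot(is.data.frame(cells), "cell_id" %in% names(cells))
  if (!"dose_pM" %in% names(cells)) cells$dose_pM <- NA_real_
  if (is.null(rownames(ratio))) rownames(ratio) <- cells$cell_id
  if (!identical(as.character(cells$cell_id), rownames(ratio)))
    stop("cells$cell_id must match rownames(ratio)")
  if (!is.null(divisions)) {
    stopifnot(all(c("cell_id", "time") %in% names(divisions)))
    if (nrow(divisions) > 0 &&
        (min(divisions$time) < time[1] || max(divisions$time) > max(time)))
      stop("division times must lie within the time grid")
  }
  structure(list(time = time, ratio = ratio, cells = cells,
                 divisions = divisions, positions = positions),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("trajectory_set:", nrow(x$ratio), "cells x", length(x$time),
      "frames (", x$time[1], "-", max(x$time), "min )\n")
  if (!is.null(x$divisions))
    cat(" ", nrow(x$divisions), "division events\n")
  invisible(x)
}

#' Number of cells in a trajectory set
#' @param ts a [trajectory_set()].
#' @export
n_cells <- function(ts) nrow(ts$ratio)

#' Subset a trajectory set by cell index or id
#' @param x a [trajectory_set()].
#' @param i integer, logical or character index over cells.
#' @param ... unused.
#' @export
`[.trajectory_set` <- function(x, i, ...) {
  ids <- rownames(x$ratio)[if (is.character(i)) match(i, rownames(x$ratio))
                           else i]
  div <- if (!is.null(x$divisions))
    x$divisions[x$divisions$cell_id %in% ids, , drop = FALSE]
  pos <- if (!is.null(x$positions))
    x$positions[x$positions$cell_id %in% ids, , drop = FALSE]
  trajectory_set(x$time, x$ratio[ids, , drop = FALSE],
                 x$cells[match(ids, x$cells$cell_id), , drop = FALSE],
                 div, pos)
}

#' cDTW configuration
#'
#' @param max_run maximum number of consecutive warp steps in the same
#'   non-diagonal direction (the elastic constraint); default 6 frames
#'   (30 min at the standard 5-min frame interval). 0 forces the diagonal
#'   path.
#' @param band optional Sakoe-Chiba global band half-width in frames
#'   (`NULL` = no band).
#' @param exponent local cost exponent: 1 = absolute difference (default),
#'   2 = squared.
#' @param normalize divide the optimal path cost by its path length
#'   (default TRUE), making distances comparable across series lengths.
#' @return object of class `cdtw_config`.
#' @export
cdtw_config <- function(max_run = 6, band = NULL, exponent = 1,
                        normalize = TRUE) {
  stopifnot(max_run >= 0, is.null(band) || band >= 0, exponent > 0)
  structure(list(max_run = as.integer(max_run),
                 band = if (is.null(band)) -1L else as.integer(band),
                 exponent = exponent, normalize = isTRUE(normalize)),
            class = "cdtw_config")
}

#' Constrained dynamic time warping distance between two series
#'
#' Optimal warp-path cost under the elastic constraint that at most
#' `max_run` consecutive steps may stretch the same series; symmetric by
#' construction. Raw nuc/cyt ratios are compared (no z-scoring), so
#' amplitude differences are preserved.
#'
#' @param x,y numeric vectors (trajectory values on uniform grids).
#' @param cfg a [cdtw_config()].
#' @return non-negative distance; `Inf` (with a warning) if no admissible
#'   warp path exists under the constraint.
#' @export
cdtw_distance <- function(x, y, cfg = cdtw_config()) {
  stopifnot(length(x) > 0, length(y) > 0)
  d <- .Call("c_cdtw", as.numeric(x), as.numeric(y), cfg$max_run,
             cfg$band, cfg$exponent, cfg$normalize, PACKAGE = "smadtier")
  if (is.infinite(d))
    warning("no admissible warp path under the elastic constraint")
  d
}

#' Pairwise cDTW dissimilarity matrix
#'
#' @param ts a [trajectory_set()] (or list of numeric vectors).
#' @param cfg a [cdtw_config()].
#' @return symmetric matrix with zero diagonal, dimnames = cell ids. The
#'   number of inadmissible (infinite) pairs is recorded in attribute
#'   `n_infinite`.
#' @export
dissimilarity_matrix <- function(ts, cfg = cdtw_config()) {
  if (inherits(ts, "trajectory_set")) {
    series <- lapply(seq_len(nrow(ts$ratio)),
                     function(i) as.numeric(ts$ratio[i, ]))
    ids <- rownames(ts$ratio)
  } else {
    series <- lapply(ts, as.numeric)
    ids <- names(ts) %||% as.character(seq_along(ts))
  }
  if (length(series) < 2) stop("need at least 2 trajectories")
  D <- .Call("c_cdtw_matrix", series, cfg$max_run, cfg$band,
             cfg$exponent, cfg$normalize, PACKAGE = "smadtier")
  dimnames(D) <- list(ids, ids)
  n_inf <- sum(is.infinite(D)) / 2
  if (n_inf > 0)
    warning(n_inf, " pairs had no admissible warp path")
  attr(D, "n_infinite") <- n_inf
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hierarchical clustering of trajectories into signaling classes
#'
#' Agglomerative clustering (average linkage by default) on a cDTW
#' dissimilarity matrix. Classes are renumbered by ascending mean late-phase
#' (>= `late_min` min) median level, so class 1 is the weakest responder and
#' class k the strongest.
#'
#' @param D dissimilarity matrix from [dissimilarity_matrix()].
#' @param k number of classes (1 <= k <= number of cells).
#' @param ts the [trajectory_set()] the matrix was computed from (used for
#'   class medians).
#' @param linkage hclust agglomeration method, default `"average"`.
#' @param late_min start of the late signaling phase used for renumbering
#'   (min), default 300.
#' @return object of class `class_model`: list with `k`, `labels` (named
#'   integer vector in 1..k), `medians` (k x frames matrix), `time`,
#'   `linkage` (the hclust tree), `members` (per-class cell ids).
#' @export
hierarchical_classes <- function(D, k, ts, linkage = "average",
                                 late_min = 300) {
  n <- nrow(D)
  if (k > n) stop("k must not exceed the number of cells")
  if (any(!is.finite(D))) stop("dissimilarity matrix has non-finite entries")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  raw <- stats::cutree(hc, k = k)
  med <- t(vapply(seq_len(k), function(g)
    apply(ts$ratio[raw == g, , drop = FALSE], 2, stats::median),
    numeric(length(ts$time))))
  late <- ts$time >= late_min
  if (!any(late)) late <- rep(TRUE, length(ts$time))
  ord <- order(rowMeans(med[, late, drop = FALSE]))
  relabel <- match(seq_len(k), ord)       # old label -> new label
  labels <- relabel[raw]
  names(labels) <- rownames(D)
  med <- med[ord, , drop = FALSE]
  rownames(med) <- paste0("class", seq_len(k))
  structure(list(k = k, labels = labels, medians = med, time = ts$time,
                 linkage = hc,
                 members = split(names(labels), labels)),
            class = "class_model")
}

#' Jump statistic for choosing the number of clusters
#'
#' Within-cluster dispersion W(k) is the sum over clusters of the mean
#' squared cDTW dissimilarity to the cluster medoid; the transformed
#' dispersion d(k) = W(k)^(-p) is differenced to give the jump
#' J(k) = d(k) - d(k-1) (with d(0) = 0). Candidate cluster numbers are the
#' local maxima of J.
#'
#' @param D dissimilarity matrix.
#' @param k_range integer vector of cluster numbers to score.
#' @param p transform power, default 1.
#' @param linkage hclust method used to produce the candidate partitions.
#' @return data.frame with columns `k`, `W`, `d`, `J`, plus attribute
#'   `candidates` (local maxima of J over `k_range`) and `degenerate`
#'   (TRUE if any W(k) = 0 made the transform undefined).
#' @export
jump_statistic <- function(D, k_range, p = 1, linkage = "average") {
  if (any(!is.finite(D))) stop("dissimilarity matrix has non-finite entries")
  n <- nrow(D)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) >= 1, max(k_range) <= n - 1)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  ks <- sort(unique(c(k_range, k_range - 1)))
  ks <- ks[ks >= 1]
  Wk <- vapply(ks, function(k) {
    lab <- stats::cutree(hc, k = k)
    sum(vapply(split(seq_len(n), lab), function(idx) {
      sub <- D[idx, idx, drop = FALSE]
      medoid <- idx[which.min(colSums(sub^2))]
      mean(D[idx, medoid]^2)
    }, numeric(1)))
  }, numeric(1))
  names(Wk) <- ks
  degenerate <- any(Wk[as.character(k_range)] == 0)
  dk <- ifelse(Wk > 0, Wk^(-p), NA_real_)
  dfun <- function(k) if (k == 0) 0 else unname(dk[as.character(k)])
  J <- vapply(k_range, function(k) dfun(k) - dfun(k - 1), numeric(1))
  out <- data.frame(k = k_range, W = unname(Wk[as.character(k_range)]),
                    d = unname(dk[as.character(k_range)]), J = J)
  finite_J <- ifelse(is.na(J), -Inf, J)
  is_max <- vapply(seq_along(k_range), function(i) {
    left <- if (i == 1) -Inf else finite_J[i - 1]
    right <- if (i == length(k_range)) -Inf else finite_J[i + 1]
    finite_J[i] > left && finite_J[i] >= right
  }, logical(1))
  attr(out, "candidates") <- k_range[is_max]
  attr(out, "degenerate") <- degenerate
  out
}

#' Silhouette scores on a cDTW dissimilarity
#'
#' Standard silhouette s = (b - a) / max(a, b), where a is the mean
#' dissimilarity to the cell's own group and b the smallest mean
#' dissimilarity to any other group. Grouping may be by signaling class or
#' by stimulus dose. Members of singleton groups score 0 (flagged).
#'
#' @param D dissimilarity matrix.
#' @param labels group label per cell (class id or dose), length nrow(D).
#' @return numeric vector of per-cell scores; attribute `singletons` lists
#'   cells in singleton groups.
#' @export
silhouette_scores <- function(D, labels) {
  stopifnot(length(labels) == nrow(D))
  labels <- as.character(labels)
  groups <- split(seq_along(labels), labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  s <- numeric(length(labels))
  singles <- character(0)
  for (i in seq_along(labels)) {
    own <- setdiff(groups[[labels[i]]], i)
    if (length(own) == 0) {
      s[i] <- 0
      singles <- c(singles, rownames(D)[i] %||% as.character(i))
      next
    }
    a <- mean(D[i, own])
    b <- min(vapply(groups[names(groups) != labels[i]],
                    function(idx) mean(D[i, idx]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- rownames(D)
  attr(s, "singletons") <- singles
  s
}

#' Map a trajectory onto previously defined signaling classes
#'
#' Assigns a trajectory to the class whose median time course (median mode,
#' default) or whose nearest member trajectory (nearest-neighbor mode) is
#' closest in Euclidean distance. The trajectory is linearly resampled to
#' the class-model grid first. Ties break toward the lower class id.
#'
#' @param ratio numeric vector (one trajectory) or matrix (cells x frames).
#' @param time time grid of `ratio` (min).
#' @param classes a `class_model` from [hierarchical_classes()] (or a list
#'   with `medians` and `time`).
#' @param mode `"median"` or `"nearest"`; nearest-neighbor mode requires
#'   `member_ratio`.
#' @param member_ratio matrix of stored member trajectories (rows named as
#'   in `classes$labels`) for nearest-neighbor mode.
#' @return integer vector of class ids.
#' @export
map_to_classes <- function(ratio, time, classes,
                           mode = c("median", "nearest"),
                           member_ratio = NULL) {
  mode <- match.arg(mode)
  if (is.vector(ratio)) ratio <- matrix(ratio, nrow = 1)
  grid <- classes$time
  if (min(time) > min(grid) || max(time) < max(grid))
    stop("trajectory does not cover the class-median grid")
  res <- t(apply(ratio, 1, function(v)
    stats::approx(time, v, xout = grid)$y))
  if (mode == "median") {
    ref <- classes$medians
    ref_class <- seq_len(nrow(ref))
  } else {
    if (is.null(member_ratio))
      stop("nearest-neighbor mode needs member_ratio")
    ref <- member_ratio
    ref_class <- as.integer(classes$labels[rownames(member_ratio)])
    if (anyNA(ref_class)) stop("member_ratio rows not found in class labels")
  }
  apply(res, 1, function(v) {
    d2 <- colSums((t(ref) - v)^2)
    ref_class[which.min(d2 + ref_class * 1e-12)]  # ties -> lower class id
  })
}

#' Thin a trajectory set to a coarser frame grid
#'
#' Keeps every `every`-th frame (e.g. 3 turns the standard 5-min grid into
#' a 15-min grid). Pairwise cDTW cost is quadratic in the frame count, so
#' large-population dissimilarity matrices are routinely computed on a
#' thinned grid with the elastic constraint rescaled to the same number of
#' minutes (e.g. max_run 6 at 5 min = max_run 2 at 15 min).
#'
#' @param ts a [trajectory_set()].
#' @param every keep every `every`-th frame (integer >= 1).
#' @export
thin_trajectories <- function(ts, every) {
  stopifnot(every >= 1)
  keep <- seq(1, length(ts$time), by = every)
  trajectory_set(ts$time[keep], ts$ratio[, keep, drop = FALSE], ts$cells,
                 ts$divisions, ts$positions)
}
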