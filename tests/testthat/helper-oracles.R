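# exhaustive warp-path enumeration: the independent oracle for cDTW on
# short series (<= 8 points). Tracks the minimal total cost and, among
# minimal-cost paths, the shortest path length (for normalization).
brute_force_cdtw <- function(x, y, max_run, exponent = 1) {
  n <- length(x)
  m <- length(y)
  best <- Inf
  best_len <- NA_integer_
  rec <- function(i, j, dir, run, cost, len) {
    cost <- cost + abs(x[i] - y[j])^exponent
    if (i == n && j == m) {
      if (cost < best || (cost == best && len < best_len)) {
        best <<- cost
        best_len <<- len
      }
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, 0L, 0L, cost, len + 1)
    if (max_run > 0) {
      if (i < n && (dir != 1L || run < max_run))
        rec(i + 1, j, 1L, if (dir == 1L) run + 1L else 1L, cost, len + 1)
      if (j < m && (dir != 2L || run < max_run))
        rec(i, j + 1, 2L, if (dir == 2L) run + 1L else 1L, cost, len + 1)
    }
  }
  rec(1, 1, 0L, 0L, 0, 1L)
  list(cost = best, len = best_len)
}

# tiny deterministic trajectory set: two well-separated shape groups
two_group_set <- function(n_per = 5, horizon = 600, by = 10) {
  time <- seq(0, horizon, by = by)
  flat <- 0.8 + 0 * time
  high <- 0.8 + 1.5 * (time / 60) * exp(1 - time / 60) + 0.6 * (time > 150)
  ratio <- rbind(
    t(sapply(seq_len(n_per), function(i) flat * (1 + 0.01 * i))),
    t(sapply(seq_len(n_per), function(i) high * (1 + 0.01 * i))))
  ids <- sprintf("g%d_%d", rep(1:2, each = n_per), rep(seq_len(n_per), 2))
  rownames(ratio) <- ids
  trajectory_set(time, ratio,
                 data.frame(cell_id = ids,
                            dose_pM = rep(c(5, 100), each = n_per),
                            group = rep(1:2, each = n_per)))
}
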