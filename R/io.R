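#' Write a trajectory set to the standard long-form CSV
#'
#' Columns: `cell_id`, `time_min`, `ratio`, `x`, `y`, `division_flag`,
#' `dose_pM`. Positions are per cell (repeated on every row); the division
#' flag marks frames at which a division occurred. Values are written with
#' 17 significant digits so a write-then-read round trip is value-exact.
#'
#' @param ts a [trajectory_set()].
#' @param path output CSV path.
#' @export
write_trajectories <- function(ts, path) {
  ids <- rownames(ts$ratio)
  nt <- length(ts$time)
  pos <- ts$positions
  div <- ts$divisions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("cell_id,time_min,ratio,x,y,division_flag,dose_pM", con)
  for (i in seq_along(ids)) {
    id <- ids[i]
    xy <- if (!is.null(pos) && id %in% pos$cell_id)
      as.numeric(pos[match(id, pos$cell_id), c("x", "y")])
    else c(NA_real_, NA_real_)
    dflag <- rep(0L, nt)
    if (!is.null(div)) {
      dt <- div$time[div$cell_id == id]
      dflag[ts$time %in% dt] <- 1L
    }
    dose <- ts$cells$dose_pM[match(id, ts$cells$cell_id)]
    writeLines(sprintf("%s,%.10g,%.17g,%s,%s,%d,%.10g",
                       id, ts$time, ts$ratio[i, ],
                       ifelse(is.na(xy[1]), "", sprintf("%.10g", xy[1])),
                       ifelse(is.na(xy[2]), "", sprintf("%.10g", xy[2])),
                       dflag, dose), con)
  }
  invisible(path)
}

#' Read a trajectory set from the standard long-form CSV
#'
#' Validates the uniform time grid and positive ratios; missing ratio
#' values at division frames (nuclear envelope breakdown prevents a
#' meaningful measurement there) are filled by linear interpolation and
#' flagged in the load report (attribute `load_report`).
#'
#' @param path CSV with required columns `cell_id`, `time_min`, `ratio`
#'   and optional `x`, `y`, `division_flag`, `dose_pM`.
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "ratio")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing required columns: ",
         paste(missing_cols, collapse = ", "))
  ids <- unique(df$cell_id)
  time <- sort(unique(df$time_min))
  if (length(time) > 1) {
    dt <- diff(time)
    if (max(dt) - min(dt) > 1e-6 * max(dt))
      stop("non-uniform time grid")
  }
  ratio <- matrix(NA_real_, length(ids), length(time),
                  dimnames = list(ids, NULL))
  interpolated <- character(0)
  div_flag <- "division_flag" %in% names(df)
  divisions <- list()
  positions <- list()
  cells <- list()
  for (id in ids) {
    sub <- df[df$cell_id == id, ]
    sub <- sub[order(sub$time_min), ]
    if (nrow(sub) != length(time))
      stop("cell ", id, " does not cover the full time grid")
    v <- sub$ratio
    dmask <- if (div_flag) sub$division_flag == 1 else rep(FALSE, nrow(sub))
    if (any(is.na(v))) {
      if (!all(dmask[is.na(v)]))
        stop("cell ", id, ": missing ratio outside division frames (rows ",
             paste(which(is.na(v)), collapse = ","), ")")
      v <- stats::approx(time[!is.na(v)], v[!is.na(v)], xout = time,
                         rule = 2)$y
      interpolated <- c(interpolated, id)
    }
    bad <- which(v <= 0)
    if (length(bad) > 0)
      stop("cell ", id, ": non-positive ratio at row ", bad[1],
           " (t = ", time[bad[1]], " min)")
    ratio[id, ] <- v
    if (div_flag && any(dmask))
      divisions[[id]] <- data.frame(cell_id = id, time = time[dmask])
    if (all(c("x", "y") %in% names(df)) && !is.na(sub$x[1]))
      positions[[id]] <- data.frame(cell_id = id, x = sub$x[1],
                                    y = sub$y[1])
    cells[[id]] <- data.frame(
      cell_id = id,
      dose_pM = if ("dose_pM" %in% names(df)) sub$dose_pM[1] else NA_real_)
  }
  ts <- trajectory_set(
    time, ratio, do.call(rbind, cells),
    divisions = if (length(divisions) > 0) do.call(rbind, divisions),
    positions = if (length(positions) > 0) do.call(rbind, positions))
  attr(ts, "load_report") <- list(n_cells = length(ids),
                                  interpolated_cells = interpolated)
  ts
}

#' Write / read a dissimilarity matrix as square CSV with id header
#' @param D symmetric dissimilarity matrix with dimnames.
#' @param path file path.
#' @export
write_dissimilarity <- function(D, path) {
  utils::write.csv(as.data.frame(D), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write class labels and class medians of a class model
#' @param classes a `class_model` from [hierarchical_classes()].
#' @param labels_path,medians_path output CSV paths.
#' @export
write_class_model <- function(classes, labels_path, medians_path) {
  utils::write.csv(data.frame(cell_id = names(classes$labels),
                              class = as.integer(classes$labels)),
                   labels_path, row.names = FALSE)
  med <- data.frame(time_min = classes$time, t(classes$medians))
  utils::write.csv(med, medians_path, row.names = FALSE)
  invisible(labels_path)
}

#' Write a run manifest (JSON) describing one analysis run
#'
#' @param command short name of the analysis step.
#' @param config list of configuration values (seeds included).
#' @param inputs,outputs character vectors of file paths.
#' @param path manifest output path.
#' @export
write_manifest <- function(command, config, inputs, outputs, path) {
  jsonlite::write_json(list(
    command = command,
    config = config,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("smadtier")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
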