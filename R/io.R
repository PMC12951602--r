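# Flat-file interchange: track tables, boundary traces, recoil series and
# YAML scenario configurations.

#' Read and write centroid track tables
#'
#' Long CSV schema: `cell_id`, `time`, `x`, `y`, `type`, `divided`,
#' `boundary_adjacent` (coordinates in micrometres).
#'
#' @param tracks A track table data.frame.
#' @param path CSV file path.
#' @return `read_track_csv` returns the track table.
#' @export
write_track_csv <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  d <- read.csv(path)
  need <- c("cell_id", "time", "x", "y", "type")
  if (!all(need %in% names(d)))
    stop("track CSV must contain columns: ", paste(need, collapse = ", "))
  if (is.null(d$divided)) d$divided <- FALSE
  if (is.null(d$boundary_adjacent)) d$boundary_adjacent <- FALSE
  d
}

#' Read and write boundary traces
#'
#' Long CSV schema: `frame`, `time`, `point`, `x`, `y`, `side`; one row per
#' polyline point.
#'
#' @param traces Per-frame list of trace data.frames (as produced by
#'   [extract_boundaries()] or [make_boundary_series()]).
#' @param times Frame times.
#' @param path CSV file path.
#' @return `read_boundary_csv` returns `list(traces, times)` in the
#'   per-frame list format.
#' @export
write_boundary_csv <- function(traces, times, path) {
  rows <- list()
  for (fi in seq_along(traces)) {
    frame_traces <- traces[[fi]]
    if (is.data.frame(frame_traces)) frame_traces <- list(frame_traces)
    for (tr in frame_traces) {
      side <- if (!is.null(tr$side)) tr$side else "dorsal"
      rows[[length(rows) + 1]] <-
        data.frame(frame = fi, time = times[fi],
                   point = seq_len(nrow(tr)), x = tr$x, y = tr$y,
                   side = side)
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundary_csv
#' @export
read_boundary_csv <- function(path) {
  d <- read.csv(path)
  frames <- sort(unique(d$frame))
  times <- vapply(frames, function(f) d$time[d$frame == f][1], numeric(1))
  traces <- lapply(frames, function(f) {
    sub <- d[d$frame == f, ]
    lapply(split(sub, sub$side), function(s)
      data.frame(x = s$x[order(s$point)], y = s$y[order(s$point)],
                 side = s$side[1]))
  })
  list(traces = traces, times = times)
}

#' Read a long-format recoil table
#'
#' Columns `series_id`, `t`, `L` and optional `group`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_recoil_csv <- function(path) {
  d <- read.csv(path)
  need <- c("series_id", "t", "L")
  if (!all(need %in% names(d)))
    stop("recoil CSV must contain columns: ", paste(need, collapse = ", "))
  d
}

#' Write / read a scenario configuration as YAML
#'
#' Serializes every scalar field of an [scenario_config()] (parameters,
#' schedule, flags, seeds, cadence); `read_config_yaml` rebuilds the typed
#' objects.
#'
#' @param config An `me_config`.
#' @param path YAML file path.
#' @return `read_config_yaml` returns the `me_config`.
#' @export
write_config_yaml <- function(config, path) {
  x <- config
  x$params <- unclass(x$params)
  x$schedule <- unclass(x$schedule)
  x$flags <- unclass(x$flags)
  x$tissue0 <- NULL
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_config(
    n_cells = x$n_cells, seed = x$seed,
    params = do.call(me_params, x$params),
    schedule = do.call(me_schedule, x$schedule),
    flags = do.call(me_flags, x$flags),
    horizon_min = x$horizon_min, cadence_min = x$cadence_min,
    equil_min = x$equil_min, relax_tau_init = x$relax_tau_init,
    post_div_relax_tau = x$post_div_relax_tau, l_t1 = x$l_t1,
    stripe_halfwidth = x$stripe_halfwidth, um_per_unit = x$um_per_unit,
    store_tissues = x$store_tissues)
}
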