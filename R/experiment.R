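#' Run a multi-scenario, multi-replicate in-silico experiment
#'
#' Runs each requested scenario for every replicate seed, computes the full
#' metric panel per replicate (relative roughness with windowed AUCs,
#' self-overlap and its half-time on a tracked subsample of non-divided
#' ectoderm cells, MSD with axis components, and the ectoderm junctional
#' tension series), and returns tidy per-replicate and summary tables.
#' Initialization is shared across scenarios within a seed so that
#' perturbations are compared on matched initial tissues.
#'
#' @param scenarios Character vector of scenario names understood by
#'   [scenario_flags()].
#' @param replicates Number of replicate seeds per scenario.
#' @param seeds Optional explicit seeds (length `replicates`).
#' @param n_cells Cells per simulation.
#' @param horizon_min Simulated minutes.
#' @param n_track Tracked non-divided ectoderm cells per replicate for the
#'   mobility metrics.
#' @param auc_windows List of `c(start, end)` windows (minutes) for the
#'   roughness AUC statistic.
#' @param base_config Optional [scenario_config()] whose schedule and
#'   parameters are reused (its flags/seed are overridden per run).
#' @param progress Print one line per completed run.
#' @return An object of class `me_experiment`: list with `replicates`
#'   (per-replicate metric rows), `curves` (per-scenario ensemble mean
#'   curves), and `config0` (the base configuration used).
#' @export
run_experiment <- function(scenarios = c("control", "no_tension",
                                         "no_division",
                                         "no_tension_no_division"),
                           replicates = 20, seeds = NULL, n_cells = 400,
                           horizon_min = 40, n_track = 40,
                           auc_windows = list(c(0, 10), c(10, 40)),
                           base_config = NULL, progress = FALSE) {
  if (is.null(seeds)) seeds <- seq_len(replicates)
  stopifnot(length(seeds) == replicates)
  if (is.null(base_config))
    base_config <- scenario_config(n_cells = n_cells,
                                   horizon_min = horizon_min)
  rows <- list()
  curves <- list()
  for (r in seq_len(replicates)) {
    seed <- seeds[r]
    # one initial tissue per seed, shared by all scenarios
    set.seed(seed)
    tis0 <- initialize_tissue(n_cells, seed = NULL,
                              params = base_config$params,
                              schedule = base_config$schedule,
                              stripe_halfwidth = base_config$stripe_halfwidth,
                              relax_tau = base_config$relax_tau_init,
                              l_t1 = base_config$l_t1)
    for (sc in scenarios) {
      cfg <- base_config
      cfg$seed <- seed
      cfg$flags <- scenario_flags(sc)
      cfg$tissue0 <- tis0
      cfg$n_cells <- n_cells
      cfg$horizon_min <- horizon_min
      rec <- run_scenario(cfg)
      met <- replicate_metrics(rec, n_track = n_track,
                               auc_windows = auc_windows)
      met$row$scenario <- sc
      met$row$seed <- seed
      rows[[length(rows) + 1]] <- met$row
      curves[[sc]] <- c(curves[[sc]], list(met$curves))
      if (progress)
        message(sprintf("done %s seed %d (%d divisions)", sc, seed,
                        sum(rec$events$event == "division")))
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  structure(list(replicates = reps, curves = curves,
                 config0 = base_config, seeds = seeds),
            class = "me_experiment")
}

#' Metric panel for one simulation record
#'
#' @param record An `me_record`.
#' @param n_track Tracked non-divided ectoderm cells for mobility metrics.
#' @param auc_windows List of AUC windows (minutes).
#' @return List with `row` (one-row data.frame of scalar metrics) and
#'   `curves` (the roughness/Q/MSD/tension time series).
#' @export
replicate_metrics <- function(record, n_track = 40,
                              auc_windows = list(c(0, 10), c(10, 40))) {
  rough <- relative_roughness_curve(record)
  tracks <- register_tracks(track_table(record))
  elig <- eligible_cells(tracks, min(tracks$time))
  elig <- elig[!tracks$boundary_adjacent[match(elig, tracks$cell_id)]]
  picked <- if (length(elig) > n_track)
    sort(sample(elig, n_track)) else sort(elig)
  Q <- self_overlap(tracks, a = 4, cells = picked)
  M <- msd(tracks, cells = picked, register = FALSE)
  tens <- tension_summary(record)

  tmax <- max(record$times)
  at <- function(d, col, t) {
    i <- match(t, d$time)
    if (is.na(i)) NA_real_ else d[[col]][i]
  }
  row <- data.frame(
    roughness0 = rough$roughness[1],
    rough_rel_10 = at(rough, "relative", 10),
    rough_rel_end = at(rough, "relative", tmax),
    halftime = overlap_halftime(Q),
    Q_end = at(Q, "Q", tmax),
    msd_end = at(M, "msd", tmax),
    msd_ap_end = at(M, "msd_ap", tmax),
    msd_dv_end = at(M, "msd_dv", tmax),
    tension0 = tens$series$mean_ecto_tension[1],
    tension_end = at(tens$series, "mean_ecto_tension", tmax),
    tension_pct = tens$percent_change,
    n_divisions = sum(record$events$event == "division"),
    n_cells_end = nrow(record$frames[[length(record$frames)]]),
    n_tracked = length(picked))
  for (w in auc_windows) {
    nm <- sprintf("auc_%g_%g", w[1], w[2])
    row[[nm]] <- roughness_auc(rough, w[1], w[2])
  }
  list(row = row,
       curves = list(roughness = rough, Q = Q, msd = M,
                     tension = tens$series))
}

#' @export
print.me_experiment <- function(x, ...) {
  cat("me_experiment:\n")
  print(table(x$replicates$scenario))
  invisible(x)
}

#' Scenario-level summary of an experiment
#'
#' Ensemble means and s.e.m. of the endpoint metrics per scenario.
#'
#' @param x An `me_experiment`.
#' @return data.frame with one row per scenario.
#' @export
summarize_experiment <- function(x) {
  reps <- x$replicates
  num <- names(reps)[vapply(reps, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(split(reps, reps$scenario), function(s) {
    means <- vapply(num, function(v) mean(s[[v]], na.rm = TRUE), numeric(1))
    sems <- vapply(num, function(v) {
      ok <- is.finite(s[[v]])
      if (sum(ok) < 2) return(NA_real_)
      sd(s[[v]][ok]) / sqrt(sum(ok))
    }, numeric(1))
    d <- data.frame(scenario = s$scenario[1], n = nrow(s))
    for (v in num) { d[[v]] <- means[[v]]; d[[paste0(v, "_sem")]] <- sems[[v]] }
    d
  }))
  rownames(out) <- NULL
  out
}

#' Render summary figures for an experiment
#'
#' Writes mean +/- s.e.m. curves for roughness, self-overlap, MSD and
#' tension, AUC box plots, and a tension-coloured rendering of a final
#' tissue (compressed junctions in a distinct class) when full tissues were
#' stored. Uses ggplot2 when available; an empty experiment yields an empty
#' report without error.
#'
#' @param x An `me_experiment`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (is.null(x$replicates) || nrow(x$replicates) == 0) return(invisible(paths))
  p <- file.path(dir, "replicate_metrics.csv")
  write.csv(x$replicates, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "scenario_summary.csv")
  write.csv(summarize_experiment(x), p, row.names = FALSE)
  paths <- c(paths, p)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    for (metric in c("roughness", "Q", "msd", "tension")) {
      dat <- do.call(rbind, lapply(names(x$curves), function(sc) {
        value_col <- switch(metric, roughness = "relative", Q = "Q",
                            msd = "msd", tension = "mean_ecto_tension")
        ens <- ensemble_summary(lapply(x$curves[[sc]], `[[`, metric),
                                value_col)
        cbind(ens$summary, scenario = sprintf("%s (n=%d)", sc,
                                              length(x$curves[[sc]])))
      }))
      gg <- ggplot2::ggplot(dat, ggplot2::aes(
        x = time, y = mean, ymin = mean - sem, ymax = mean + sem,
        colour = scenario, fill = scenario)) +
        ggplot2::geom_ribbon(alpha = 0.2, colour = NA) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (min)", y = metric) +
        ggplot2::theme_minimal()
      p <- file.path(dir, paste0(metric, ".pdf"))
      ggplot2::ggsave(p, gg, width = 6, height = 4)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
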