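#' Scenario configuration
#'
#' Bundles everything needed for one simulation run: tissue size, seed,
#' mechanical parameters, schedules, perturbation flags, simulated horizon,
#' snapshot cadence and the micrometre calibration. The calibration maps one
#' simulation length unit to `um_per_unit` micrometres; the default makes
#' the mean ectoderm cell radius approximately 4 um, consistent with the
#' 4 um self-overlap radius being about one cell radius.
#'
#' @param n_cells Number of cells (default 400).
#' @param seed Integer seed controlling all stochasticity of the run.
#' @param params An [me_params()].
#' @param schedule An [me_schedule()].
#' @param flags An [me_flags()] or a scenario name accepted by
#'   [scenario_flags()].
#' @param horizon_min Simulated span after t = 0, in minutes.
#' @param cadence_min Minutes between recorded frames.
#' @param equil_min Pre-t0 equilibration (minutes) with the full cable
#'   tension `gamma0` and constant preferred areas, letting the boundary
#'   settle before measurements start.
#' @param relax_tau_init Relaxation at target parameters before cell types
#'   are assigned (time units).
#' @param post_div_relax_tau Zero-temperature relaxation after each division
#'   (time units).
#' @param l_t1 T1 edge-length threshold.
#' @param stripe_halfwidth Mesectoderm stripe half-width (length units).
#' @param um_per_unit Micrometres per simulation length unit.
#' @param store_tissues Which full tissue snapshots to keep: `"ends"`
#'   (first/last), `"all"`, or `"none"`.
#' @param tissue0 Optional pre-built initial tissue (an `me_tissue`); when
#'   supplied, initialization is skipped and the run starts from it.
#' @return A list of class `me_config`.
#' @export
scenario_config <- function(n_cells = 400, seed = 1, params = me_params(),
                            schedule = me_schedule(), flags = me_flags(),
                            horizon_min = 40, cadence_min = 1,
                            equil_min = 4, relax_tau_init = 1000,
                            post_div_relax_tau = 10, l_t1 = 0.04,
                            stripe_halfwidth = 2 * sqrt(1 / pi),
                            um_per_unit = 4 / sqrt(1 / pi),
                            store_tissues = c("ends", "all", "none"),
                            tissue0 = NULL) {
  if (is.character(flags)) flags <- scenario_flags(flags)
  structure(list(n_cells = n_cells, seed = seed, params = params,
                 schedule = schedule, flags = flags,
                 horizon_min = horizon_min, cadence_min = cadence_min,
                 equil_min = equil_min, relax_tau_init = relax_tau_init,
                 post_div_relax_tau = post_div_relax_tau, l_t1 = l_t1,
                 stripe_halfwidth = stripe_halfwidth,
                 um_per_unit = um_per_unit,
                 store_tissues = match.arg(store_tissues),
                 tissue0 = tissue0),
            class = "me_config")
}

#' Perturbation flag presets for the named in-silico scenarios
#'
#' `"control"`: decaying cable tension, divisions on. `"no_tension"`: acute
#' loss of boundary tension at t = 0. `"no_division"`: divisions blocked at
#' 5 min. `"no_tension_no_division"`: both perturbations. The supplementary
#' modes alter division orientation (`"angle_randomized"`,
#' `"angle_rotated_90"`), restrict the dividing region
#' (`"near_boundary_only"`, `"far_only"`), or hold the mesectoderm
#' preferred area (`"constrained_constriction"`).
#'
#' @param scenario Scenario name.
#' @return An [me_flags()] object.
#' @export
scenario_flags <- function(scenario) {
  switch(scenario,
    control = me_flags(),
    no_tension = me_flags(boundary_tension_on = FALSE),
    no_division = me_flags(divisions_on = FALSE),
    no_tension_no_division = me_flags(boundary_tension_on = FALSE,
                                      divisions_on = FALSE),
    angle_randomized = me_flags(division_angle_mode = "randomized"),
    angle_rotated_90 = me_flags(division_angle_mode = "rotated_90"),
    near_boundary_only = me_flags(division_region = "near_boundary_only"),
    far_only = me_flags(division_region = "far_only"),
    constrained_constriction = me_flags(constrain_apical_constriction = TRUE),
    no_tension_angle_randomized = me_flags(boundary_tension_on = FALSE,
                                           division_angle_mode = "randomized"),
    no_tension_rotated_90 = me_flags(boundary_tension_on = FALSE,
                                     division_angle_mode = "rotated_90"),
    no_tension_near_only = me_flags(boundary_tension_on = FALSE,
                                    division_region = "near_boundary_only"),
    no_tension_far_only = me_flags(boundary_tension_on = FALSE,
                                   division_region = "far_only"),
    no_tension_constrained = me_flags(boundary_tension_on = FALSE,
                                      constrain_apical_constriction = TRUE),
    stop("unknown scenario: ", scenario))
}

#' Run one simulation scenario
#'
#' Advances the tissue over the configured horizon under the time-varying
#' schedules: per-minute frames record cell centroids, types, division
#' status, the extracted ME boundary polylines, and the mean junctional
#' tension over ectoderm-ectoderm edges. Divisions are drawn at each frame
#' by Poisson thinning, executed as polygon splits, and followed by a
#' zero-temperature relaxation. The run is deterministic given
#' `config$seed`.
#'
#' @param config An [scenario_config()] object.
#' @return An object of class `me_record`: list with `config`, `times`,
#'   `frames` (per-frame cell tables), `boundary` (per-frame lists of
#'   boundary traces), `tension` (per-frame mean ectoderm tension),
#'   `events` (division log) and stored tissues per `store_tissues`.
#' @export
run_scenario <- function(config) {
  cfg <- config
  p <- cfg$params; sch <- cfg$schedule; flags <- cfg$flags
  set.seed(cfg$seed)
  tis <- if (!is.null(cfg$tissue0)) cfg$tissue0
         else initialize_tissue(cfg$n_cells, seed = NULL, params = p,
                                schedule = sch,
                                stripe_halfwidth = cfg$stripe_halfwidth,
                                relax_tau = cfg$relax_tau_init,
                                l_t1 = cfg$l_t1)
  spm <- steps_per_minute(p)

  # pre-t0 equilibration with the full cable
  if (cfg$equil_min > 0) {
    nst <- round(cfg$equil_min * spm)
    tis <- advance_tissue(tis, sch$gamma0, nst, p, l_t1 = cfg$l_t1)$tissue
  }

  times <- seq(0, cfg$horizon_min, by = cfg$cadence_min)
  nf <- length(times)
  frames <- vector("list", nf)
  boundary <- vector("list", nf)
  tension <- data.frame(time = times, mean_ecto_tension = NA_real_,
                        n_edges = NA_integer_)
  events <- list()
  tissues <- list()
  mesec_idx <- function(t) which(t$type == "mesectoderm")

  for (fi in seq_len(nf)) {
    t_now <- times[fi]
    g_now <- gamma_at(t_now, sch, flags)
    geo <- cell_geometry(tis)
    geo$divided <- tis$divided
    adj <- boundary_adjacent_cells(tis)
    geo$boundary_adjacent <- seq_len(nrow(geo)) %in% adj
    frames[[fi]] <- geo
    boundary[[fi]] <- boundary_envelope(tis)
    et <- edge_table(tis, g_now, p)
    ee <- !et$het & tis$type[et$c1] != "mesectoderm" &
      tis$type[et$c2] != "mesectoderm"
    tension$mean_ecto_tension[fi] <- mean(et$tension[ee])
    tension$n_edges[fi] <- sum(ee)
    if (cfg$store_tissues == "all" ||
        (cfg$store_tissues == "ends" && fi %in% c(1L, nf)))
      tissues[[as.character(t_now)]] <- tis
    if (fi == nf) break

    # divisions during (t_now, t_now + cadence)
    divs <- schedule_divisions(tis, t_now, cfg$cadence_min, sch, flags)
    if (nrow(divs) > 0) {
      # cells are addressed by id: indices shift as divisions are applied
      div_ids <- tis$cell_id[divs$cell]
      for (k in seq_len(nrow(divs))) {
        idx <- match(div_ids[k], tis$cell_id)
        if (is.na(idx)) next
        res <- divide_cell(tis, idx, divs$angle[k], p,
                           A0_post = sch$A0_ecto_post)
        if (res$done) {
          tis <- res$tissue
          events[[length(events) + 1]] <-
            data.frame(time = t_now, event = "division",
                       cell_id = div_ids[k], angle = divs$angle[k])
          if (cfg$post_div_relax_tau > 0) {
            nst <- round(cfg$post_div_relax_tau / p$dt)
            tis <- advance_tissue(tis, g_now, nst, p, l_t1 = cfg$l_t1,
                                  temperature = 0, f_tol = 0.01)$tissue
          }
        }
      }
    }

    # apical constriction: update mesectoderm preferred geometry
    mi <- mesec_idx(tis)
    a0m <- a0_mesec_at(times[fi + 1], sch, flags)
    tis$A0[mi] <- a0m
    tis$P0[mi] <- p$q * sqrt(a0m)

    # advance one cadence with the continuously decaying tension
    nst <- round(cfg$cadence_min * spm)
    tsub <- t_now + seq_len(nst) * p$dt * p$tau_min
    gvec <- gamma_at(tsub, sch, flags)
    tis <- advance_tissue(tis, gvec, nst, p, l_t1 = cfg$l_t1)$tissue
  }

  events <- if (length(events)) do.call(rbind, events)
            else data.frame(time = numeric(0), event = character(0),
                            cell_id = integer(0), angle = numeric(0))
  structure(list(config = cfg, times = times, frames = frames,
                 boundary = boundary, tension = tension, events = events,
                 tissues = tissues),
            class = "me_record")
}

#' @export
print.me_record <- function(x, ...) {
  cat(sprintf("me_record: %d frames over %g min, %d divisions\n",
              length(x$times), max(x$times),
              sum(x$events$event == "division")))
  invisible(x)
}

#' Centroid track table from a simulation record
#'
#' Flattens the per-frame cell tables into a long track table in
#' micrometres, matching the schema used for tracked-cell data: one row per
#' cell per frame with stable cell id, position, tissue type, whether the
#' cell has divided (or was born from a division), and whether it touched
#' the ME boundary at t = 0.
#'
#' @param record An `me_record`.
#' @return data.frame with columns `cell_id`, `time`, `x`, `y` (um),
#'   `type`, `divided`, `boundary_adjacent`.
#' @export
track_table <- function(record) {
  u <- record$config$um_per_unit
  adj0 <- record$frames[[1]]$cell_id[record$frames[[1]]$boundary_adjacent]
  out <- do.call(rbind, lapply(seq_along(record$times), function(fi) {
    f <- record$frames[[fi]]
    data.frame(cell_id = f$cell_id, time = record$times[fi],
               x = f$cx * u, y = f$cy * u, type = f$type,
               divided = f$divided,
               boundary_adjacent = f$cell_id %in% adj0)
  }))
  rownames(out) <- NULL
  # make trajectories continuous across the periodic box
  if (!is.null(record$tissues) && length(record$tissues))
    box <- record$tissues[[1]]$box * u
  else
    box <- rep(sqrt(record$config$n_cells), 2) * u
  unwrap_tracks(out, box)
}
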