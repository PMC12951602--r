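#' Time-varying model inputs (schedules)
#'
#' The schedule collects every time-dependent input of a simulation: the
#' boundary line tension `gamma(t) = gamma0 * exp(-k_gamma * t)` modelling
#' the disassembly of the actomyosin cable, the shrinking preferred area of
#' mesectoderm cells emulating apical constriction, the bidisperse ectoderm
#' preferred areas (cells before/after division), and the stochastic
#' division process of the ectoderm.
#'
#' Default values were fixed by the calibration described in the methods
#' vignette, anchored on the control and acute-tension-loss roughness
#' dynamics, the division-driven tension release, and the average
#' ectoderm junction counts per simulation; only pre-division ectoderm
#' cells divide, so the realized division count saturates near the size
#' of that pool as it depletes.
#'
#' @param gamma0 Boundary line tension at t = 0 (energy per unit length,
#'   units of `K_A * A0^(3/2)`).
#' @param k_gamma Tension decay rate (per minute).
#' @param A0_mesec0 Mesectoderm preferred area at t = 0.
#' @param A0_mesec_end_frac Fraction of `A0_mesec0` reached at
#'   `t_constrict_min` (linear decrease; constant afterwards).
#' @param t_constrict_min Duration of the apical-constriction ramp (minutes).
#' @param A0_ecto_pre,A0_ecto_post Preferred areas of ectoderm cells before
#'   and after division (bidisperse mixture).
#' @param division_rate Expected ectoderm divisions per minute in the whole
#'   tissue.
#' @param block_time Time (minutes) at which divisions stop when the
#'   no-division perturbation is active (mimics the delayed action of a
#'   cell-cycle inhibitor).
#' @param spindle_sd_deg Angular spread (degrees) of the spindle orientation
#'   of boundary-adjacent divisions about the dorsal-ventral axis.
#'
#' @return An object of class `me_schedule`.
#' @export
me_schedule <- function(gamma0 = 0.75, k_gamma = 0.02, A0_mesec0 = 1,
                        A0_mesec_end_frac = 0.65, t_constrict_min = 40,
                        A0_ecto_pre = 1.287, A0_ecto_post = 0.713,
                        division_rate = 8, block_time = 5,
                        spindle_sd_deg = 15) {
  stopifnot(gamma0 >= 0, k_gamma >= 0, A0_mesec0 > 0,
            A0_mesec_end_frac > 0, A0_mesec_end_frac <= 1,
            A0_ecto_pre > 0, A0_ecto_post > 0, division_rate >= 0,
            block_time >= 0)
  structure(list(gamma0 = gamma0, k_gamma = k_gamma, A0_mesec0 = A0_mesec0,
                 A0_mesec_end_frac = A0_mesec_end_frac,
                 t_constrict_min = t_constrict_min,
                 A0_ecto_pre = A0_ecto_pre, A0_ecto_post = A0_ecto_post,
                 division_rate = division_rate, block_time = block_time,
                 spindle_sd_deg = spindle_sd_deg),
            class = "me_schedule")
}

#' Perturbation flags
#'
#' Switches selecting the in-silico experiment: acute loss of boundary
#' tension, inhibition of ectoderm divisions (blocked at the schedule's
#' `block_time`), altered division orientation of boundary-adjacent cells,
#' regional restriction of divisions, and constrained apical constriction
#' (mesectoderm preferred area held at its initial value).
#'
#' @param boundary_tension_on When FALSE, `gamma` drops to 0 for all t > 0
#'   (acute tension loss).
#' @param divisions_on When FALSE, divisions stop at the schedule's
#'   `block_time`.
#' @param division_angle_mode One of `"in_vivo"` (boundary-adjacent cells
#'   divide along the dorsal-ventral axis, others randomly), `"randomized"`,
#'   `"rotated_90"`.
#' @param division_region Which divisions remain: `"all"`,
#'   `"near_boundary_only"`, `"far_only"`, `"none"`.
#' @param constrain_apical_constriction Hold the mesectoderm preferred area
#'   at its t = 0 value.
#' @return An object of class `me_flags`.
#' @export
me_flags <- function(boundary_tension_on = TRUE, divisions_on = TRUE,
                     division_angle_mode = c("in_vivo", "randomized",
                                             "rotated_90"),
                     division_region = c("all", "near_boundary_only",
                                         "far_only", "none"),
                     constrain_apical_constriction = FALSE) {
  structure(list(
    boundary_tension_on = isTRUE(boundary_tension_on),
    divisions_on = isTRUE(divisions_on),
    division_angle_mode = match.arg(division_angle_mode),
    division_region = match.arg(division_region),
    constrain_apical_constriction = isTRUE(constrain_apical_constriction)
  ), class = "me_flags")
}

#' Boundary line tension at time t
#'
#' `gamma(t) = gamma0 * exp(-k_gamma * t)`; under acute tension loss
#' (`boundary_tension_on = FALSE`) the cable is absent for all t > 0.
#'
#' @param t Time in minutes (vectorized).
#' @param schedule An [me_schedule()].
#' @param flags An [me_flags()].
#' @return Line tension value(s).
#' @export
gamma_at <- function(t, schedule, flags = me_flags()) {
  g <- schedule$gamma0 * exp(-schedule$k_gamma * t)
  if (!flags$boundary_tension_on) g[t > 0] <- 0
  g
}

#' Mesectoderm preferred area at time t
#'
#' Linear decrease from `A0_mesec0` to `A0_mesec_end_frac * A0_mesec0` over
#' `t_constrict_min` minutes (apical constriction), constant afterwards.
#' With `constrain_apical_constriction` the initial value is held.
#'
#' @inheritParams gamma_at
#' @return Preferred area value(s).
#' @export
a0_mesec_at <- function(t, schedule, flags = me_flags()) {
  if (flags$constrain_apical_constriction)
    return(rep(schedule$A0_mesec0, length(t)))
  frac <- pmin(pmax(t, 0) / schedule$t_constrict_min, 1)
  schedule$A0_mesec0 * (1 - frac * (1 - schedule$A0_mesec_end_frac))
}

#' Select cells to divide during a time interval
#'
#' Ectoderm cells (pre-division type) are chosen by Poisson thinning at the
#' schedule's tissue-level division rate. Boundary-adjacent cells (sharing
#' at least one edge with a mesectoderm cell) receive a spindle angle drawn
#' from a wrapped normal centred on the dorsal-ventral axis; other cells
#' divide with uniformly random orientation. Angle and region modes of
#' `flags` override these rules.
#'
#' @param tis An `me_tissue`.
#' @param t Current time (minutes).
#' @param dt_min Interval length (minutes).
#' @param schedule An [me_schedule()].
#' @param flags An [me_flags()].
#' @return data.frame with columns `cell` (cell index) and `angle` (spindle
#'   angle, radians; 0 = anterior-posterior axis); zero rows when nothing
#'   divides.
#' @export
schedule_divisions <- function(tis, t, dt_min, schedule, flags = me_flags()) {
  empty <- data.frame(cell = integer(0), angle = numeric(0))
  if (!flags$divisions_on && t >= schedule$block_time) return(empty)
  if (flags$division_region == "none") return(empty)
  if (schedule$division_rate <= 0) return(empty)

  eligible <- which(tis$type == "ectoderm_pre" & lengths(tis$loops) >= 4)
  if (length(eligible) == 0) return(empty)
  adj <- boundary_adjacent_cells(tis)
  eligible <- switch(flags$division_region,
    all = eligible,
    near_boundary_only = intersect(eligible, adj),
    far_only = setdiff(eligible, adj),
    none = integer(0))
  if (length(eligible) == 0) return(empty)

  n <- rpois(1, schedule$division_rate * dt_min)
  n <- min(n, length(eligible))
  if (n == 0) return(empty)
  cells <- if (length(eligible) == 1) eligible else sample(eligible, n)

  sdr <- schedule$spindle_sd_deg * pi / 180
  angle <- vapply(cells, function(cc) {
    near <- cc %in% adj
    mode <- flags$division_angle_mode
    if (mode == "randomized" || !near) {
      runif(1, 0, pi)
    } else if (mode == "rotated_90") {
      rnorm(1, 0, sdr) %% pi          # anterior-posterior axis
    } else {
      (pi / 2 + rnorm(1, 0, sdr)) %% pi  # dorsal-ventral axis
    }
  }, numeric(1))
  data.frame(cell = cells, angle = angle)
}

#' Ectoderm cells adjacent to the ME boundary
#'
#' @param tis An `me_tissue`.
#' @return Integer vector of cell indices sharing at least one edge with a
#'   mesectoderm cell.
#' @export
boundary_adjacent_cells <- function(tis) {
  et <- edge_table(tis, 0)
  het <- et[et$het, ]
  cells <- unique(c(het$c1, het$c2))
  cells <- cells[!is.na(cells)]
  sort(cells[tis$type[cells] != "mesectoderm"])
}
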