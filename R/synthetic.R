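# Synthetic-data generators. These stand in for segmented embryo
# recordings: every generator returns its ground truth alongside the data
# so downstream recovery tests compare estimates against stored truth.

#' Synthetic ME-boundary traces with known roughness
#'
#' Sinusoidal boundaries `y = amplitude(t) * sin(2 pi x / wavelength)` plus
#' independent Gaussian localization noise, optionally rotated rigidly per
#' frame. Densely sampled over whole periods, the noiseless roughness is
#' `amplitude / sqrt(2)`; with localization noise sigma the expected
#' squared roughness is `amplitude^2 / 2 + sigma^2`.
#'
#' @param amplitude Per-frame amplitude (um); scalar or vector of length
#'   `frames`.
#' @param wavelength Sinusoid wavelength (um).
#' @param extent Boundary length along x (um); an integer number of
#'   wavelengths keeps the closed-form roughness exact.
#' @param n_points Sample points per frame.
#' @param frames Number of frames.
#' @param cadence Minutes between frames.
#' @param noise_sd Localization noise (um; default 0.2).
#' @param rotate_deg Rigid rotation applied per frame (degrees; scalar or
#'   vector).
#' @param seed Optional seed.
#' @return List with `traces` (list of data.frames `x`, `y`, `side`),
#'   `times`, and `truth` (data.frame `time`, `amplitude`,
#'   `roughness_expected`).
#' @export
make_boundary_series <- function(amplitude, wavelength = 20, extent = 140,
                                 n_points = 200, frames = 41, cadence = 1,
                                 noise_sd = 0.2, rotate_deg = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amplitude <- rep_len(amplitude, frames)
  rotate_deg <- rep_len(rotate_deg, frames)
  times <- (seq_len(frames) - 1) * cadence
  traces <- lapply(seq_len(frames), function(fi) {
    x <- seq(0, extent, length.out = n_points)
    y <- amplitude[fi] * sin(2 * pi * x / wavelength) +
      rnorm(n_points, 0, noise_sd)
    th <- rotate_deg[fi] * pi / 180
    data.frame(x = cos(th) * x - sin(th) * y,
               y = sin(th) * x + cos(th) * y,
               side = "dorsal")
  })
  truth <- data.frame(time = times, amplitude = amplitude,
                      roughness_expected = sqrt(amplitude^2 / 2 +
                                                noise_sd^2))
  list(traces = traces, times = times, truth = truth)
}

#' Synthetic centroid track tables with known mobility
#'
#' Generates per-cell trajectories under a chosen mobility model (static,
#' diffusive with coefficient `D_um2_min`, or ballistic with speed
#' `v_um_min` along a random direction), plus an optional common drift that
#' mesectoderm registration must remove (a synthetic mesectoderm population
#' moving with the drift is appended), labelled division events to exercise
#' the exclusion rules, and Gaussian localization noise. For the diffusive
#' model the ground-truth MSD is `4 * D_um2_min * t`; for the ballistic
#' model `(v t)^2`.
#'
#' @param n_cells Ectoderm cells.
#' @param frames,cadence Number of frames and minutes between them.
#' @param mobility One of `"static"`, `"diffusive"`, `"ballistic"`.
#' @param D_um2_min Diffusion coefficient (um^2/min).
#' @param v_um_min Ballistic speed (um/min).
#' @param drift_um_min Common drift velocity, length-2 (um/min).
#' @param divided_fraction Fraction of ectoderm cells flagged as divided.
#' @param noise_sd Localization noise (um; default 0.2).
#' @param field_um Field side for initial positions (um).
#' @param n_mesec Synthetic mesectoderm cells carried along the drift.
#' @param seed Optional seed.
#' @return List with `tracks` (long table) and `truth` (list of the model
#'   and parameters).
#' @export
make_track_table <- function(n_cells = 40, frames = 41, cadence = 1,
                             mobility = c("static", "diffusive",
                                          "ballistic"),
                             D_um2_min = 0.2, v_um_min = 0.3,
                             drift_um_min = c(0, 0),
                             divided_fraction = 0, noise_sd = 0.2,
                             field_um = 136, n_mesec = 10, seed = NULL) {
  mobility <- match.arg(mobility)
  if (!is.null(seed)) set.seed(seed)
  times <- (seq_len(frames) - 1) * cadence
  x0 <- runif(n_cells, 0, field_um)
  y0 <- runif(n_cells, 0, field_um)
  theta <- runif(n_cells, 0, 2 * pi)
  divided <- seq_len(n_cells) <= round(divided_fraction * n_cells)
  ecto <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    if (mobility == "diffusive") {
      dx <- c(0, cumsum(rnorm(frames - 1, 0, sqrt(2 * D_um2_min * cadence))))
      dy <- c(0, cumsum(rnorm(frames - 1, 0, sqrt(2 * D_um2_min * cadence))))
    } else if (mobility == "ballistic") {
      dx <- v_um_min * times * cos(theta[i])
      dy <- v_um_min * times * sin(theta[i])
    } else {
      dx <- dy <- rep(0, frames)
    }
    data.frame(cell_id = i, time = times,
               x = x0[i] + dx + drift_um_min[1] * times +
                 rnorm(frames, 0, noise_sd),
               y = y0[i] + dy + drift_um_min[2] * times +
                 rnorm(frames, 0, noise_sd),
               type = "ectoderm_pre", divided = divided[i],
               boundary_adjacent = FALSE)
  }))
  mes <- do.call(rbind, lapply(seq_len(n_mesec), function(i) {
    data.frame(cell_id = n_cells + i, time = times,
               x = runif(1, 0, field_um) + drift_um_min[1] * times,
               y = runif(1, 0, field_um) + drift_um_min[2] * times,
               type = "mesectoderm", divided = FALSE,
               boundary_adjacent = FALSE)
  }))
  truth <- list(mobility = mobility, D_um2_min = D_um2_min,
                v_um_min = v_um_min, drift_um_min = drift_um_min,
                noise_sd = noise_sd)
  list(tracks = rbind(ecto, mes), truth = truth)
}

#' Synthetic post-ablation recoil curves
#'
#' Kelvin-Voigt curves sampled every `dt_s` seconds with per-series
#' parameters drawn from lognormal distributions around the group means and
#' additive Gaussian noise. Two-group designs with a stated percent
#' difference in `D` and `tau` exercise the group-comparison layer.
#'
#' @param n Series per group (scalar or length matching `groups`).
#' @param D_mean,tau_mean Group means of the retraction amplitude (um) and
#'   relaxation time (s); scalars or vectors per group.
#' @param cv Lognormal coefficient of variation of the per-series
#'   parameters.
#' @param L0 Pre-ablation end-to-end distance (um).
#' @param noise_sd Measurement noise (um).
#' @param t_max,dt_s Observation window and sampling interval (s; default
#'   every 4 s to 60 s).
#' @param groups Group labels.
#' @param seed Optional seed.
#' @return List with `data` (long table `series_id`, `group`, `t`, `L`)
#'   and `truth` (per-series true parameters).
#' @export
make_recoil_set <- function(n = 35, D_mean = 2, tau_mean = 8, cv = 0.2,
                            L0 = 3, noise_sd = 0.05, t_max = 60, dt_s = 4,
                            groups = "control", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ng <- length(groups)
  n <- rep_len(n, ng); D_mean <- rep_len(D_mean, ng)
  tau_mean <- rep_len(tau_mean, ng)
  tt <- seq(0, t_max, by = dt_s)
  sdlog <- sqrt(log(1 + cv^2))
  rows <- list(); truth <- list(); sid <- 0
  for (g in seq_len(ng)) {
    for (i in seq_len(n[g])) {
      sid <- sid + 1
      D <- if (cv > 0) stats::rlnorm(1, log(D_mean[g]) - sdlog^2 / 2, sdlog)
           else D_mean[g]
      tau <- if (cv > 0) stats::rlnorm(1, log(tau_mean[g]) - sdlog^2 / 2,
                                       sdlog) else tau_mean[g]
      L <- kv_model(tt, L0, D, tau) + rnorm(length(tt), 0, noise_sd)
      rows[[sid]] <- data.frame(series_id = sid, group = groups[g],
                                t = tt, L = L)
      truth[[sid]] <- data.frame(series_id = sid, group = groups[g],
                                 D = D, tau_relax = tau, v0 = D / tau)
    }
  }
  list(data = do.call(rbind, rows), truth = do.call(rbind, truth))
}
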