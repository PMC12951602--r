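# Cell-mobility metrics: self-overlap, half-time, MSD with axis components.

#' Unwrap periodic trajectories
#'
#' Replaces per-cell positions by cumulative minimum-image increments so
#' trajectories are continuous across the periodic box. No-op when `box`
#' is NULL (real tracked data).
#'
#' @param tracks Long track table (`cell_id`, `time`, `x`, `y`, ...).
#' @param box Length-2 box dimensions in the same units as `x`, `y`.
#' @return The track table with unwrapped coordinates.
#' @export
unwrap_tracks <- function(tracks, box) {
  if (is.null(box)) return(tracks)
  tracks <- tracks[order(tracks$cell_id, tracks$time), ]
  for (axis in c("x", "y")) {
    L <- box[[if (axis == "x") 1 else 2]]
    v <- tracks[[axis]]
    newcell <- c(TRUE, tracks$cell_id[-1] != tracks$cell_id[-nrow(tracks)])
    d <- c(0, diff(v))
    d[newcell] <- 0
    d <- d - L * round(d / L)
    anchor <- v
    anchor[!newcell] <- 0
    tracks[[axis]] <- ave(anchor + d, tracks$cell_id, FUN = cumsum)
  }
  tracks
}

#' Register tracks to the mesectoderm
#'
#' Subtracts the mean frame-to-frame drift of the mesectoderm centroids
#' from every trajectory, removing rigid tissue motion (in embryos, the
#' residue of germband extension/retraction) so that only motion relative
#' to the mesectoderm remains.
#'
#' @param tracks Long track table with a `type` column; coordinates must be
#'   continuous (unwrap first for periodic data).
#' @return The track table with registered coordinates.
#' @export
register_tracks <- function(tracks) {
  mes <- tracks[tracks$type == "mesectoderm", ]
  if (nrow(mes) == 0) return(tracks)
  tt <- sort(unique(tracks$time))
  drift_x <- vapply(tt, function(t) mean(mes$x[mes$time == t]), numeric(1))
  drift_y <- vapply(tt, function(t) mean(mes$y[mes$time == t]), numeric(1))
  ix <- match(tracks$time, tt)
  tracks$x <- tracks$x - (drift_x[ix] - drift_x[1])
  tracks$y <- tracks$y - (drift_y[ix] - drift_y[1])
  tracks
}

# cells eligible for mobility analyses: ectoderm cells present at the
# reference frame that never divide during the observation window
eligible_cells <- function(tracks, reference_time) {
  present0 <- unique(tracks$cell_id[tracks$time == reference_time])
  ect <- tracks$cell_id[tracks$type %in% c("ectoderm_pre", "ectoderm_post")]
  ever_divided <- unique(tracks$cell_id[tracks$divided])
  last_t <- max(tracks$time)
  full <- vapply(present0, function(id)
    any(tracks$cell_id == id & tracks$time == last_t), logical(1))
  setdiff(intersect(present0[full], ect), ever_divided)
}

#' Self-overlap function Q(t)
#'
#' Fraction of cells whose centroid has moved less than the overlap radius
#' `a` since the reference frame: `Q(t) = mean(w(|r_i(t) - r_i(0)| ))` with
#' `w = 1` below `a` and 0 otherwise. High Q indicates solid-like
#' ("frozen") tissue. Only ectoderm cells that have not divided are used.
#'
#' @param tracks Long track table (continuous coordinates; register first
#'   if a mesectoderm reference is available).
#' @param a Overlap radius, default 4 um (about one cell radius).
#' @param reference_time Reference frame (default the first time present).
#' @param cells Optional vector of cell ids restricting the analysis (e.g.
#'   a tracked subsample).
#' @return data.frame with columns `time`, `Q`, `n`.
#' @export
self_overlap <- function(tracks, a = 4, reference_time = NULL,
                         cells = NULL) {
  stopifnot(a > 0)
  if (is.null(reference_time)) reference_time <- min(tracks$time)
  ids <- eligible_cells(tracks, reference_time)
  if (!is.null(cells)) ids <- intersect(ids, cells)
  if (length(ids) == 0) stop("no eligible cells at the reference frame")
  sub <- tracks[tracks$cell_id %in% ids & tracks$time >= reference_time, ]
  ref <- sub[sub$time == reference_time, ]
  x0 <- setNames(ref$x, ref$cell_id)
  y0 <- setNames(ref$y, ref$cell_id)
  tt <- sort(unique(sub$time))
  Q <- vapply(tt, function(t) {
    f <- sub[sub$time == t, ]
    d2 <- (f$x - x0[as.character(f$cell_id)])^2 +
          (f$y - y0[as.character(f$cell_id)])^2
    mean(d2 < a^2)
  }, numeric(1))
  data.frame(time = tt, Q = Q, n = length(ids))
}

#' Half-time of the self-overlap decrease
#'
#' Linear-interpolated first crossing of Q = 0.5. Returns `NA` when the
#' series never reaches 0.5 within the observation window ("no-decrease").
#'
#' @param Qseries data.frame with columns `time`, `Q` (from
#'   [self_overlap()]).
#' @param threshold Crossing level (default 0.5).
#' @return Half-time in the time units of the series, or `NA_real_` when Q
#'   does not decrease to the threshold.
#' @export
overlap_halftime <- function(Qseries, threshold = 0.5) {
  t <- Qseries$time; Q <- Qseries$Q
  below <- which(Q < threshold)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(t[1])
  t[i - 1] + (threshold - Q[i - 1]) * (t[i] - t[i - 1]) / (Q[i] - Q[i - 1])
}

#' Mean squared displacement with axis components
#'
#' `MSD(t) = mean_i |r_i(t) - r_i(0)|^2` over non-divided ectoderm cells,
#' after registration to the mesectoderm when `register = TRUE` and
#' mesectoderm tracks are present. The anterior-posterior (x) and
#' dorsal-ventral (y) components use the squared axis components of the
#' displacement; they sum to the total at every frame.
#'
#' @inheritParams self_overlap
#' @param register Subtract mesectoderm drift first (default TRUE).
#' @return data.frame with columns `time`, `msd`, `msd_ap`, `msd_dv`, `n`.
#' @export
msd <- function(tracks, reference_time = NULL, cells = NULL,
                register = TRUE) {
  if (register) tracks <- register_tracks(tracks)
  if (is.null(reference_time)) reference_time <- min(tracks$time)
  ids <- eligible_cells(tracks, reference_time)
  if (!is.null(cells)) ids <- intersect(ids, cells)
  if (length(ids) == 0) stop("no eligible cells at the reference frame")
  sub <- tracks[tracks$cell_id %in% ids & tracks$time >= reference_time, ]
  ref <- sub[sub$time == reference_time, ]
  x0 <- setNames(ref$x, ref$cell_id)
  y0 <- setNames(ref$y, ref$cell_id)
  tt <- sort(unique(sub$time))
  out <- do.call(rbind, lapply(tt, function(t) {
    f <- sub[sub$time == t, ]
    dx <- f$x - x0[as.character(f$cell_id)]
    dy <- f$y - y0[as.character(f$cell_id)]
    data.frame(time = t, msd = mean(dx^2 + dy^2), msd_ap = mean(dx^2),
               msd_dv = mean(dy^2), n = nrow(f))
  }))
  rownames(out) <- NULL
  out
}

#' Cell density in a rectangular region
#'
#' @param x Track table (uses the earliest frame unless `time` is given) or
#'   a data.frame of centroids with `x`, `y`.
#' @param region `c(xmin, xmax, ymin, ymax)` in the coordinate units.
#' @param time Optional frame to use for track tables.
#' @return Cells per 100 square units (per 100 um^2 for um coordinates).
#' @export
cell_density <- function(x, region, time = NULL) {
  stopifnot(length(region) == 4)
  area <- (region[2] - region[1]) * (region[4] - region[3])
  stopifnot(area > 0)
  if (!is.null(x$time)) {
    if (is.null(time)) time <- min(x$time)
    x <- x[x$time == time, ]
  }
  inside <- x$x >= region[1] & x$x < region[2] &
            x$y >= region[3] & x$y < region[4]
  100 * sum(inside) / area
}
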