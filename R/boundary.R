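#' Extract ME boundary polylines from a tissue
#'
#' Walks the edges separating mesectoderm from ectoderm. In a stripe
#' geometry these form two closed curves wrapping the periodic box along
#' the anterior-posterior axis, one per side of the mesectoderm. Each curve
#' is returned as an ordered polyline, unwrapped along its walk, sampled at
#' edge endpoints plus midpoints.
#'
#' @param tis An `me_tissue`.
#' @param midpoints Also sample edge midpoints (default TRUE).
#' @return List of data.frames `(x, y, side)` in simulation length units;
#'   `side` is `"dorsal"` or `"ventral"` by position relative to the stripe.
#' @export
extract_boundaries <- function(tis, midpoints = TRUE) {
  et <- edge_table(tis, 0)
  het <- et[et$het, c("a", "b")]
  if (nrow(het) == 0) return(list())
  Lx <- tis$box[1]; Ly <- tis$box[2]
  nbr <- split(c(het$b, het$a), c(het$a, het$b))
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  traces <- list()
  for (r in seq_len(nrow(het))) {
    if (!is.null(used[[ekey(het$a[r], het$b[r])]])) next
    # walk the cycle starting from this edge
    start <- het$a[r]
    path <- c(start, het$b[r])
    used[[ekey(path[1], path[2])]] <- TRUE
    repeat {
      cur <- path[length(path)]
      nxt <- NULL
      for (cand in nbr[[as.character(cur)]]) {
        if (is.null(used[[ekey(cur, cand)]])) { nxt <- cand; break }
      }
      if (is.null(nxt)) break
      used[[ekey(cur, nxt)]] <- TRUE
      if (nxt == start) break
      path <- c(path, nxt)
    }
    x <- tis$vx[path]; y <- tis$vy[path]
    for (j in seq_along(path)[-1]) {
      x[j] <- x[j - 1] + wrap_delta(x[j] - x[j - 1], Lx)
      y[j] <- y[j - 1] + wrap_delta(y[j] - y[j - 1], Ly)
    }
    if (midpoints && length(x) > 1) {
      mx <- (head(x, -1) + tail(x, -1)) / 2
      my <- (head(y, -1) + tail(y, -1)) / 2
      x <- c(rbind(head(x, -1), mx), tail(x, 1))
      y <- c(rbind(head(y, -1), my), tail(y, 1))
    }
    traces[[length(traces) + 1]] <- data.frame(x = x, y = y)
  }
  # keep the two longest curves (one per side); label sides by mean y
  ord <- order(vapply(traces, nrow, 1L), decreasing = TRUE)
  traces <- traces[ord[seq_len(min(2, length(traces)))]]
  mid <- Ly / 2
  for (i in seq_along(traces)) {
    ybar <- mean(traces[[i]]$y) %% Ly
    traces[[i]]$side <- if (ybar >= mid) "dorsal" else "ventral"
  }
  traces
}

#' Envelope boundary traces of the mesectoderm stripe
#'
#' Returns, per side, the extreme extent of the mesectoderm region in
#' dorsoventral bins along the anterior-posterior axis: the dorsal trace
#' follows the maximal y of mesectoderm cell outlines per bin, the ventral
#' trace the minimal y, with linear interpolation across bins that contain
#' no mesectoderm (e.g. where ectoderm bridges cross the stripe). This
#' mimics an interactive annotation of the interface, which always spans
#' the field of view even when the stripe is locally interrupted, and is
#' the trace used for the roughness time series of simulation records.
#'
#' @param tis An `me_tissue`.
#' @param bin Bin width along x (length units).
#' @return List of two data.frames `(x, y, side)`.
#' @export
boundary_envelope <- function(tis, bin = 0.5) {
  Lx <- tis$box[1]
  mes <- which(tis$type == "mesectoderm")
  if (length(mes) == 0) return(list())
  # annotate the main stripe only: mesectoderm cells that detach and
  # wander into the ectoderm are not part of the traced interface
  if (length(mes) > 1) {
    et <- edge_table(tis, 0)
    mm <- et$c1 %in% mes & et$c2 %in% mes
    comp <- setNames(seq_along(mes), mes)
    pairs <- cbind(match(et$c1[mm], mes), match(et$c2[mm], mes))
    for (k in seq_len(nrow(pairs))) {
      a <- comp[pairs[k, 1]]; b <- comp[pairs[k, 2]]
      if (a != b) comp[comp == b] <- a
    }
    lab <- as.integer(names(which.max(table(comp))))
    mes <- mes[comp == lab]
  }
  polys <- tissue_polygons(tis)[mes]
  pts <- do.call(rbind, lapply(polys, function(pp) {
    # vertices plus edge midpoints
    mx <- (head(pp[, 1], -1) + tail(pp[, 1], -1)) / 2
    my <- (head(pp[, 2], -1) + tail(pp[, 2], -1)) / 2
    cbind(c(pp[, 1], mx), c(pp[, 2], my))
  }))
  x <- pts[, 1] %% Lx
  y <- pts[, 2]
  bins <- floor(x / bin)
  xb <- (unique(sort(bins)) + 0.5) * bin
  all_b <- seq(0, floor((Lx - 1e-9) / bin))
  xall <- (all_b + 0.5) * bin
  env <- function(side_fun, lab) {
    yb <- tapply(y, bins, side_fun)
    yy <- stats::approx(xb, as.numeric(yb), xout = xall, rule = 2)$y
    data.frame(x = xall, y = yy, side = lab)
  }
  list(env(max, "dorsal"), env(min, "ventral"))
}

#' Boundary roughness
#'
#' The polyline is rotated so that its least-squares fit line is horizontal
#' and detrended so the mean transverse coordinate is zero; roughness is the
#' population standard deviation of the transverse coordinates. Degenerate
#' near-vertical traces are rotated by 90 degrees before fitting.
#'
#' @param trace data.frame or matrix with columns `x`, `y` (any units).
#' @return Scalar roughness in the input units.
#' @export
boundary_roughness <- function(trace) {
  x <- trace[["x"]]; y <- trace[["y"]]
  stopifnot(length(x) >= 3)
  if (sd(x) < 1e-12 * max(sd(y), 1e-300)) { tmp <- x; x <- -y; y <- tmp }
  th <- atan(unname(coef(lm(y ~ x))[2]))
  yr <- -sin(th) * x + cos(th) * y
  yr <- yr - mean(yr)
  sqrt(mean(yr^2))
}

#' Roughness time series and its normalized (relative) form
#'
#' Per-frame roughness is the mean over the boundary traces present
#' (typically the two sides of the stripe); the relative curve divides by
#' the value at the reference time `t0`.
#'
#' @param x An `me_record`, or a list of per-frame lists of traces.
#' @param times Frame times (ignored for records).
#' @param t0 Reference time for normalization (default the first frame).
#' @return data.frame with columns `time`, `roughness`, `relative`.
#' @export
relative_roughness_curve <- function(x, times = NULL, t0 = NULL) {
  if (inherits(x, "me_record")) { times <- x$times; x <- x$boundary }
  stopifnot(length(x) == length(times))
  rough <- vapply(x, function(traces) {
    if (length(traces) == 0) return(NA_real_)
    mean(vapply(traces, boundary_roughness, numeric(1)))
  }, numeric(1))
  if (is.null(t0)) t0 <- times[1]
  i0 <- which(times == t0)
  if (length(i0) != 1) stop("t0 not present in the series")
  data.frame(time = times, roughness = rough,
             relative = rough / rough[i0])
}

#' Area under the (re-anchored) roughness curve
#'
#' Trapezoidal integral of `curve - curve(window_start)` over the window;
#' the curve is re-anchored at the value at the window start, so a constant
#' curve integrates to zero regardless of its level.
#'
#' @param curve data.frame with columns `time` and a value column.
#' @param start,end Window in the time units of `curve`.
#' @param value Name of the value column (default `"relative"`).
#' @return Scalar AUC (value units x time units).
#' @export
roughness_auc <- function(curve, start, end, value = "relative") {
  t <- curve$time; v <- curve[[value]]
  ok <- is.finite(v)
  t <- t[ok]; v <- v[ok]
  stopifnot(start >= min(t), end <= max(t), end > start)
  vt <- function(tt) stats::approx(t, v, xout = tt)$y
  tt <- sort(unique(c(start, t[t > start & t < end], end)))
  vv <- vapply(tt, vt, numeric(1)) - vt(start)
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}
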