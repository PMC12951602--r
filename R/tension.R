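#' Junctional tension summary of a simulation record
#'
#' Returns the per-frame mean tension over ectoderm-ectoderm junctions, the
#' percentage change at the requested endpoint relative to t = 0, and (when
#' full tissues were stored) a per-edge tension map of the final frame with
#' a tensile/compressed classification for rendering.
#'
#' @param record An `me_record`.
#' @param endpoint_min Endpoint for the percent change (default the last
#'   frame).
#' @return List with `series` (data.frame `time`, `mean_ecto_tension`,
#'   `n_edges`), `percent_change`, and `edge_map` (or NULL).
#' @export
tension_summary <- function(record, endpoint_min = NULL) {
  s <- record$tension
  if (is.null(endpoint_min)) endpoint_min <- max(s$time)
  v0 <- s$mean_ecto_tension[s$time == min(s$time)]
  v1 <- s$mean_ecto_tension[s$time == endpoint_min]
  pc <- 100 * (v1 - v0) / v0
  edge_map <- NULL
  key <- as.character(endpoint_min)
  if (!is.null(record$tissues[[key]])) {
    tis <- record$tissues[[key]]
    g <- gamma_at(endpoint_min, record$config$schedule, record$config$flags)
    et <- edge_table(tis, g, record$config$params)
    et$state <- ifelse(et$tension >= 0, "tensile", "compressed")
    edge_map <- et
  }
  list(series = s, percent_change = pc, edge_map = edge_map)
}

#' Pointwise ensemble summary of replicate curves
#'
#' Aligns per-replicate time series on their common time grid and returns
#' pointwise mean and standard error of the mean, plus the per-replicate
#' endpoint values (retained for group tests).
#'
#' @param curves List of data.frames sharing a `time` column.
#' @param value Name of the value column.
#' @param endpoints Times at which per-replicate values and percent changes
#'   (relative to the first time) are reported.
#' @return List with `summary` (data.frame `time`, `mean`, `sem`, `n`) and
#'   `endpoints` (data.frame `replicate`, `time`, `value`,
#'   `percent_change`).
#' @export
ensemble_summary <- function(curves, value, endpoints = NULL) {
  stopifnot(length(curves) >= 2)
  tt <- sort(unique(unlist(lapply(curves, function(d) d$time))))
  mat <- vapply(curves, function(d) {
    d[[value]][match(tt, d$time)]
  }, numeric(length(tt)))
  summary <- data.frame(
    time = tt,
    mean = rowMeans(mat, na.rm = TRUE),
    sem = apply(mat, 1, function(r) {
      r <- r[is.finite(r)]
      if (length(r) < 2) return(NA_real_)
      sd(r) / sqrt(length(r))
    }),
    n = rowSums(is.finite(mat)))
  ep <- NULL
  if (!is.null(endpoints)) {
    base <- mat[match(tt[1], tt), ]
    ep <- do.call(rbind, lapply(endpoints, function(te) {
      v <- mat[match(te, tt), ]
      data.frame(replicate = seq_along(curves), time = te, value = v,
                 percent_change = 100 * (v - base) / base)
    }))
  }
  list(summary = summary, endpoints = ep)
}
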