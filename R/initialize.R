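#' Initialize a tissue for an ME-boundary simulation
#'
#' Builds a confluent periodic tissue as the Voronoi tessellation of
#' uniformly random points, relaxes it at target parameters (uniform
#' `A0 = 1`, `P0 = q`) under the Brownian dynamics for `relax_tau` time
#' units, then labels a horizontal (anterior-posterior) central stripe of
#' cells as mesectoderm and assigns the remaining cells a 50/50 bidisperse
#' ectoderm pre/post mixture. Preferred perimeters are set from the target
#' shape index, `P0 = q * sqrt(A0)`, for every cell.
#'
#' @param n_cells Number of cells (box side is `sqrt(n_cells)` so the mean
#'   cell area is 1).
#' @param seed Optional seed passed to [set.seed()]; `NULL` leaves the
#'   random stream untouched.
#' @param params An [me_params()] object.
#' @param schedule An [me_schedule()] supplying the per-type preferred
#'   areas.
#' @param stripe_halfwidth Half-width of the mesectoderm stripe (simulation
#'   length units) about the box midline; the default of one mean cell
#'   diameter selects roughly two cell rows.
#' @param relax_tau Relaxation time before cell types are assigned (time
#'   units).
#' @param l_t1 T1 threshold used during relaxation.
#' @return An `me_tissue` with labelled cell types.
#' @export
initialize_tissue <- function(n_cells = 400, seed = NULL,
                              params = me_params(),
                              schedule = me_schedule(),
                              stripe_halfwidth = 2 * sqrt(1 / pi),
                              relax_tau = 1000, l_t1 = 0.04) {
  stopifnot(n_cells >= 16)
  if (!is.null(seed)) set.seed(seed)
  L <- sqrt(n_cells)
  px <- runif(n_cells) * L
  py <- runif(n_cells) * L
  vor <- vm_periodic_voronoi(px, py, L, L)
  tis <- tissue(vor$vx, vor$vy, vor$loops,
                type = rep("ectoderm_pre", n_cells), box = c(L, L),
                A0 = rep(1, n_cells), P0 = rep(params$q, n_cells))
  if (relax_tau > 0) {
    nsteps <- round(relax_tau / params$dt)
    tis <- advance_tissue(tis, 0, nsteps, params, l_t1 = l_t1)$tissue
  }
  # label the mesectoderm stripe and the bidisperse ectoderm
  geo <- cell_geometry(tis)
  mid <- L / 2
  mesec <- which(abs(geo$cy - mid) < stripe_halfwidth)
  if (length(mesec) == 0) stop("mesectoderm stripe selects zero cells")
  type <- rep("ectoderm_pre", n_cells)
  type[mesec] <- "mesectoderm"
  ecto <- which(type == "ectoderm_pre")
  post <- sample(ecto, floor(length(ecto) / 2))
  type[post] <- "ectoderm_post"
  A0 <- ifelse(type == "mesectoderm", schedule$A0_mesec0,
               ifelse(type == "ectoderm_pre", schedule$A0_ecto_pre,
                      schedule$A0_ecto_post))
  tis$type <- type
  tis$A0 <- A0
  tis$P0 <- params$q * sqrt(A0)
  tis
}
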