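CELL_TYPES <- c("ectoderm_pre", "ectoderm_post", "mesectoderm")

type_codes <- function(type) {
  code <- match(type, CELL_TYPES) - 1L
  if (anyNA(code)) stop("unknown cell type label")
  code
}

#' Construct a periodic vertex-model tissue
#'
#' A tissue is a polygonal tiling of a periodic rectangle: vertex positions,
#' per-cell counter-clockwise loops of vertex indices, a tissue-type label
#' per cell, and the current preferred area `A0` and perimeter `P0` of each
#' cell. Cells carry stable integer ids so that trajectories and division
#' events can be traced through topological changes.
#'
#' @param vx,vy Vertex coordinates (wrapped into the box).
#' @param loops List of integer vectors; each is the counter-clockwise vertex
#'   loop of one cell.
#' @param type Character vector of cell types, one of `"ectoderm_pre"`,
#'   `"ectoderm_post"`, `"mesectoderm"`.
#' @param box Numeric length-2, the periodic box dimensions `c(Lx, Ly)`.
#' @param A0,P0 Per-cell preferred areas and perimeters.
#' @param cell_id Optional stable cell ids (default `seq_along(loops)`).
#' @param divided Logical per cell: whether the cell was born from, or has
#'   undergone, a division during the simulation.
#' @param validate Run structural checks (default TRUE).
#'
#' @return An object of class `me_tissue`.
#' @export
tissue <- function(vx, vy, loops, type, box, A0, P0,
                   cell_id = seq_along(loops),
                   divided = rep(FALSE, length(loops)),
                   validate = TRUE) {
  tis <- structure(list(
    vx = as.numeric(vx), vy = as.numeric(vy),
    loops = lapply(loops, as.integer),
    type = as.character(type),
    box = as.numeric(box),
    A0 = as.numeric(A0), P0 = as.numeric(P0),
    cell_id = as.integer(cell_id),
    divided = as.logical(divided),
    next_id = max(cell_id) + 1L
  ), class = "me_tissue")
  if (validate) validate_tissue(tis)
  tis
}

#' Validate the structural invariants of a tissue
#'
#' Checks that every vertex belongs to at least one cell, that interior
#' vertices are tri-junctions (degree 3), that cell polygons are simple and
#' counter-clockwise under the periodic metric, and that cell areas tile the
#' box.
#'
#' @param tis An `me_tissue`.
#' @param strict Also require exact degree-3 vertices (default TRUE; set
#'   FALSE transiently during topological moves).
#' @return Invisibly `tis`; errors on violation.
#' @export
validate_tissue <- function(tis, strict = TRUE) {
  nv <- length(tis$vx)
  nc <- length(tis$loops)
  stopifnot(length(tis$vy) == nv, length(tis$type) == nc,
            length(tis$A0) == nc, length(tis$P0) == nc,
            length(tis$box) == 2, all(tis$box > 0))
  all_v <- unlist(tis$loops)
  if (any(all_v < 1L) || any(all_v > nv)) stop("loop references unknown vertex")
  deg <- tabulate(all_v, nbins = nv)
  if (any(deg == 0)) stop("vertex belongs to no cell")
  if (strict && any(deg != 3))
    stop("vertex of degree != 3 (expected tri-junctions)")
  if (any(vapply(tis$loops, anyDuplicated, 1L) > 0))
    stop("cell loop repeats a vertex (non-simple polygon)")
  geo <- cell_geometry(tis)
  if (any(geo$area <= 0)) stop("cell with non-positive area (not CCW/simple)")
  if (abs(sum(geo$area) - prod(tis$box)) > 1e-6 * prod(tis$box))
    stop("cell areas do not tile the periodic box")
  invisible(tis)
}

#' Per-cell geometry (area, perimeter, centroid)
#'
#' @param tis An `me_tissue`.
#' @return A data.frame with columns `cell_id`, `type`, `area`, `perim`,
#'   `cx`, `cy` (centroids wrapped into the box).
#' @export
cell_geometry <- function(tis) {
  g <- vm_cell_geometry(tis$vx, tis$vy, tis$loops, tis$box[1], tis$box[2])
  data.frame(cell_id = tis$cell_id, type = tis$type, area = g$area,
             perim = g$perim, cx = g$cx, cy = g$cy)
}

#' Tissue energy
#'
#' The energy of the tissue is the sum over cells of an area-elasticity term
#' `K_A (A - A0)^2` and a perimeter term `K_P (P - P0)^2`, plus a line
#' tension `gamma` on every edge separating mesectoderm from ectoderm (the
#' supracellular actomyosin cable at the ME interface).
#'
#' @param tis An `me_tissue`.
#' @param gamma Boundary line tension (>= 0).
#' @param params An [me_params()] object.
#' @return Scalar energy in units of `K_A * A0^2`.
#' @export
tissue_energy <- function(tis, gamma, params = me_params()) {
  stopifnot(gamma >= 0)
  vm_energy(tis$vx, tis$vy, tis$loops, type_codes(tis$type), tis$A0, tis$P0,
            tis$box[1], tis$box[2], params$K_A, params$K_P, gamma)
}

#' Forces on vertices
#'
#' Analytic gradient forces `F_k = -grad_k E` under the periodic metric.
#'
#' @inheritParams tissue_energy
#' @return A matrix with one `(Fx, Fy)` row per vertex.
#' @export
vertex_forces <- function(tis, gamma, params = me_params()) {
  F <- vm_forces(tis$vx, tis$vy, tis$loops, type_codes(tis$type), tis$A0,
                 tis$P0, tis$box[1], tis$box[2], params$K_A, params$K_P,
                 gamma)
  colnames(F) <- c("Fx", "Fy")
  F
}

#' Advance the tissue by one forward-Euler step
#'
#' `r_k <- r_k + mu F_k dt + eta_k`, with `eta_k` zero-mean normal noise of
#' per-component variance `2 mu T dt`; positions are wrapped into the box.
#' Uses R's random number stream, so runs are reproducible under
#' [set.seed()].
#'
#' @inheritParams tissue_energy
#' @param n Number of steps to take (default 1).
#' @return The advanced `me_tissue`.
#' @export
euler_step <- function(tis, gamma, params = me_params(), n = 1L) {
  res <- vm_run_chunk(tis$vx, tis$vy, tis$loops, type_codes(tis$type),
                      tis$A0, tis$P0, tis$box[1], tis$box[2], params$K_A,
                      params$K_P, params$mu, params$temperature, params$dt,
                      rep(gamma, n), -1, 1L, integer(0), integer(0))
  tis$vx <- res$vx; tis$vy <- res$vy
  tis
}

#' Edge table with junctional tensions
#'
#' One row per undirected cell-cell junction, with the adjacent cells, the
#' edge length, whether it lies on the ME boundary, and the junctional
#' tension `dE/dl`: `2 K_P (P_j - P0_j) + 2 K_P (P_k - P0_k)` for the two
#' adjacent cells, plus `gamma` on heterotypic (ME boundary) edges. Positive
#' tension is tensile, negative compressive.
#'
#' @inheritParams tissue_energy
#' @return A data.frame with columns `a`, `b`, `c1`, `c2`, `length`, `het`,
#'   `tension`.
#' @export
edge_table <- function(tis, gamma, params = me_params()) {
  vm_edge_table(tis$vx, tis$vy, tis$loops, type_codes(tis$type), tis$A0,
                tis$P0, tis$box[1], tis$box[2], params$K_A, params$K_P,
                gamma)
}

#' Tension along a single junction
#'
#' @inheritParams tissue_energy
#' @param edge Integer length-2 vector of vertex indices.
#' @return Scalar tension `dE/dl` along the edge.
#' @export
junction_tension <- function(tis, edge, gamma, params = me_params()) {
  et <- edge_table(tis, gamma, params)
  a <- min(edge); b <- max(edge)
  row <- which(et$a == a & et$b == b)
  if (length(row) != 1) stop("edge not found in tissue")
  et$tension[row]
}

#' @export
print.me_tissue <- function(x, ...) {
  cat(sprintf("me_tissue: %d cells, %d vertices, box %.3g x %.3g\n",
              length(x$loops), length(x$vx), x$box[1], x$box[2]))
  print(table(x$type))
  invisible(x)
}

#' Export tissue polygons as coordinate lists
#'
#' Each cell is returned as a closed, locally unwrapped coordinate matrix
#' (GeoJSON-style ring), convenient for plotting.
#'
#' @param tis An `me_tissue`.
#' @return Named list of n x 2 matrices, one per cell.
#' @export
tissue_polygons <- function(tis) {
  out <- lapply(seq_along(tis$loops), function(c) {
    lp <- tis$loops[[c]]
    x <- tis$vx[lp]; y <- tis$vy[lp]
    # unwrap consecutive vertices by minimum image
    for (j in seq_along(lp)[-1]) {
      dx <- x[j] - x[j - 1]; dy <- y[j] - y[j - 1]
      x[j] <- x[j - 1] + dx - tis$box[1] * round(dx / tis$box[1])
      y[j] <- y[j - 1] + dy - tis$box[2] * round(dy / tis$box[2])
    }
    cbind(x = c(x, x[1]), y = c(y, y[1]))
  })
  names(out) <- tis$cell_id
  out
}

#' Write / read a tissue snapshot as flat CSV tables
#'
#' Serializes a tissue to two CSV files (`<stem>_vertices.csv`,
#' `<stem>_cells.csv`) holding vertex positions and per-cell membership
#' (loop order), types, preferred geometry and the box, so snapshots can be
#' inspected or re-loaded without binary formats.
#'
#' @param tis An `me_tissue`.
#' @param stem File stem (path without suffix).
#' @return `write_tissue_csv`: invisibly the two paths;
#'   `read_tissue_csv`: the reconstructed `me_tissue`.
#' @export
write_tissue_csv <- function(tis, stem) {
  vfile <- paste0(stem, "_vertices.csv")
  cfile <- paste0(stem, "_cells.csv")
  write.csv(data.frame(vertex = seq_along(tis$vx), x = tis$vx, y = tis$vy,
                       Lx = tis$box[1], Ly = tis$box[2]),
            vfile, row.names = FALSE)
  cells <- do.call(rbind, lapply(seq_along(tis$loops), function(c) {
    data.frame(cell_id = tis$cell_id[c], position = seq_along(tis$loops[[c]]),
               vertex = tis$loops[[c]], type = tis$type[c], A0 = tis$A0[c],
               P0 = tis$P0[c], divided = tis$divided[c])
  }))
  write.csv(cells, cfile, row.names = FALSE)
  invisible(c(vfile, cfile))
}

#' @rdname write_tissue_csv
#' @export
read_tissue_csv <- function(stem) {
  v <- read.csv(paste0(stem, "_vertices.csv"))
  cells <- read.csv(paste0(stem, "_cells.csv"))
  ids <- unique(cells$cell_id)
  loops <- lapply(ids, function(i) {
    sub <- cells[cells$cell_id == i, ]
    sub$vertex[order(sub$position)]
  })
  first <- cells[!duplicated(cells$cell_id), ]
  tissue(v$x, v$y, loops, first$type, c(v$Lx[1], v$Ly[1]), first$A0,
         first$P0, cell_id = ids, divided = first$divided)
}
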