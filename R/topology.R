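# Topological moves: T1 neighbour exchanges and cell division.

wrap_delta <- function(d, L) d - L * round(d / L)

# cells whose loop contains vertex v
cells_with_vertex <- function(tis, v) {
  which(vapply(tis$loops, function(lp) v %in% lp, logical(1)))
}

# cells containing the undirected edge a-b as consecutive loop entries
cells_with_edge <- function(tis, a, b) {
  which(vapply(tis$loops, function(lp) {
    n <- length(lp)
    i <- match(a, lp)
    if (is.na(i)) return(FALSE)
    lp[i %% n + 1L] == b || lp[(i - 2L) %% n + 1L] == b
  }, logical(1)))
}

# every undirected edge must be shared by exactly two cells, traversed in
# opposite directions; cheap global consistency check used to validate moves
edge_map_consistent <- function(loops) {
  nv <- max(unlist(loops)) + 1
  from <- unlist(lapply(loops, identity))
  to <- unlist(lapply(loops, function(lp) lp[c(seq_along(lp)[-1], 1L)]))
  keys <- from * nv + to
  if (anyDuplicated(keys) > 0) return(FALSE)
  all((to * nv + from) %in% keys)
}

loops_simple <- function(tis, cells) {
  g <- vm_cell_geometry(tis$vx, tis$vy, tis$loops[cells],
                        tis$box[1], tis$box[2])
  all(is.finite(g$area)) && all(g$area > 0) &&
    !any(vapply(tis$loops[cells], anyDuplicated, 1L) > 0)
}

#' T1 transition (neighbour exchange) on a short edge
#'
#' The two cells sharing the edge lose contact and the two cells at its
#' endpoints gain a new contact, rotated 90 degrees and stretched to
#' `1.5 * l_t1`. The move is skipped (with `done = FALSE`) when either
#' sharing cell is a triangle, or when no orientation of the swapped edge
#' yields a consistent, simple tiling.
#'
#' @param tis An `me_tissue`.
#' @param edge Integer length-2 vector of vertex ids.
#' @param params An [me_params()] object (unused geometry-wise; kept for
#'   interface symmetry).
#' @param l_t1 Edge-length threshold; the new edge is `1.5 * l_t1` long.
#' @return List with elements `tissue` and `done`.
#' @export
t1_transition <- function(tis, edge, params = me_params(), l_t1 = 0.04) {
  a <- edge[1]; b <- edge[2]
  Lx <- tis$box[1]; Ly <- tis$box[2]
  pq <- cells_with_edge(tis, a, b)
  if (length(pq) != 2) return(list(tissue = tis, done = FALSE))
  if (any(lengths(tis$loops[pq]) <= 3)) return(list(tissue = tis, done = FALSE))
  ca <- setdiff(cells_with_vertex(tis, a), pq)
  cb <- setdiff(cells_with_vertex(tis, b), pq)
  if (length(ca) != 1 || length(cb) != 1 || ca == cb)
    return(list(tissue = tis, done = FALSE))

  # midpoint and rotated edge endpoints
  ax <- tis$vx[a]; ay <- tis$vy[a]
  bx <- ax + wrap_delta(tis$vx[b] - ax, Lx)
  by <- ay + wrap_delta(tis$vy[b] - ay, Ly)
  mx <- (ax + bx) / 2; my <- (ay + by) / 2
  l <- sqrt((bx - ax)^2 + (by - ay)^2)
  if (l < 1e-12) { ux <- 1; uy <- 0 } else { ux <- (bx - ax) / l; uy <- (by - ay) / l }
  nx <- -uy; ny <- ux
  half <- 0.75 * l_t1

  insert_after <- function(lp, at, v) append(lp, v, after = match(at, lp))
  insert_before <- function(lp, at, v) append(lp, v, after = match(at, lp) - 1L)

  for (sgn in c(1, -1)) {
    for (drop_variant in 1:2) {
      keepP <- if (drop_variant == 1) a else b   # vertex P keeps
      keepQ <- if (drop_variant == 1) b else a
      for (ins_a in 1:2) for (ins_b in 1:2) {
        cand <- tis
        cand$vx[a] <- (mx + sgn * half * nx) %% Lx
        cand$vy[a] <- (my + sgn * half * ny) %% Ly
        cand$vx[b] <- (mx - sgn * half * nx) %% Lx
        cand$vy[b] <- (my - sgn * half * ny) %% Ly
        cand$loops[[pq[1]]] <- setdiff(cand$loops[[pq[1]]], setdiff(c(a, b), keepP))
        cand$loops[[pq[2]]] <- setdiff(cand$loops[[pq[2]]], setdiff(c(a, b), keepQ))
        cand$loops[[ca]] <- if (ins_a == 1) insert_after(cand$loops[[ca]], a, b)
                            else insert_before(cand$loops[[ca]], a, b)
        cand$loops[[cb]] <- if (ins_b == 1) insert_after(cand$loops[[cb]], b, a)
                            else insert_before(cand$loops[[cb]], b, a)
        affected <- c(pq, ca, cb)
        if (loops_simple(cand, affected) && edge_map_consistent(cand$loops))
          return(list(tissue = cand, done = TRUE))
      }
    }
  }
  list(tissue = tis, done = FALSE)
}

#' Divide a cell along a plane perpendicular to its spindle
#'
#' The cell polygon is cut by the line through its centroid perpendicular to
#' the spindle angle, so that the two daughter centroids separate along the
#' spindle axis. Both daughters are labelled `ectoderm_post` and receive the
#' post-division preferred area `A0_post` (with `P0 = q * sqrt(A0_post)`).
#' Daughter areas sum exactly to the parent area at the instant of division.
#' When the cut line fails to intersect exactly two edges, the angle is
#' jittered and retried; after `max_tries` failures the division is skipped.
#'
#' @param tis An `me_tissue`.
#' @param cell Cell index (position, not id).
#' @param angle Spindle angle in radians (0 = anterior-posterior axis).
#' @param params An [me_params()] object (supplies `q`).
#' @param A0_post Preferred area assigned to the daughters.
#' @param max_tries Attempts with jittered angles before giving up.
#' @return List with elements `tissue`, `done`, and `daughters` (the two new
#'   cell ids when successful).
#' @export
divide_cell <- function(tis, cell, angle, params = me_params(),
                        A0_post = 2 / 3, max_tries = 5L) {
  lp <- tis$loops[[cell]]
  if (length(lp) < 4) return(list(tissue = tis, done = FALSE, daughters = NULL))
  Lx <- tis$box[1]; Ly <- tis$box[2]
  # unwrapped polygon
  x <- tis$vx[lp]; y <- tis$vy[lp]
  for (j in seq_along(lp)[-1]) {
    x[j] <- x[j - 1] + wrap_delta(x[j] - x[j - 1], Lx)
    y[j] <- y[j - 1] + wrap_delta(y[j] - y[j - 1], Ly)
  }
  n <- length(lp)
  A2 <- sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
  cx <- sum((x + x[c(2:n, 1)]) * (x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / (3 * A2)
  cy <- sum((y + y[c(2:n, 1)]) * (x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / (3 * A2)

  for (try in seq_len(max_tries)) {
    th <- angle + if (try == 1) 0 else stats::runif(1, -0.3, 0.3)
    # cut direction perpendicular to the spindle
    dx <- -sin(th); dy <- cos(th)
    s <- (x - cx) * dy - (y - cy) * dx        # signed side of the cut line
    if (any(abs(s) < 1e-9)) next              # grazes a vertex; jitter
    nxt <- c(2:n, 1)
    crossing <- which(s * s[nxt] < 0)
    if (length(crossing) != 2) next
    i1 <- crossing[1]; i2 <- crossing[2]
    tpar <- function(i) s[i] / (s[i] - s[nxt[i]])
    w1x <- x[i1] + tpar(i1) * (x[nxt[i1]] - x[i1])
    w1y <- y[i1] + tpar(i1) * (y[nxt[i1]] - y[i1])
    w2x <- x[i2] + tpar(i2) * (x[nxt[i2]] - x[i2])
    w2y <- y[i2] + tpar(i2) * (y[nxt[i2]] - y[i2])

    nv <- length(tis$vx)
    w1 <- nv + 1L; w2 <- nv + 2L
    cand <- tis
    cand$vx <- c(cand$vx, w1x %% Lx, w2x %% Lx)
    cand$vy <- c(cand$vy, w1y %% Ly, w2y %% Ly)
    # daughters (indices into the parent loop, CCW)
    d1 <- c(w1, lp[(i1 %% n + 1L):i2], w2)
    idx2 <- if (i2 == n) seq_len(i1) else c((i2 + 1L):n, seq_len(i1))
    d2 <- c(w2, lp[idx2], w1)
    # insert the new vertices into the neighbours across the cut edges
    # (a confluent tiling always has one; isolated test polygons have none)
    nb_insert <- function(loops, va, vb, w) {
      for (cc in seq_along(loops)) {
        if (cc == cell) next
        lpc <- loops[[cc]]
        i <- match(vb, lpc)
        if (!is.na(i) && lpc[i %% length(lpc) + 1L] == va) {
          loops[[cc]] <- append(lpc, w, after = i)
          return(loops)
        }
      }
      loops
    }
    cand$loops <- nb_insert(cand$loops, lp[i1], lp[nxt[i1]], w1)
    cand$loops <- nb_insert(cand$loops, lp[i2], lp[nxt[i2]], w2)
    cand$loops[[cell]] <- as.integer(d1)
    cand$loops <- c(cand$loops, list(as.integer(d2)))
    ids <- c(cand$next_id, cand$next_id + 1L)
    cand$cell_id[cell] <- ids[1]
    cand$cell_id <- c(cand$cell_id, ids[2])
    cand$type[cell] <- "ectoderm_post"
    cand$type <- c(cand$type, "ectoderm_post")
    cand$A0[cell] <- A0_post
    cand$A0 <- c(cand$A0, A0_post)
    p0 <- params$q * sqrt(A0_post)
    cand$P0[cell] <- p0
    cand$P0 <- c(cand$P0, p0)
    cand$divided[cell] <- TRUE
    cand$divided <- c(cand$divided, TRUE)
    cand$next_id <- cand$next_id + 2L
    if (loops_simple(cand, c(cell, length(cand$loops))))
      return(list(tissue = cand, done = TRUE, daughters = ids))
  }
  list(tissue = tis, done = FALSE, daughters = NULL)
}

#' Advance a tissue with T1 handling
#'
#' Runs the Brownian Euler dynamics for `nsteps` steps, monitoring edge
#' lengths every `check_every` steps; edges shorter than `l_t1` trigger a T1
#' neighbour exchange. Unswappable edges (e.g. on triangular cells) are
#' temporarily ignored.
#'
#' @param tis An `me_tissue`.
#' @param gamma Per-step boundary line tension: scalar or vector of length
#'   `nsteps`.
#' @param nsteps Number of Euler steps.
#' @param params An [me_params()] object.
#' @param l_t1 T1 threshold (simulation length units); set `<= 0` to disable.
#' @param check_every Steps between edge-length scans.
#' @param temperature Overrides `params$temperature` when not `NULL` (used
#'   for zero-noise relaxations).
#' @param f_tol Zero-temperature convergence tolerance: the relaxation stops
#'   early once the largest vertex force falls below this value (0 disables;
#'   ignored when noise is on).
#' @return List with `tissue` and `n_t1` (number of swaps performed).
#' @export
advance_tissue <- function(tis, gamma, nsteps, params = me_params(),
                           l_t1 = 0.04, check_every = 10L,
                           temperature = NULL, f_tol = 0) {
  p <- params
  if (!is.null(temperature)) p$temperature <- temperature
  gvec <- if (length(gamma) == 1) rep(gamma, nsteps) else gamma
  stopifnot(length(gvec) == nsteps)
  done <- 0L
  n_t1 <- 0L
  skip <- matrix(integer(0), ncol = 2)
  while (done < nsteps) {
    ask <- nsteps - done
    res <- vm_run_chunk(tis$vx, tis$vy, tis$loops, type_codes(tis$type),
                        tis$A0, tis$P0, tis$box[1], tis$box[2], p$K_A, p$K_P,
                        p$mu, p$temperature, p$dt,
                        gvec[(done + 1L):nsteps], l_t1,
                        as.integer(check_every), skip[, 1], skip[, 2], f_tol)
    tis$vx <- res$vx; tis$vy <- res$vy
    done <- done + res$steps_done
    if (res$t1_a == 0 && res$steps_done < ask) break  # converged early
    if (res$t1_a > 0) {
      out <- t1_transition(tis, c(res$t1_a, res$t1_b), p, l_t1 = l_t1)
      if (out$done) {
        tis <- out$tissue
        n_t1 <- n_t1 + 1L
        skip <- matrix(integer(0), ncol = 2)
      } else {
        skip <- rbind(skip, c(res$t1_a, res$t1_b))
      }
    }
  }
  list(tissue = tis, n_t1 = n_t1)
}
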