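# Fixtures built in code: small deterministic tissues and grids.

wrap_d <- function(d, L) d - L * round(d / L)

# single polygon in a large periodic box (structural checks bypassed)
one_cell_tissue <- function(xy, box = c(10, 10), type = "ectoderm_pre",
                            A0 = 1, P0 = 4) {
  tissue(xy[, 1], xy[, 2], list(seq_len(nrow(xy))), type, box, A0, P0,
         validate = FALSE)
}

square_cell <- function(side = 2, origin = c(1, 1)) {
  one_cell_tissue(cbind(origin[1] + c(0, side, side, 0),
                        origin[2] + c(0, 0, side, side)))
}

regular_hexagon <- function(r = 1, centre = c(5, 5)) {
  th <- pi / 6 + seq(0, 5) * pi / 3
  one_cell_tissue(cbind(centre[1] + r * cos(th), centre[2] + r * sin(th)))
}

# 3x3 periodic grid of unit squares; vertices have degree 4, so this is
# only for energy/tension accounting, not for topological moves
nine_square_tissue <- function(types = rep("ectoderm_pre", 9),
                               A0 = rep(1, 9), P0 = rep(4, 9)) {
  vid <- function(i, j) 1L + (i %% 3L) + 3L * (j %% 3L)
  vx <- rep(0:2, times = 3)
  vy <- rep(0:2, each = 3)
  loops <- list()
  for (j in 0:2) for (i in 0:2)
    loops[[length(loops) + 1]] <- c(vid(i, j), vid(i + 1L, j),
                                    vid(i + 1L, j + 1L), vid(i, j + 1L))
  tissue(vx, vy, loops, types, c(3, 3), A0, P0, validate = FALSE)
}

# left column labelled mesectoderm: 6 unit heterotypic edges
nine_square_striped <- function(...) {
  types <- rep("ectoderm_pre", 9)
  types[c(1, 4, 7)] <- "mesectoderm"
  nine_square_tissue(types = types, ...)
}

# relaxed random tissue used across dynamics tests
small_relaxed_tissue <- function(n = 36, seed = 7, stripe = TRUE) {
  sch <- me_schedule()
  tis <- initialize_tissue(n, seed = seed, schedule = sch, relax_tau = 30)
  if (!stripe) {
    tis$type <- rep("ectoderm_pre", n)
    tis$A0 <- rep(1, n)
    tis$P0 <- rep(me_params()$q, n)
  }
  tis
}

expect_valid_tissue <- function(tis) {
  expect_silent(validate_tissue(tis))
}
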