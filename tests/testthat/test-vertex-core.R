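# Energy, forces, dynamics and tensions of the vertex-model core.

test_that("energy matches hand-evaluated cases", {
  # all cells at target geometry, no line tension -> zero energy
  tis <- nine_square_tissue()
  expect_equal(tissue_energy(tis, 0), 0, tolerance = 1e-12)

  # single square cell, side 2, A0 = 1, P0 = 4: (4-1)^2 + (8-4)^2 = 25
  sq <- square_cell(side = 2)
  expect_equal(tissue_energy(sq, 0), 25, tolerance = 1e-12)

  # heterotypic edges contribute gamma * length: a mesectoderm column in
  # the periodic 3x3 grid touches ectoderm along 6 unit edges
  tis <- nine_square_striped()
  g0 <- 0.37
  expect_equal(tissue_energy(tis, g0), g0 * 6, tolerance = 1e-12)
  et <- edge_table(tis, g0)
  expect_equal(sum(et$length[et$het]), 6)
})

test_that("forces are the analytic gradient of the energy", {
  tis <- small_relaxed_tissue(n = 25, seed = 3)
  # displace vertices so forces are O(1) rather than near machine zero
  set.seed(1)
  tis$vx <- (tis$vx + rnorm(length(tis$vx), 0, 0.02)) %% tis$box[1]
  tis$vy <- (tis$vy + rnorm(length(tis$vy), 0, 0.02)) %% tis$box[2]
  gam <- 0.2
  F <- vertex_forces(tis, gam)
  h <- 1e-6
  for (k in sample(length(tis$vx), 12)) {
    for (d in 1:2) {
      tp <- tis; tm <- tis
      if (d == 1) { tp$vx[k] <- tp$vx[k] + h; tm$vx[k] <- tm$vx[k] - h }
      else        { tp$vy[k] <- tp$vy[k] + h; tm$vy[k] <- tm$vy[k] - h }
      fd <- -(tissue_energy(tp, gam) - tissue_energy(tm, gam)) / (2 * h)
      expect_lt(abs(F[k, d] - fd), 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("forces are invariant under uniform translation", {
  tis <- small_relaxed_tissue(n = 25, seed = 5)
  F1 <- vertex_forces(tis, 0.1)
  tis$vx <- (tis$vx + 0.731) %% tis$box[1]
  tis$vy <- (tis$vy + 1.113) %% tis$box[2]
  F2 <- vertex_forces(tis, 0.1)
  expect_equal(F1, F2, tolerance = 1e-9)
})

test_that("forces vanish at a relaxed minimum and noise-free steps are inert", {
  tis <- nine_square_tissue()
  F <- vertex_forces(tis, 0)
  expect_lt(max(abs(F)), 1e-12)
  p0 <- me_params(temperature = 0)
  t2 <- euler_step(tis, 0, p0)
  expect_equal(t2$vx, tis$vx, tolerance = 1e-14)
  expect_equal(t2$vy, tis$vy, tolerance = 1e-14)
})

test_that("Brownian step displacements have variance 2*mu*T*dt", {
  # zero spring constants isolate the noise term
  tis <- nine_square_tissue()
  p <- me_params(K_A = 0, K_P = 0, temperature = 0.010)
  set.seed(11)
  disp <- replicate(2500, {
    t2 <- euler_step(tis, 0, p)
    dx <- t2$vx - tis$vx
    wrap_d(dx, tis$box[1])
  })
  v <- var(as.numeric(disp))
  expected <- 2 * p$mu * p$temperature * p$dt
  n <- length(disp)
  se <- expected * sqrt(2 / (n - 1))
  expect_lt(abs(v - expected), 3 * se)
  expect_equal(mean(as.numeric(disp)), 0, tolerance = 3 * sqrt(expected / n))
})

test_that("zero-temperature dynamics relax the energy monotonically", {
  tis <- small_relaxed_tissue(n = 25, seed = 9)
  set.seed(2)
  k <- sample(length(tis$vx), 1)
  tis$vx[k] <- tis$vx[k] + 0.05   # perturb one vertex
  E <- tissue_energy(tis, 0)
  for (i in 1:20) {
    tis <- euler_step(tis, 0, me_params(temperature = 0))
    E2 <- tissue_energy(tis, 0)
    expect_lte(E2, E + 1e-12)
    E <- E2
  }
})

test_that("junction tension matches the dE/dl finite-difference oracle", {
  # In the square grid with areas at target, axial displacement of an
  # edge's endpoints changes, to first order, only the lengths of that
  # edge and of its two collinear continuations (the perpendicular flanks
  # are first-order invariant and the area term has zero gradient). With
  # the perimeter strain localized to the two cells sharing the target
  # edge, the continuation edges carry zero tension, so central
  # differences of the total energy give dE/dl of the target edge alone.
  base <- nine_square_tissue()
  et0 <- edge_table(base, 0)
  eps <- 1e-6
  set.seed(6)
  for (r in sample(nrow(et0), 5)) {
    tis <- base
    cells <- c(et0$c1[r], et0$c2[r])
    tis$P0[cells] <- 3.6            # strained pair: tension 2*(4-3.6)*2
    a <- et0$a[r]; b <- et0$b[r]
    dx <- wrap_d(tis$vx[b] - tis$vx[a], tis$box[1])
    dy <- wrap_d(tis$vy[b] - tis$vy[a], tis$box[2])
    l <- sqrt(dx^2 + dy^2)
    ux <- dx / l; uy <- dy / l
    stretch <- function(s) {
      t2 <- tis
      t2$vx[a] <- t2$vx[a] - s * ux / 2; t2$vy[a] <- t2$vy[a] - s * uy / 2
      t2$vx[b] <- t2$vx[b] + s * ux / 2; t2$vy[b] <- t2$vy[b] + s * uy / 2
      tissue_energy(t2, 0)
    }
    dEdl <- (stretch(eps) - stretch(-eps)) / (2 * eps)
    tens <- junction_tension(tis, c(a, b), 0)
    expect_equal(tens, 2 * (4 - 3.6) * 2, tolerance = 1e-9)
    expect_equal(tens, dEdl, tolerance = 1e-3)
  }
})

test_that("tension is zero at target geometry and gamma on the boundary", {
  tis <- nine_square_striped()
  g0 <- 0.42
  et <- edge_table(tis, g0)
  expect_equal(et$tension[!et$het], rep(0, sum(!et$het)), tolerance = 1e-12)
  expect_equal(et$tension[et$het], rep(g0, sum(et$het)), tolerance = 1e-12)
})

test_that("junction tensions share sign with the perimeter strain", {
  # inflated preferred perimeters -> all junctions compressed
  tis <- nine_square_tissue(P0 = rep(5, 9))
  et <- edge_table(tis, 0)
  expect_true(all(et$tension < 0))
  # squeezed preferred perimeters -> all junctions tensile
  tis <- nine_square_tissue(P0 = rep(3, 9))
  et <- edge_table(tis, 0)
  expect_true(all(et$tension > 0))
})

test_that("cell areas tile the box through dynamics and T1s", {
  tis <- small_relaxed_tissue(n = 36, seed = 21)
  set.seed(3)
  res <- advance_tissue(tis, 0.25, 1500, me_params())
  g <- cell_geometry(res$tissue)
  expect_equal(sum(g$area), prod(res$tissue$box), tolerance = 1e-9)
  expect_valid_tissue(res$tissue)
})
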