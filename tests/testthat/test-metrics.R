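# Boundary roughness, AUC statistic, self-overlap, MSD, density, tension
# summaries and the group-comparison wrappers.

test_that("roughness closed forms: line, sinusoid, invariances", {
  x <- seq(0, 100, length.out = 2001)
  # straight boundary at a slope -> 0
  line <- data.frame(x = x, y = 0.5 * x + 3)
  expect_lt(boundary_roughness(line), 1e-10)
  # vertical boundary (degenerate orientation)
  vert <- data.frame(x = rep(2, 101), y = seq(0, 10, length.out = 101))
  expect_lt(boundary_roughness(vert), 1e-10)
  # sinusoid over whole periods: rms = a / sqrt(2)
  a <- 1.7
  sine <- data.frame(x = x, y = a * sin(2 * pi * x / 20))
  # the rotation by the fitted slope (nonzero even over whole periods,
  # from the x * sin boundary term) deflates the rms by about 1%
  expect_equal(boundary_roughness(sine), a / sqrt(2), tolerance = 2e-2)
  # offset invariance (detrending) and rotation invariance
  expect_equal(boundary_roughness(transform(sine, y = y + 11)),
               boundary_roughness(sine), tolerance = 1e-9)
  th <- 25 * pi / 180
  rot <- data.frame(x = cos(th) * sine$x - sin(th) * sine$y,
                    y = sin(th) * sine$x + cos(th) * sine$y)
  expect_equal(boundary_roughness(rot), boundary_roughness(sine),
               tolerance = 5e-3)
})

test_that("relative roughness is 1 at t0 and scale invariant", {
  set.seed(3)
  frames <- lapply(1:5, function(f) {
    x <- seq(0, 50, length.out = 200)
    list(data.frame(x = x, y = f * 0.1 * sin(2 * pi * x / 10)))
  })
  cur <- relative_roughness_curve(frames, times = 0:4)
  expect_equal(cur$relative[1], 1)
  scaled <- lapply(frames, function(tr) list(transform(tr[[1]], x = 2 * x,
                                                       y = 2 * y)))
  cur2 <- relative_roughness_curve(scaled, times = 0:4)
  expect_equal(cur2$relative, cur$relative, tolerance = 1e-9)
  expect_equal(cur$relative, (1:5) / 1, tolerance = 1e-3)
})

test_that("roughness AUC matches trapezoids and re-anchors at the window", {
  # constant curve -> 0
  const <- data.frame(time = 0:10, relative = rep(2, 11))
  expect_equal(roughness_auc(const, 0, 10), 0)
  # linear rise 1 -> 1.4 over 0..10: triangle area 0.4 * 10 / 2 = 2
  lin <- data.frame(time = 0:10, relative = 1 + 0.04 * (0:10))
  expect_equal(roughness_auc(lin, 0, 10), 2, tolerance = 1e-12)
  # flat after 10 -> window 10..40 gives 0 regardless of earlier rise
  curve <- data.frame(time = 0:40,
                      relative = c(1 + 0.04 * (0:10), rep(1.4, 30)))
  expect_equal(roughness_auc(curve, 10, 40), 0, tolerance = 1e-12)
  # additivity over adjacent windows after re-anchoring
  set.seed(4)
  wig <- data.frame(time = 0:40, relative = 1 + cumsum(rnorm(41, 0, 0.01)))
  v0 <- wig$relative[wig$time == 0]
  vm <- wig$relative[wig$time == 15]
  full <- roughness_auc(wig, 0, 40)
  a <- roughness_auc(wig, 0, 15)
  b <- roughness_auc(wig, 15, 40)
  # re-anchoring removes a rectangle (v_mid - v_start) * width
  expect_equal(a + b + (vm - v0) * 25, full, tolerance = 1e-9)
})

test_that("self-overlap counts static cells and clamps to [0, 1]", {
  tt <- 0:3
  mk <- function(id, xs) data.frame(cell_id = id, time = tt, x = xs, y = 0,
                                    type = "ectoderm_pre", divided = FALSE)
  # half the cells jump 10 um at t >= 1, half stay: Q = 0.5
  tracks <- rbind(mk(1, c(0, 10, 10, 10)), mk(2, c(0, 0, 0, 0)),
                  mk(3, c(5, 15, 15, 15)), mk(4, c(5, 5, 5, 5)))
  Q <- self_overlap(tracks, a = 4)
  expect_equal(Q$Q, c(1, 0.5, 0.5, 0.5))
  expect_true(all(Q$Q >= 0 & Q$Q <= 1))
  # all displaced beyond the radius -> 0; displacement exactly a counts out
  tracks2 <- rbind(mk(1, c(0, 5, 5, 5)), mk(2, c(0, 4, 4, 4)))
  expect_equal(self_overlap(tracks2, a = 4)$Q, c(1, 0, 0, 0))
  # rigid translation of all tracks leaves Q unchanged
  tracks3 <- tracks
  tracks3$x <- tracks3$x + 100; tracks3$y <- tracks3$y - 50
  expect_equal(self_overlap(tracks3, a = 4)$Q, Q$Q)
})

test_that("divided cells are excluded from mobility metrics", {
  tt <- 0:2
  mk <- function(id, div) data.frame(cell_id = id, time = tt, x = 0, y = 0,
                                     type = "ectoderm_pre", divided = div)
  tracks <- rbind(mk(1, FALSE), mk(2, TRUE))
  expect_equal(unique(self_overlap(tracks)$n), 1)
})

test_that("overlap half-time interpolates the Q = 0.5 crossing", {
  # never decreases -> NA ("no-decrease")
  expect_true(is.na(overlap_halftime(data.frame(time = 0:10, Q = 1))))
  # linear decay 1 -> 0 over 60 min: crossing at 30
  lin <- data.frame(time = seq(0, 60, 4), Q = 1 - seq(0, 60, 4) / 60)
  expect_equal(overlap_halftime(lin), 30)
  # crossing between samples at 20 and 24 with Q 0.6 -> 0.4: 22 min
  s <- data.frame(time = c(0, 20, 24), Q = c(1, 0.6, 0.4))
  expect_equal(overlap_halftime(s), 22)
})

test_that("MSD closed forms and the axis decomposition identity", {
  tt <- 0:10
  # ballistic motion along AP at v = 2 um/min
  v <- 2
  tracks <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(cell_id = i, time = tt, x = i + v * tt, y = i,
               type = "ectoderm_pre", divided = FALSE)
  }))
  M <- msd(tracks, register = FALSE)
  expect_equal(M$msd, (v * tt)^2, tolerance = 1e-12)
  expect_equal(M$msd_dv, rep(0, length(tt)))
  expect_equal(M$msd_ap + M$msd_dv, M$msd, tolerance = 1e-12)
  expect_equal(M$msd[1], 0)
})

test_that("mesectoderm registration removes rigid drift", {
  tt <- 0:10
  drift <- 3 * tt
  ecto <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(cell_id = i, time = tt, x = i * 10 + drift, y = drift,
               type = "ectoderm_pre", divided = FALSE)
  }))
  mes <- do.call(rbind, lapply(5:7, function(i) {
    data.frame(cell_id = i, time = tt, x = i + drift, y = 50 + drift,
               type = "mesectoderm", divided = FALSE)
  }))
  M <- msd(rbind(ecto, mes), register = TRUE)
  expect_equal(max(M$msd), 0, tolerance = 1e-18)
  Q <- self_overlap(register_tracks(rbind(ecto, mes)), a = 4)
  expect_equal(Q$Q, rep(1, length(tt)))
})

test_that("track unwrapping reconstructs continuous trajectories", {
  L <- 10
  # a cell walking right across the periodic seam
  xw <- c(8, 9, 0.5, 1.5)
  tracks <- data.frame(cell_id = 1, time = 0:3, x = xw, y = 1,
                       type = "ectoderm_pre", divided = FALSE)
  un <- unwrap_tracks(tracks, c(L, L))
  expect_equal(un$x, c(8, 9, 10.5, 11.5))
})

test_that("cell density counts per 100 square micrometres", {
  pts <- data.frame(x = runif(10, 0, 100) * 0 + seq(5, 95, 10),
                    y = rep(5, 10))
  # 10 cells in a 100 x 10 region = 1000 um^2 -> 1 per 100 um^2
  expect_equal(cell_density(pts, c(0, 100, 0, 10)), 1)
  # doubling the region with the same pattern density leaves it unchanged
  pts2 <- rbind(pts, transform(pts, y = y + 10))
  expect_equal(cell_density(pts2, c(0, 100, 0, 20)), 1)
})

test_that("group comparisons dispatch to the right tests", {
  set.seed(10)
  # identical groups -> omnibus p near 1
  v <- rep(c(1, 2, 3, 4, 5), 3)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- group_compare(v, g)
  expect_equal(res$omnibus$method, "kruskal_wallis")
  expect_gt(res$omnibus$p_value, 0.95)
  # 4 groups -> 6 Dunn comparisons
  v4 <- rnorm(40); g4 <- rep(letters[1:4], each = 10)
  expect_equal(nrow(group_compare(v4, g4)$pairwise), 6)
  # two clearly shifted groups -> Mann-Whitney p < 0.001
  x <- rnorm(50); y <- rnorm(50) + 10
  res2 <- group_compare(c(x, y), rep(c("ctl", "trt"), each = 50))
  expect_equal(res2$omnibus$method, "mann_whitney")
  expect_lt(res2$omnibus$p_value, 1e-3)
  expect_equal(res2$pairwise$direction, -1)
  # paired dispatch
  res3 <- group_compare(c(x, x + 1), rep(c("pre", "post"), each = 50),
                        paired = TRUE)
  expect_equal(res3$omnibus$method, "wilcoxon_signed_rank")
})

test_that("Dunn z statistics agree with a direct two-group rank computation", {
  set.seed(12)
  v <- c(rnorm(8), rnorm(9, 1), rnorm(7, 2))
  g <- rep(c("a", "b", "c"), c(8, 9, 7))
  d <- dunn_test(v, g, p_adjust = "none")
  # independent recomputation for the a-b pair
  N <- length(v); r <- rank(v)
  ties <- table(r)
  se <- sqrt((N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))) *
             (1 / 8 + 1 / 9))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], z_ab,
               tolerance = 1e-12)
})

test_that("ensemble summary computes mean, sem and percent changes", {
  c1 <- data.frame(time = 0:2, v = c(1, 1, 0.9))
  c2 <- data.frame(time = 0:2, v = c(1, 1, 1.1))
  es <- ensemble_summary(list(c1, c2), "v", endpoints = 2)
  expect_equal(es$summary$mean, c(1, 1, 1))
  expect_equal(es$summary$sem[3], 0.1, tolerance = 1e-12)
  expect_equal(es$summary$sem[1], 0)
  expect_equal(sort(es$endpoints$percent_change), c(-10, 10))
  # identical replicates -> sem 0
  es2 <- ensemble_summary(list(c1, c1), "v")
  expect_equal(max(es2$summary$sem), 0)
})
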