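# Synthetic-data generators: ground truth is returned with the data and
# recovered by the measurement layer.

test_that("synthetic boundaries reproduce the sinusoid roughness", {
  syn <- make_boundary_series(amplitude = 2, wavelength = 20, extent = 200,
                              n_points = 2000, frames = 3, noise_sd = 0,
                              seed = 1)
  r <- vapply(syn$traces, boundary_roughness, numeric(1))
  expect_equal(r, rep(2 / sqrt(2), 3), tolerance = 5e-3)
  # zero amplitude: measured roughness ~ localization noise sigma
  syn0 <- make_boundary_series(amplitude = 0, noise_sd = 0.2,
                               n_points = 4000, frames = 2, seed = 2)
  r0 <- boundary_roughness(syn0$traces[[1]])
  expect_equal(r0, 0.2, tolerance = 0.02)
  # per-frame rigid rotation leaves the roughness curve unchanged
  synr <- make_boundary_series(amplitude = 1.5, rotate_deg = seq(0, 40, 10),
                               frames = 5, noise_sd = 0, n_points = 1000,
                               seed = 3)
  rr <- vapply(synr$traces, boundary_roughness, numeric(1))
  expect_lt(max(rr) - min(rr), 0.02)
  # the stored truth matches the measurement
  expect_equal(unique(syn$truth$roughness_expected), 2 / sqrt(2))
})

test_that("diffusive tracks recover MSD = 4 D t", {
  Dc <- 0.25
  syn <- make_track_table(n_cells = 300, frames = 41, mobility = "diffusive",
                          D_um2_min = Dc, noise_sd = 0, seed = 5)
  M <- msd(syn$tracks, register = FALSE)
  late <- M$time >= 10
  slope <- coef(lm(M$msd[late] ~ M$time[late]))[2]
  expect_equal(unname(slope), 4 * Dc, tolerance = 0.15)
})

test_that("static cells under drift freeze after registration", {
  syn <- make_track_table(n_cells = 30, frames = 21, mobility = "static",
                          drift_um_min = c(1, -0.5), noise_sd = 0, seed = 6)
  reg <- register_tracks(syn$tracks)
  Q <- self_overlap(reg, a = 4)
  expect_equal(Q$Q, rep(1, 21))
  # without registration the drift carries everyone past the radius
  Qraw <- self_overlap(syn$tracks, a = 4)
  expect_lt(min(Qraw$Q), 0.5)
})

test_that("half static, half ballistic crosses Q = 0.5 at the design time", {
  # ballistic cells cross the 4 um radius at t* = 4 / v
  v <- 0.5; tstar <- 4 / v
  mov <- make_track_table(n_cells = 120, frames = 41,
                          mobility = "ballistic", v_um_min = v,
                          noise_sd = 0, n_mesec = 0, seed = 8)$tracks
  sta <- make_track_table(n_cells = 80, frames = 41, mobility = "static",
                          noise_sd = 0, n_mesec = 0, seed = 9)$tracks
  sta$cell_id <- sta$cell_id + 1000
  Q <- self_overlap(rbind(mov, sta), a = 4)
  ht <- overlap_halftime(Q)
  expect_equal(ht, tstar, tolerance = 0.15)
})

test_that("generators are byte-identical under a fixed seed", {
  a <- make_boundary_series(amplitude = 1, frames = 3, seed = 11)
  b <- make_boundary_series(amplitude = 1, frames = 3, seed = 11)
  expect_identical(a, b)
  x <- make_track_table(n_cells = 10, frames = 5, mobility = "diffusive",
                        seed = 12)
  y <- make_track_table(n_cells = 10, frames = 5, mobility = "diffusive",
                        seed = 12)
  expect_identical(x, y)
  r1 <- make_recoil_set(n = 3, seed = 13)
  r2 <- make_recoil_set(n = 3, seed = 13)
  expect_identical(r1, r2)
})

test_that("two-group power and type-I behaviour are as designed", {
  # groups differing 24% in D with study-sized n: detected in most draws
  hits <- vapply(1:20, function(i) {
    syn <- make_recoil_set(n = c(35, 32), D_mean = c(2, 2.48),
                           tau_mean = 8, cv = 0.15, noise_sd = 0.05,
                           groups = c("ctl", "trt"), seed = 100 + i)
    fits <- fit_recoil_set(syn$data)
    group_compare(fits$D, fits$group)$omnibus$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.7)
  # null design: approximately nominal type-I error
  null_p <- vapply(1:20, function(i) {
    syn <- make_recoil_set(n = c(20, 20), D_mean = 2, tau_mean = 8,
                           cv = 0.15, noise_sd = 0.05,
                           groups = c("a", "b"), seed = 200 + i)
    fits <- fit_recoil_set(syn$data)
    group_compare(fits$D, fits$group)$omnibus$p_value
  }, numeric(1))
  expect_lt(mean(null_p < 0.05), 0.25)
})
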