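# Initialization, schedules, division scheduling and scenario runs.
# Small tissues and short horizons keep these fast; the full-scale study
# conditions live in the analysis scripts.

test_that("initialization builds a valid labelled tissue", {
  sch <- me_schedule()
  tis <- initialize_tissue(100, seed = 2, schedule = sch, relax_tau = 20)
  expect_equal(length(tis$loops), 100)
  g <- cell_geometry(tis)
  expect_equal(sum(g$area), prod(tis$box), tolerance = 1e-9)
  expect_valid_tissue(tis)
  # stripe labelled and bidisperse ectoderm split
  expect_gt(sum(tis$type == "mesectoderm"), 0)
  n_pre <- sum(tis$type == "ectoderm_pre")
  n_post <- sum(tis$type == "ectoderm_post")
  expect_lte(abs(n_pre - n_post), 1)
  # shape index q holds exactly at assignment for every cell
  expect_equal(tis$P0 / sqrt(tis$A0),
               rep(me_params()$q, 100), tolerance = 1e-12)
  # preferred areas follow the type assignment
  expect_equal(unname(tis$A0[tis$type == "mesectoderm"][1]), sch$A0_mesec0)
  expect_equal(unname(tis$A0[tis$type == "ectoderm_pre"][1]),
               sch$A0_ecto_pre)
  # determinism: same seed, identical tissue
  tis2 <- initialize_tissue(100, seed = 2, schedule = sch, relax_tau = 20)
  expect_identical(tis$vx, tis2$vx)
  expect_identical(tis$loops, tis2$loops)
  expect_identical(tis$type, tis2$type)
})

test_that("an empty mesectoderm stripe is a configuration error", {
  expect_error(initialize_tissue(36, seed = 1, relax_tau = 0,
                                 stripe_halfwidth = 1e-9),
               "stripe")
})

test_that("gamma schedule: exponential decay and acute loss", {
  sch <- me_schedule(gamma0 = 0.4, k_gamma = 0.1)
  expect_equal(gamma_at(0, sch), 0.4)
  expect_equal(gamma_at(1 / 0.1, sch), 0.4 / exp(1))
  off <- me_flags(boundary_tension_on = FALSE)
  expect_equal(gamma_at(0.1, sch, off), 0)
  expect_equal(gamma_at(c(0, 5, 10), sch),
               0.4 * exp(-0.1 * c(0, 5, 10)))
  # non-increasing
  g <- gamma_at(seq(0, 40, 0.5), sch)
  expect_true(all(diff(g) <= 0))
})

test_that("mesectoderm preferred-area schedule constricts linearly", {
  sch <- me_schedule(A0_mesec0 = 1, A0_mesec_end_frac = 0.4,
                     t_constrict_min = 40)
  expect_equal(a0_mesec_at(0, sch), 1)
  expect_equal(a0_mesec_at(20, sch), 0.7)
  expect_equal(a0_mesec_at(40, sch), 0.4)
  expect_equal(a0_mesec_at(60, sch), 0.4)   # constant after the ramp
  held <- me_flags(constrain_apical_constriction = TRUE)
  expect_equal(a0_mesec_at(30, sch, held), 1)
})

test_that("division scheduling respects rates, blocks and regions", {
  tis <- small_relaxed_tissue(n = 64, seed = 17)
  sch <- me_schedule(division_rate = 5)
  set.seed(1)
  # rate zero -> empty
  expect_equal(nrow(schedule_divisions(tis, 0, 1,
                                       me_schedule(division_rate = 0))), 0)
  # no-division flag blocks only after the block time
  off <- me_flags(divisions_on = FALSE)
  expect_equal(nrow(schedule_divisions(tis, 6, 1, sch, off)), 0)
  set.seed(2)
  expect_gt(nrow(schedule_divisions(tis, 0, 1, sch)), 0)
  # region restriction: near-boundary-only divisions are boundary adjacent
  set.seed(3)
  adj <- boundary_adjacent_cells(tis)
  near <- schedule_divisions(tis, 0, 4, sch,
                             me_flags(division_region = "near_boundary_only"))
  expect_true(all(near$cell %in% adj))
  far <- schedule_divisions(tis, 0, 4, sch,
                            me_flags(division_region = "far_only"))
  expect_true(all(!far$cell %in% adj))
  expect_equal(nrow(schedule_divisions(tis, 0, 4, sch,
                                       me_flags(division_region = "none"))), 0)
  # only pre-division ectoderm cells are selected
  many <- schedule_divisions(tis, 0, 10, sch)
  expect_true(all(tis$type[many$cell] == "ectoderm_pre"))
})

test_that("boundary-adjacent spindles align with the DV axis in vivo mode", {
  tis <- small_relaxed_tissue(n = 64, seed = 19)
  sch <- me_schedule(division_rate = 500)   # select many cells at once
  adj <- boundary_adjacent_cells(tis)
  set.seed(7)
  d <- do.call(rbind, lapply(1:40, function(i)
    schedule_divisions(tis, 0, 1, sch)))
  near <- d$angle[d$cell %in% adj]
  fari <- d$angle[!d$cell %in% adj]
  # circular spread about DV is tighter for boundary-adjacent divisions
  dev_near <- abs(near - pi / 2)
  spread_far <- sd(fari)
  expect_lt(mean(dev_near), 0.35)           # concentrated near 90 degrees
  expect_gt(spread_far, 0.5)                # roughly uniform
})

test_that("short scenario runs are deterministic and bookkept", {
  cfg <- scenario_config(n_cells = 64, seed = 5, horizon_min = 3,
                         equil_min = 1, relax_tau_init = 20,
                         schedule = me_schedule(division_rate = 3),
                         store_tissues = "ends")
  rec <- run_scenario(cfg)
  expect_s3_class(rec, "me_record")
  expect_equal(rec$times, 0:3)
  expect_length(rec$frames, 4)
  expect_length(rec$boundary, 4)
  # byte-identical rerun under the same seed
  rec2 <- run_scenario(cfg)
  expect_identical(rec$frames, rec2$frames)
  expect_identical(rec$tension, rec2$tension)
  expect_identical(rec$events, rec2$events)
  # division bookkeeping: final count = initial + divisions
  ndiv <- sum(rec$events$event == "division")
  expect_equal(nrow(rec$frames[[4]]), 64 + ndiv)
  # gamma non-increasing over the horizon is reflected in stored config
  g <- gamma_at(rec$times, cfg$schedule, cfg$flags)
  expect_true(all(diff(g) <= 0))
})

test_that("no-division scenarios keep the cell count fixed", {
  cfg <- scenario_config(n_cells = 64, seed = 6, horizon_min = 2,
                         equil_min = 0.5, relax_tau_init = 20,
                         flags = "no_division",
                         schedule = me_schedule(division_rate = 3,
                                                block_time = 0))
  rec <- run_scenario(cfg)
  expect_equal(sum(rec$events$event == "division"), 0)
  expect_equal(nrow(rec$frames[[3]]), 64)
})

test_that("apical constriction shrinks mesectoderm preferred area in runs", {
  cfg <- scenario_config(n_cells = 64, seed = 8, horizon_min = 4,
                         equil_min = 0, relax_tau_init = 10,
                         schedule = me_schedule(division_rate = 0,
                                                A0_mesec_end_frac = 0.4,
                                                t_constrict_min = 4),
                         store_tissues = "ends")
  rec <- run_scenario(cfg)
  tis_end <- rec$tissues[["4"]]
  mi <- tis_end$type == "mesectoderm"
  expect_equal(unique(tis_end$A0[mi]), 0.4, tolerance = 1e-12)
  # mean mesectoderm area decreases over the run
  a0 <- mean(rec$frames[[1]]$area[rec$frames[[1]]$type == "mesectoderm"])
  a1 <- mean(rec$frames[[5]]$area[rec$frames[[5]]$type == "mesectoderm"])
  expect_lt(a1, a0)
})

test_that("track tables carry types, division flags and unwrap correctly", {
  cfg <- scenario_config(n_cells = 64, seed = 9, horizon_min = 2,
                         equil_min = 0.5, relax_tau_init = 20,
                         schedule = me_schedule(division_rate = 2))
  rec <- run_scenario(cfg)
  tr <- track_table(rec)
  expect_true(all(c("cell_id", "time", "x", "y", "type", "divided",
                    "boundary_adjacent") %in% names(tr)))
  # one row per cell per frame
  expect_false(any(duplicated(tr[, c("cell_id", "time")])))
  # micrometre scale: mean cell area ~ pi * (4 um)^2 by calibration
  um <- cfg$um_per_unit
  expect_equal(um, 4 / sqrt(1 / pi))
})
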