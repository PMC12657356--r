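test_that("alignment is the identity for a trial already in the pelvis frame", {
  tr <- static_trial()
  out <- align_to_pelvis(tr)
  expect_equal(out$coords, tr$coords, tolerance = 1e-9)
})

test_that("a half-turned pelvis maps a forward point to the rear", {
  tr <- rotate_trial_z(static_trial(n_frames = 1), 180)
  # place a marker 1 m forward of the (rotated) pelvis in global coordinates
  tr$coords[1, "head_top", ] <- tr$coords[1, "pelvis_origin", ] + c(1000, 0, 0)
  out <- align_to_pelvis(tr)
  rel <- out$coords[1, "head_top", ] - out$coords[1, "pelvis_origin", ]
  expect_equal(unname(rel), c(-1000, 0, 0), tolerance = 1e-6)
})

test_that("alignment is equivariant under a constant global heading", {
  g <- generate_trial(sim_config(n_cycles = 2, noise_sd_mm = 0,
                                 drift_mm_per_s = 0, seed = 12))
  a <- align_to_pelvis(g$trial)
  b <- align_to_pelvis(rotate_trial_z(g$trial, 90))
  expect_equal(b$coords, a$coords, tolerance = 1e-6)
})

test_that("alignment rotations are proper (determinant +1)", {
  g <- generate_trial(sim_config(n_cycles = 1, seed = 13))
  al <- align_to_pelvis(g$trial)
  ax <- al$alignment$rotation
  for (i in c(1, 50, length(g$trial$time_s))) {
    R <- cbind(ax$x[i, ], ax$y[i, ], ax$z[i, ])
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("degenerate pelvis geometry is reported with its frame index", {
  tr <- static_trial(n_frames = 3)
  tr$coords[2, "asis_r", ] <- tr$coords[2, "asis_l", ] # ML axis collapses
  expect_error(align_to_pelvis(tr), "frame 2")
})

test_that("T12 referencing zeroes T12 and preserves inter-point vectors", {
  g <- generate_trial(sim_config(n_cycles = 2, seed = 14))
  ref <- reference_to_t12(g$trial)
  expect_equal(max(abs(ref$coords[, "t12", ])), 0)
  v_before <- g$trial$coords[, "toe_l", ] - g$trial$coords[, "t12", ]
  v_after <- ref$coords[, "toe_l", ] - ref$coords[, "t12", ]
  expect_equal(v_after, v_before, tolerance = 1e-12)
  # translation invariance
  ref2 <- reference_to_t12(offset_trial(g$trial, c(5000, 5000, 5000)))
  expect_equal(ref2$coords, ref$coords, tolerance = 1e-9)
})

test_that("pelvis alignment and T12 referencing commute", {
  g <- generate_trial(sim_config(n_cycles = 2, seed = 15))
  ab <- reference_to_t12(align_to_pelvis(g$trial))
  ba <- align_to_pelvis(reference_to_t12(g$trial))
  expect_equal(ab$coords, ba$coords, tolerance = 1e-9)
})

test_that("a periodic toe loop yields the analytic peak and interval count", {
  # distance from the toe's mean has one maximum per 1.2 s period; a 12 s
  # trial with mid-period maxima holds exactly 10 of them -> 9 cycles
  tr <- toe_loop_trial(duration_s = 12, period_s = 1.2, r0_mm = 60, r1_mm = 40)
  seg <- segment_cycles(tr)
  expect_length(attr(seg, "peaks"), 10)
  expect_equal(nrow(seg), 9)
  expect_true(all(seg$end_frame > seg$start_frame))
  # peaks sit mid-period: t = 0.6 + 1.2 k
  expect_equal(tr$time_s[attr(seg, "peaks")], 0.6 + 1.2 * (0:9),
               tolerance = 0.02)
})

test_that("sub-threshold toe motion yields no cycles", {
  tr <- toe_loop_trial(duration_s = 6, period_s = 1.2, r0_mm = 3, r1_mm = 2)
  seg <- segment_cycles(tr)
  expect_equal(nrow(seg), 0)
  expect_length(attr(seg, "peaks"), 0)
})

test_that("segmentation is invariant to constant offsets of the whole trial", {
  tr <- toe_loop_trial(duration_s = 6, period_s = 1.2, r0_mm = 60, r1_mm = 40)
  seg <- segment_cycles(tr)
  seg2 <- segment_cycles(offset_trial(tr, c(1e5, -2e5, 3e5)))
  expect_equal(attr(seg2, "peaks"), attr(seg, "peaks"))
})

test_that("noise-free simulator boundaries are recovered within 2 frames", {
  for (seed in c(21, 22, 23)) {
    g <- generate_trial(sim_config(technique = "skating", n_cycles = 8,
                                   noise_sd_mm = 0, drift_mm_per_s = 0,
                                   seed = seed))
    al <- reference_to_t12(align_to_pelvis(g$trial))
    seg <- segment_cycles(al)
    pk <- attr(seg, "peaks")
    expect_length(pk, length(g$truth$cycle_boundaries))
    expect_lte(max(abs(pk - g$truth$cycle_boundaries)), 2)
  }
})

test_that("time normalization reproduces linear ramps and constants exactly", {
  tr <- static_trial(n_frames = 50)
  tr$coords[, "hand_l", 1] <- seq(0, 490, by = 10) # linear ramp
  tr$power[, "rta"] <- 7                           # constant
  cy <- time_normalize(tr, 1, 50)
  expect_length(cy$time_norm, 101)
  expect_equal(cy$coords[, "hand_l", 1],
               seq(0, 490, length.out = 101), tolerance = 1e-9)
  expect_equal(cy$coords[1, "hand_l", 1], 0)
  expect_equal(cy$coords[101, "hand_l", 1], 490)
  expect_equal(unname(cy$power[, "rta"]), rep(7, 101))
  expect_gt(cy$duration_s, 0)
})

test_that("time normalization tracks a 240 Hz sinusoid to 1e-3 of amplitude", {
  tr <- static_trial(n_frames = 241)
  amp <- 80
  tr$coords[, "hand_l", 3] <- amp * sin(2 * pi * tr$time_s) # 1 s period
  cy <- time_normalize(tr, 1, 241)
  t_q <- seq(tr$time_s[1], tr$time_s[241], length.out = 101)
  expect_lt(max(abs(cy$coords[, "hand_l", 3] - amp * sin(2 * pi * t_q))),
            1e-3 * amp)
})

test_that("segments shorter than 4 samples are rejected or discarded", {
  tr <- static_trial(n_frames = 10)
  expect_error(time_normalize(tr, 1, 3), "4 samples")
})

test_that("cycle count never exceeds peak count minus one", {
  g <- generate_trial(sim_config(n_cycles = 6, seed = 33))
  pp <- suppressWarnings(preprocess_trial(g$trial))
  expect_lte(nrow(pp$segments), length(attr(pp$segments, "peaks")) - 1)
  expect_length(pp$cycles, nrow(pp$segments))
  expect_true(all(vapply(pp$cycles, function(c) length(c$time_norm), 1L) == 101L))
})

test_that("cadence summary handles strong effects and degenerate groups", {
  # equal durations everywhere: zero variance -> p = 1 by convention
  cs <- cadence_summary(rep(1.0, 40), rep(skill_levels(), each = 10))
  expect_equal(cs$anova$p_value, 1)
  expect_true(all(cs$groups$mean_s == 1))

  # a strong group difference is detected
  dur <- c(rnorm(30, 1.0, 0.02), rnorm(30, 1.5, 0.02))
  sk <- rep(c("beginner", "elite"), each = 30)
  cs2 <- withr::with_seed(1, cadence_summary(dur, sk))
  expect_lt(cs2$anova$p_value, 1e-6)

  # undersized groups are excluded with a warning
  expect_warning(
    cadence_summary(c(rnorm(10), rnorm(10), 1.23),
                    c(rep("beginner", 10), rep("elite", 10), "advanced")),
    "advanced")
})

test_that("cadence F statistic matches the linear-model ANOVA oracle", {
  withr::with_seed(5, {
    dur <- rnorm(60, 1.2, 0.1)
    sk <- sample(rep(skill_levels(), 15))
  })
  cs <- cadence_summary(dur, sk)
  or <- anova(lm(dur ~ factor(sk)))
  expect_equal(cs$anova$f_statistic, or$`F value`[1], tolerance = 1e-10)
  expect_equal(cs$anova$p_value, or$`Pr(>F)`[1], tolerance = 1e-10)
})
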