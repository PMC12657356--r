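test_that("generation is bit-identical under a repeated seed", {
  cfg <- sim_config(technique = "skating", skill = "advanced", n_cycles = 4,
                    seed = 77)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a$trial$coords, b$trial$coords)
  expect_identical(a$trial$power, b$trial$power)
  expect_identical(a$truth$cycle_boundaries, b$truth$cycle_boundaries)
  expect_identical(a$truth$effects, b$truth$effects)
})

test_that("ground truth carries one boundary and one label per cycle", {
  g <- generate_trial(sim_config(technique = "double_pole", n_cycles = 20,
                                 noise_sd_mm = 0, drift_mm_per_s = 0, seed = 2))
  expect_length(g$truth$cycle_boundaries, 20)
  expect_length(g$truth$technique_labels, 20)
  expect_true(all(diff(g$truth$cycle_boundaries) > 0))
  expect_true(all(g$truth$technique_labels == "double_pole"))
})

test_that("skill multipliers move the embedded effects in the right direction", {
  eff <- skill_effect_profile()
  el <- generate_trial(sim_config(skill = "elite", n_cycles = 6, seed = 31), eff)
  be <- generate_trial(sim_config(skill = "beginner", n_cycles = 6, seed = 31), eff)
  expect_true(all(el$truth$effects$peak_upper_wkg >
                    be$truth$effects$peak_upper_wkg))
  expect_true(all(el$truth$effects$peak_lower_wkg >
                    be$truth$effects$peak_lower_wkg))
  expect_true(all(el$truth$effects$frontal_area_m2 <
                    be$truth$effects$frontal_area_m2))
  expect_true(all(el$truth$effects$ski_angle_deg <
                    be$truth$effects$ski_angle_deg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(technique = "telemark"), "telemark")
  expect_error(sim_config(sample_rate_hz = 1), "Nyquist")
  expect_error(sim_config(n_cycles = 0), "n_cycles")
  # noise at 10x the toe template amplitude buries the 1 cm threshold
  expect_error(generate_trial(sim_config(noise_sd_mm = 400)), "bury")
  expect_error(
    skill_effect_profile(technique_mix = list(beginner = c(double_pole = 1))),
    "skill level")
})

test_that("cohorts have the requested size and honour degenerate mixes", {
  eff <- skill_effect_profile()
  co <- generate_cohort(2, eff, seed = 1, n_cycles = 2)
  expect_length(co$trials, 8)
  expect_setequal(unique(co$info$skill), skill_levels())

  mix <- default_technique_mix()
  mix$beginner[] <- 0
  mix$beginner["diagonal_stride"] <- 1
  eff2 <- skill_effect_profile(technique_mix = mix)
  co2 <- generate_cohort(3, eff2, seed = 2, n_cycles = 1)
  expect_true(all(co2$info$technique[co2$info$skill == "beginner"] ==
                    "diagonal_stride"))
})

test_that("empirical technique shares match the configured mix", {
  co <- generate_cohort(50, seed = 7, n_cycles = 1)
  p <- default_technique_mix()$beginner[["diagonal_stride"]]
  share <- mean(co$info$technique[co$info$skill == "beginner"] ==
                  "diagonal_stride")
  se <- sqrt(p * (1 - p) / 50)
  expect_lt(abs(share - p), 3 * se)
})

test_that("embedded effects regress on skill rank with the configured signs", {
  # hold the technique mix fixed (all skating) so the regression isolates the
  # skill multipliers; under a skill-graded mix, technique composition
  # confounds the ski-angle trend (elites skate more, and skating has
  # intrinsically larger ski angles)
  mix <- default_technique_mix()
  for (sk in names(mix)) {
    mix[[sk]][] <- 0
    mix[[sk]]["skating"] <- 1
  }
  eff <- skill_effect_profile(technique_mix = mix)
  co <- generate_cohort(25, eff, seed = 606, n_cycles = 2)
  emb <- do.call(rbind, lapply(seq_along(co$truths), function(i) {
    e <- co$truths[[i]]$effects
    data.frame(rank = match(co$info$skill[i], skill_levels()) - 1,
               up = mean(e$peak_upper_wkg), lo = mean(e$peak_lower_wkg),
               area = mean(e$frontal_area_m2), angle = mean(e$ski_angle_deg))
  }))
  for (v in c("up", "lo", "area", "angle")) {
    fit <- summary(lm(emb[[v]] ~ emb$rank))$coefficients
    expect_lt(fit[2, 4], 0.01) # slope significant
    expected_sign <- if (v %in% c("up", "lo")) 1 else -1
    expect_equal(sign(fit[2, 1]), expected_sign)
  }
})

test_that("GNSS ovals repeat exactly without noise and scale as configured", {
  gn <- generate_gnss_track(3, noise_sd_m = 0, drift_m_per_s = 0,
                            rate_hz = 4, lap_time_s = 150, seed = 1)
  m <- 4 * 150
  expect_equal(gn$lap_boundaries, c(1L, 1L + m, 1L + 2L * m))
  expect_equal(nrow(gn$series), 3 * m)
  lap1 <- gn$series[1:m, c("x_m", "y_m", "elev_m")]
  lap2 <- gn$series[(m + 1):(2 * m), c("x_m", "y_m", "elev_m")]
  lap3 <- gn$series[(2 * m + 1):(3 * m), c("x_m", "y_m", "elev_m")]
  expect_equal(lap2, lap1, ignore_attr = TRUE)
  expect_equal(lap3, lap1, ignore_attr = TRUE)
  # elevation range equals the configured change (noise-free)
  expect_equal(diff(range(gn$series$elev_m)), 20, tolerance = 1e-2)
  # lap length honoured by construction
  arc <- sum(sqrt(diff(lap1$x_m)^2 + diff(lap1$y_m)^2))
  expect_equal(arc, 600, tolerance = 1)
})
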