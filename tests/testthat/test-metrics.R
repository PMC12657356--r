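# frame (76 x 3, mm) where both body boxes have known extents
boxed_frame <- function(upper_ml = 400, upper_v = 600,
                        lower_ml = 300, lower_v = 800) {
  pm <- point_model()
  fr <- matrix(0, 76, 3, dimnames = list(pm$label, c("x", "y", "z")))
  up <- pm$label[pm$group == "upper_body"]
  lo <- pm$label[pm$group == "lower_body"]
  fr[up, 2] <- seq(0, upper_ml, length.out = length(up))
  fr[up, 3] <- 1000 + seq(0, upper_v, length.out = length(up))
  fr[lo, 2] <- seq(0, lower_ml, length.out = length(lo))
  fr[lo, 3] <- seq(0, lower_v, length.out = length(lo))
  fr
}

test_that("frontal area sums the two analytic rectangles", {
  fr <- boxed_frame(400, 600, 300, 800)
  expect_equal(frontal_area(fr), 0.4 * 0.6 + 0.3 * 0.8, tolerance = 1e-12)
})

test_that("degenerate point groups contribute zero area", {
  pm <- point_model()
  fr <- matrix(0, 76, 3, dimnames = list(pm$label, c("x", "y", "z")))
  fr[, 3] <- seq_len(76) # collinear along the vertical axis
  expect_equal(frontal_area(fr), 0)
})

test_that("tucked postures occupy less frontal area than upright ones", {
  tuck <- generate_trial(sim_config(technique = "free_glide", n_cycles = 2,
                                    noise_sd_mm = 0, drift_mm_per_s = 0,
                                    seed = 21))
  stand <- generate_trial(sim_config(technique = "standing_glide", n_cycles = 2,
                                     noise_sd_mm = 0, drift_mm_per_s = 0,
                                     seed = 21))
  expect_lt(mean(tuck$truth$effects$frontal_area_m2),
            mean(stand$truth$effects$frontal_area_m2))
})

test_that("frontal area is invariant to pre-alignment rigid motion", {
  g <- generate_trial(sim_config(n_cycles = 2, noise_sd_mm = 0,
                                 drift_mm_per_s = 0, seed = 22))
  pp1 <- preprocess_trial(g$trial)
  moved <- offset_trial(rotate_trial_z(g$trial, 135), c(4e4, -2e4, 1e3))
  pp2 <- preprocess_trial(moved)
  a1 <- frontal_area_series(pp1$cycles[[1]])
  a2 <- frontal_area_series(pp2$cycles[[1]])
  expect_equal(a2, a1, tolerance = 1e-6)
})

test_that("ski angle is zero when parallel and signed outward when rotated", {
  pm <- point_model()
  cyc <- list(coords = array(0, c(1, 76, 3),
                             dimnames = list(NULL, pm$label, c("x", "y", "z"))))
  # both skis parallel to the forward axis
  cyc$coords[1, "ski_tip_l", ] <- c(900, 90, 0)
  cyc$coords[1, "ski_tail_l", ] <- c(-600, 90, 0)
  cyc$coords[1, "ski_tip_r", ] <- c(900, -90, 0)
  cyc$coords[1, "ski_tail_r", ] <- c(-600, -90, 0)
  expect_equal(ski_angle_series(cyc, "l"), 0)
  expect_equal(ski_angle_series(cyc, "r"), 0)

  # left ski rotated 30 degrees outward (tip toward +y)
  a <- 30 * pi / 180
  cyc$coords[1, "ski_tip_l", 1:2] <- 1500 * c(cos(a), sin(a)) + c(-600, 90)
  cyc$coords[1, "ski_tail_l", 1:2] <- c(-600, 90)
  expect_equal(ski_angle_series(cyc, "l"), 30, tolerance = 1e-9)

  # mirror about the sagittal plane with side swap: angle is preserved,
  # i.e. the raw signed angle is antisymmetric under reflection
  mirrored <- cyc
  mirrored$coords[, , 2] <- -mirrored$coords[, , 2]
  tmp <- mirrored$coords[, c("ski_tip_l", "ski_tail_l"), ]
  mirrored$coords[, c("ski_tip_l", "ski_tail_l"), ] <-
    mirrored$coords[, c("ski_tip_r", "ski_tail_r"), ]
  mirrored$coords[, c("ski_tip_r", "ski_tail_r"), ] <- tmp
  expect_equal(ski_angle_series(mirrored, "r"), 30, tolerance = 1e-9)
})

test_that("vertical skis are skipped with a warning", {
  pm <- point_model()
  cyc <- list(coords = array(0, c(1, 76, 3),
                             dimnames = list(NULL, pm$label, c("x", "y", "z"))))
  cyc$coords[1, "ski_tip_l", ] <- c(0, 0, 1000) # purely vertical
  cyc$coords[1, "ski_tail_l", ] <- c(0, 0, -1000)
  expect_warning(a <- ski_angle_series(cyc, "l"), "vertical")
  expect_true(is.na(a))
})

test_that("skating shows more ski external rotation than double poling", {
  sk <- generate_trial(sim_config(technique = "skating", n_cycles = 3,
                                  noise_sd_mm = 0, drift_mm_per_s = 0, seed = 23))
  dp <- generate_trial(sim_config(technique = "double_pole", n_cycles = 3,
                                  noise_sd_mm = 0, drift_mm_per_s = 0, seed = 23))
  pp_sk <- preprocess_trial(sk$trial)
  pp_dp <- preprocess_trial(dp$trial)
  m_sk <- mean(abs(ski_angle_series(pp_sk$cycles[[1]], "l")))
  m_dp <- mean(abs(ski_angle_series(pp_dp$cycles[[1]], "l")))
  expect_gt(m_sk, m_dp)
})

test_that("power summation follows the bilateral and mass conventions", {
  pw <- matrix(0, 4, 5, dimnames = list(NULL, c("shoulder_l", "shoulder_r",
                                                "knee_l", "knee_r", "rta")))
  pw[, "shoulder_l"] <- 200; pw[, "shoulder_r"] <- 200
  pw[, "knee_l"] <- 100; pw[, "knee_r"] <- 150; pw[, "rta"] <- 50
  sp <- summed_power(pw, 80)
  expect_equal(sp$upper_wkg, rep(5, 4))
  expect_equal(sp$lower_wkg, rep(300 / 80, 4))
  # homogeneity of degree -1 in mass, linearity in channels
  expect_equal(summed_power(pw, 40)$upper_wkg, 2 * sp$upper_wkg)
  expect_equal(summed_power(2 * pw, 80)$upper_wkg, 2 * sp$upper_wkg)
  expect_equal(summed_power(pw * 0, 80)$upper_wkg, rep(0, 4))
  expect_error(summed_power(pw, 0), "body_mass_kg")
})

test_that("elite trials embed larger peak powers than beginner trials", {
  el <- generate_trial(sim_config(skill = "elite", n_cycles = 4, seed = 24))
  be <- generate_trial(sim_config(skill = "beginner", n_cycles = 4, seed = 24))
  expect_gt(min(el$truth$effects$peak_upper_wkg),
            max(be$truth$effects$peak_upper_wkg))
})

test_that("identical avatars give identical metrics", {
  res <- small_cohort_pipeline()
  expect_warning(rec0 <- mcr_reconstruct(res$model, integer(), numeric()))
  mm <- metrics_for_reconstruction(rec0)
  expect_equal(nrow(mm), 2)
  expect_equal(mm$mean_area_m2[1], mm$mean_area_m2[2])
  expect_equal(mm$peak_upper_wkg[1], mm$peak_upper_wkg[2])
  expect_equal(mm$mean_abs_ski_angle_deg[1], mm$mean_abs_ski_angle_deg[2])
})
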