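#' Simulation configuration for one synthetic skiing trial
#'
#' The simulator emulates the statistical structure the downstream pipeline
#' assumes: phase-coupled periodic limb motion for six sub-techniques, a
#' left-toe trajectory whose displacement norm has exactly one peak per
#' propulsion cycle, joint-power pulses phase-locked to propulsion, whole-body
#' travel and heading change around a track, and sensor imperfections (white
#' noise plus slow linear drift). Kinematic amplitudes are invented defaults
#' (no published equations exist for them); they are chosen so that the
#' techniques are geometrically distinct and the segmentation threshold is
#' comfortably exceeded.
#'
#' @param technique one of `double_pole, kick_double_pole, diagonal_stride,
#'   standing_glide, free_glide, skating`.
#' @param skill ordinal skill level: `beginner, intermediate, advanced, elite`.
#' @param n_cycles positive integer number of propulsion cycles.
#' @param cycle_period_s mean cycle duration (seconds).
#' @param period_cv coefficient of variation of cycle duration.
#' @param sample_rate_hz sampling rate (Hz, default 240).
#' @param noise_sd_mm standard deviation of i.i.d. Gaussian coordinate noise.
#' @param drift_mm_per_s linear positional drift magnitude (mm/s).
#' @param body_mass_kg participant mass (kg).
#' @param effort effort level label carried into trial metadata.
#' @param participant participant id carried into trial metadata.
#' @param seed integer seed; all randomness is local to the generator.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(technique = "diagonal_stride",
                       skill = "beginner",
                       n_cycles = 20L,
                       cycle_period_s = 1.4,
                       period_cv = 0.08,
                       sample_rate_hz = 240,
                       noise_sd_mm = 2,
                       drift_mm_per_s = 0.5,
                       body_mass_kg = 75,
                       effort = "medium",
                       participant = "SIM",
                       seed = 1L) {
  if (length(technique) != 1L || !technique %in% technique_levels()) {
    abort(sprintf("unknown technique '%s'; must be one of %s",
                  paste(technique, collapse = ","),
                  paste(technique_levels(), collapse = ", ")))
  }
  skill <- match.arg(skill, skill_levels())
  if (!is.numeric(n_cycles) || n_cycles < 1) abort("`n_cycles` must be >= 1")
  stopifnot_scalar_number(cycle_period_s, "cycle_period_s", 0, strict = TRUE)
  stopifnot_scalar_number(period_cv, "period_cv", 0)
  stopifnot_scalar_number(sample_rate_hz, "sample_rate_hz", 0, strict = TRUE)
  if (sample_rate_hz <= 2 / cycle_period_s) {
    abort("`sample_rate_hz` must exceed 2 / cycle_period_s (Nyquist)")
  }
  stopifnot_scalar_number(noise_sd_mm, "noise_sd_mm", 0)
  stopifnot_scalar_number(drift_mm_per_s, "drift_mm_per_s", 0)
  stopifnot_scalar_number(body_mass_kg, "body_mass_kg", 0, strict = TRUE)
  effort <- match.arg(effort, effort_levels())
  structure(list(technique = technique, skill = skill,
                 n_cycles = as.integer(n_cycles),
                 cycle_period_s = cycle_period_s, period_cv = period_cv,
                 sample_rate_hz = sample_rate_hz, noise_sd_mm = noise_sd_mm,
                 drift_mm_per_s = drift_mm_per_s, body_mass_kg = body_mass_kg,
                 effort = effort, participant = participant,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Skill-effect profile embedded by the simulator
#'
#' Encodes the skill-graded contrasts the pipeline is expected to recover:
#' higher skill means larger upper/lower joint-power amplitude, a smaller
#' frontal area, and less ski external rotation. Skill is mapped to an integer
#' rank 0-3 (beginner to elite) and each multiplier applies per rank step.
#'
#' @param upper_power_gain multiplicative upper-body power gain per skill step.
#' @param lower_power_gain multiplicative lower-body power gain per skill step.
#' @param frontal_area_shrink multiplicative shrink of body cross-section per
#'   skill step (< 1 means higher skill is more compact).
#' @param ski_angle_reduction_deg degrees of external-rotation reduction per
#'   skill step.
#' @param technique_mix named list mapping each skill level to a probability
#'   vector over the six techniques (must each sum to 1).
#' @return a list of class `skill_effect_profile`.
#' @export
skill_effect_profile <- function(upper_power_gain = 1.25,
                                 lower_power_gain = 1.20,
                                 frontal_area_shrink = 0.94,
                                 ski_angle_reduction_deg = 4,
                                 technique_mix = default_technique_mix()) {
  for (nm in c("upper_power_gain", "lower_power_gain", "frontal_area_shrink")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm, 0, strict = TRUE)
  }
  stopifnot_scalar_number(ski_angle_reduction_deg, "ski_angle_reduction_deg", 0)
  if (!all(skill_levels() %in% names(technique_mix))) {
    abort("`technique_mix` must have one entry per skill level")
  }
  for (sk in skill_levels()) {
    p <- technique_mix[[sk]]
    if (!all(technique_levels() %in% names(p))) {
      abort(sprintf("technique_mix$%s must cover all six techniques", sk))
    }
    p <- p[technique_levels()]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("technique_mix$%s must be a probability vector summing to 1", sk))
    }
    technique_mix[[sk]] <- p
  }
  structure(list(upper_power_gain = upper_power_gain,
                 lower_power_gain = lower_power_gain,
                 frontal_area_shrink = frontal_area_shrink,
                 ski_angle_reduction_deg = ski_angle_reduction_deg,
                 technique_mix = technique_mix),
            class = "skill_effect_profile")
}

#' @rdname skill_effect_profile
#' @export
default_technique_mix <- function() {
  mk <- function(dp, kdp, ds, sg, fg, sk) {
    setNames(c(dp, kdp, ds, sg, fg, sk), technique_levels())
  }
  list(
    beginner     = mk(0.15, 0.15, 0.45, 0.10, 0.10, 0.05),
    intermediate = mk(0.25, 0.15, 0.30, 0.10, 0.10, 0.10),
    advanced     = mk(0.30, 0.10, 0.15, 0.10, 0.10, 0.25),
    elite        = mk(0.35, 0.10, 0.05, 0.05, 0.10, 0.35)
  )
}

skill_rank <- function(skill) match(skill, skill_levels()) - 1L

new_ground_truth <- function(cycle_boundaries, technique_labels, effects) {
  if (any(diff(cycle_boundaries) <= 0)) abort("ground-truth boundaries must be strictly increasing")
  if (length(technique_labels) != length(cycle_boundaries)) {
    abort("one technique label per cycle is required")
  }
  structure(list(cycle_boundaries = as.integer(cycle_boundaries),
                 technique_labels = technique_labels,
                 effects = tibble::as_tibble(effects)),
            class = "ski_ground_truth")
}

#' @export
as_tibble.ski_ground_truth <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(boundary_frame = x$cycle_boundaries,
                   technique = x$technique_labels),
    x$effects
  )
}

# per-technique motion parameters (metres / degrees); invented defaults
technique_params <- function(technique) {
  switch(technique,
    double_pole      = list(a_arm = 0.30, arm_ph = c(0, 0), arm_h2 = 0.3,
                            a_leg = 0.02, leg_ph = c(0, pi), lateral = FALSE,
                            trunk = 0.10, ski_deg = 4,
                            r0 = 0.06, r1 = 0.04, tuck = 1,
                            p_sh = 1.3, p_kn = 0.6, p_rta = 1.0),
    kick_double_pole = list(a_arm = 0.30, arm_ph = c(0, 0), arm_h2 = 0.3,
                            a_leg = 0.15, leg_ph = c(pi / 2, pi), lateral = FALSE,
                            trunk = 0.08, ski_deg = 4,
                            r0 = 0.06, r1 = 0.04, tuck = 1,
                            p_sh = 1.2, p_kn = 0.9, p_rta = 0.9),
    diagonal_stride  = list(a_arm = 0.25, arm_ph = c(0, pi), arm_h2 = 0,
                            a_leg = 0.20, leg_ph = c(pi, 0), lateral = FALSE,
                            trunk = 0.02, ski_deg = 6,
                            r0 = 0.06, r1 = 0.04, tuck = 1,
                            p_sh = 1.0, p_kn = 1.2, p_rta = 0.6),
    standing_glide   = list(a_arm = 0.02, arm_ph = c(0, pi), arm_h2 = 0,
                            a_leg = 0.02, leg_ph = c(0, pi), lateral = FALSE,
                            trunk = 0.01, ski_deg = 3,
                            r0 = 0.03, r1 = 0.02, tuck = 1,
                            p_sh = 0.1, p_kn = 0.1, p_rta = 0.1),
    free_glide       = list(a_arm = 0.02, arm_ph = c(0, pi), arm_h2 = 0,
                            a_leg = 0.02, leg_ph = c(0, pi), lateral = FALSE,
                            trunk = 0.01, ski_deg = 3,
                            r0 = 0.03, r1 = 0.02, tuck = 0.75,
                            p_sh = 0.1, p_kn = 0.1, p_rta = 0.1),
    skating          = list(a_arm = 0.20, arm_ph = c(0, 0), arm_h2 = 0.2,
                            a_leg = 0.18, leg_ph = c(0, pi), lateral = TRUE,
                            trunk = 0.04, ski_deg = 14,
                            r0 = 0.06, r1 = 0.04, tuck = 1,
                            p_sh = 1.1, p_kn = 1.3, p_rta = 0.8),
    abort(sprintf("unknown technique '%s'", technique))
  )
}

arm_chain_weights <- function(side) {
  w <- c(clavicle = 0.10, shoulder = 0.15, upper_arm = 0.30, elbow_lat = 0.45,
         elbow_med = 0.45, forearm = 0.60, wrist_rad = 0.75, wrist_uln = 0.75,
         hand = 0.85, finger = 1.00, pole_grip = 0.80, pole_mid = 0.90,
         pole_tip = 1.10)
  setNames(w, paste0(names(w), "_", side))
}

leg_chain_weights <- function(side) {
  w <- c(hip = 0.10, thigh = 0.30, knee_lat = 0.45, knee_med = 0.45,
         shank = 0.60, ankle_lat = 0.80, ankle_med = 0.80, heel = 0.85,
         mt1 = 0.90, mt5 = 0.90, foot_mid = 0.90, toe = 0.95,
         ski_tip = 1.00, ski_mid = 1.00, ski_tail = 1.00)
  setNames(w, paste0(names(w), "_", side))
}

trunk_labels <- function() {
  c("head_top", "head_front", "head_back", "ear_l", "ear_r", "eye_l", "eye_r",
    "c7", "t1", "sternum", "t4", "t8", "l3")
}

#' Generate one labelled synthetic skiing trial
#'
#' Builds a trial around a neutral skeleton: skill-graded posture scaling,
#' technique-specific harmonic limb templates, a left-toe loop guaranteeing
#' exactly `n_cycles` displacement-norm peaks above 1 cm, skill-scaled power
#' pulses, forward travel with slow heading change, and finally additive white
#' noise and linear drift. Fully deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param effects a [skill_effect_profile()].
#' @return a list with elements `trial` (a [ski_trial()]) and `truth`
#'   (a `ski_ground_truth` with boundary frames, per-cycle labels and realized
#'   embedded effects).
#' @export
generate_trial <- function(config, effects = skill_effect_profile()) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  tp <- technique_params(config$technique)
  if (config$noise_sd_mm >= 10 * tp$r1 * 1000) {
    abort(sprintf(
      "noise_sd_mm = %g would bury the 1 cm segmentation threshold (>= 10 x toe template amplitude %g mm)",
      config$noise_sd_mm, tp$r1 * 1000))
  }
  rank <- skill_rank(config$skill)
  model <- point_model()
  pose <- base_pose(model)

  withr::with_seed(config$seed, {
    n <- config$n_cycles
    sdlog <- sqrt(log(1 + config$period_cv^2))
    periods <- config$cycle_period_s * exp(rnorm(n, -sdlog^2 / 2, sdlog))
    starts <- c(0, cumsum(periods))
    total <- starts[n + 1]
    dt <- 1 / config$sample_rate_hz
    time_s <- seq(0, total - dt / 2, by = dt)
    nt <- length(time_s)
    cyc <- pmin(pmax(findInterval(time_s, starts), 1L), n)
    phase <- 2 * pi * (cyc - 1) + 2 * pi * (time_s - starts[cyc]) / periods[cyc]

    # skill-graded posture: compact cross-section for higher skill
    s_area <- effects$frontal_area_shrink^rank
    body <- model$label[model$group != "equipment"]
    upper <- model$label[model$group == "upper_body"]
    pose[, "y"] <- pose[, "y"] * s_area
    pz <- pose["pelvis_origin", "z"]
    pose[upper, "z"] <- pz + (pose[upper, "z"] - pz) * s_area * tp$tuck

    coords <- array(rep(pose, each = nt), c(nt, 76L, 3L),
                    dimnames = list(NULL, model$label, c("x", "y", "z")))

    # technique-specific limb templates (1-2 harmonics per chain)
    add_motion <- function(labels, weights, axis, amp, ph, h2 = 0) {
      sig <- amp * (sin(phase + ph) + h2 * sin(2 * (phase + ph)))
      for (lab in labels) {
        coords[, lab, axis] <<- coords[, lab, axis] + weights[[lab]] * sig
      }
      if (axis == 1L) { # sagittal swings pivot: coupled vertical component
        sigz <- 0.4 * amp * cos(phase + ph)
        for (lab in labels) {
          coords[, lab, 3L] <<- coords[, lab, 3L] + weights[[lab]] * sigz
        }
      }
    }
    for (side in c("l", "r")) {
      i <- if (side == "l") 1L else 2L
      aw <- arm_chain_weights(side)
      add_motion(names(aw), aw, 1L, tp$a_arm, tp$arm_ph[i], tp$arm_h2)
      lw <- leg_chain_weights(side)
      lw <- lw[setdiff(names(lw), "toe_l")] # left toe carries the loop template
      leg_axis <- if (tp$lateral) 2L else 1L
      leg_amp <- if (config$technique == "kick_double_pole" && side == "r") 0.03 else tp$a_leg
      add_motion(names(lw), lw, leg_axis, leg_amp, tp$leg_ph[i])
    }
    for (lab in trunk_labels()) {
      coords[, lab, 1L] <- coords[, lab, 1L] + tp$trunk * sin(phase)
      coords[, lab, 3L] <- coords[, lab, 3L] - 0.5 * tp$trunk * (1 - cos(phase)) / 2
    }

    # left-toe loop: distance from its trial mean is
    # sqrt(r0^2 + r0*r1*cos(phase - pi) + r1^2/4) -> one peak per cycle,
    # mid-cycle, so every peak is interior to the trial
    lc <- cos(phase - pi); ls <- sin(phase - pi)
    r <- tp$r0 + tp$r1 * lc
    coords[, "toe_l", 1L] <- coords[, "toe_l", 1L] + r * lc
    coords[, "toe_l", 3L] <- coords[, "toe_l", 3L] + r * ls

    # ski external rotation: per-cycle angle, reduced with skill
    theta_deg <- pmax(1, tp$ski_deg - effects$ski_angle_reduction_deg * rank)
    theta_cyc <- theta_deg * exp(rnorm(n, 0, 0.05))
    th <- deg2rad(theta_cyc[cyc])
    for (side in c("l", "r")) {
      sgn <- if (side == "l") 1 else -1 # external = tip outward
      pivot_lab <- paste0("toe_", side)
      px <- coords[, pivot_lab, 1L]; py <- coords[, pivot_lab, 2L]
      for (part in c("ski_tip", "ski_mid", "ski_tail")) {
        lab <- paste0(part, "_", side)
        dx <- coords[, lab, 1L] - px; dy <- coords[, lab, 2L] - py
        a <- sgn * th
        coords[, lab, 1L] <- px + cos(a) * dx - sin(a) * dy
        coords[, lab, 2L] <- py + sin(a) * dx + cos(a) * dy
      }
    }

    # phase-locked nonnegative power pulses, skill-scaled
    ug <- effects$upper_power_gain^rank
    lg <- effects$lower_power_gain^rank
    jit <- matrix(exp(rnorm(n * 5L, 0, 0.05)), n, 5L)
    pulse <- function(ph0) ((1 - cos(phase + ph0)) / 2)^3
    power <- cbind(
      shoulder_l = 120 * tp$p_sh * ug * jit[cyc, 1L] * pulse(-0.3),
      shoulder_r = 120 * tp$p_sh * ug * jit[cyc, 2L] * pulse(-0.3 + pi * (tp$arm_ph[2] != tp$arm_ph[1])),
      knee_l = 80 * tp$p_kn * lg * jit[cyc, 3L] * pulse(0.2),
      knee_r = 80 * tp$p_kn * lg * jit[cyc, 4L] * pulse(0.2 + pi * (tp$leg_ph[2] != tp$leg_ph[1])),
      rta = 60 * tp$p_rta * lg * jit[cyc, 5L] * pulse(0)
    )

    # ground truth before global motion / sensor corruption
    boundary_frames <- vapply(seq_len(n), function(i) {
      which.min(abs(time_s - (starts[i] + periods[i] / 2)))
    }, integer(1))
    start_frames <- vapply(starts[seq_len(n)], function(s) {
      which.min(abs(time_s - s))
    }, integer(1))
    end_frames <- c(start_frames[-1] - 1L, nt)
    mass <- config$body_mass_kg
    eff <- purrr::map_dfr(seq_len(n), function(i) {
      f <- boundary_frames[i]
      idx <- start_frames[i]:end_frames[i]
      fr <- coords[f, , ]
      tibble::tibble(
        cycle = i, start_frame = start_frames[i], end_frame = end_frames[i],
        frontal_area_m2 = frontal_area(fr * 1000, model),
        ski_angle_deg = theta_cyc[i],
        peak_upper_wkg = max(power[idx, "shoulder_l"] + power[idx, "shoulder_r"]) / mass,
        peak_lower_wkg = max(power[idx, "knee_l"] + power[idx, "knee_r"] + power[idx, "rta"]) / mass
      )
    })
    truth <- new_ground_truth(boundary_frames,
                              rep(config$technique, n), eff)

    # whole-body travel and slow heading change around the track
    heading <- 0.3 * sin(2 * pi * time_s / max(total, 1))
    ch <- cos(heading); sh <- sin(heading)
    px <- coords[, "pelvis_origin", 1L]; py <- coords[, "pelvis_origin", 2L]
    for (j in seq_len(76L)) {
      dx <- coords[, j, 1L] - px; dy <- coords[, j, 2L] - py
      coords[, j, 1L] <- px + ch * dx - sh * dy
      coords[, j, 2L] <- py + sh * dx + ch * dy
    }
    travel <- 3.0 * time_s # m, nominal forward speed
    coords[, , 1L] <- coords[, , 1L] + travel * ch
    coords[, , 2L] <- coords[, , 2L] + travel * sh

    # to millimetres; white noise and linear drift applied last
    coords <- coords * 1000
    if (config$noise_sd_mm > 0) {
      coords <- coords + array(rnorm(length(coords), 0, config$noise_sd_mm),
                               dim(coords))
    }
    if (config$drift_mm_per_s > 0) {
      d <- config$drift_mm_per_s * time_s / sqrt(3)
      coords <- coords + array(rep(d, 76L * 3L), dim(coords))
    }

    trial <- ski_trial(coords, time_s, power,
                       meta = list(participant = config$participant,
                                   skill = config$skill,
                                   effort = config$effort,
                                   body_mass_kg = mass,
                                   technique = config$technique))
    list(trial = trial, truth = truth)
  })
}

#' Generate a skill-graded cohort of synthetic trials
#'
#' Trials for all four skill levels with per-trial techniques drawn from the
#' profile's technique mix; per-trial seeds derive deterministically from the
#' master seed.
#'
#' @param n_per_skill trials per skill level (>= 1).
#' @param effects a [skill_effect_profile()].
#' @param seed master seed.
#' @param n_cycles cycles per trial.
#' @param ... further arguments passed to [sim_config()] (e.g. noise_sd_mm).
#' @return a list of class `ski_cohort`: `trials` (list of `ski_trial`),
#'   `truths` (list of `ski_ground_truth`) and an `info` tibble.
#' @export
generate_cohort <- function(n_per_skill, effects = skill_effect_profile(),
                            seed = 1L, n_cycles = 30L, ...) {
  if (n_per_skill < 1) abort("`n_per_skill` must be >= 1")
  grid <- tidyr::expand_grid(skill = skill_levels(), rep = seq_len(n_per_skill))
  ntr <- nrow(grid)
  draws <- withr::with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, ntr),
         u = runif(ntr))
  })
  techniques <- vapply(seq_len(ntr), function(i) {
    p <- effects$technique_mix[[grid$skill[i]]]
    technique_levels()[findInterval(draws$u[i], cumsum(p),
                                    left.open = TRUE) + 1L]
  }, character(1))
  res <- purrr::map(seq_len(ntr), function(i) {
    cfg <- sim_config(technique = techniques[i], skill = grid$skill[i],
                      n_cycles = n_cycles,
                      participant = sprintf("%s_%02d", grid$skill[i], grid$rep[i]),
                      seed = draws$seeds[i], ...)
    generate_trial(cfg, effects)
  })
  structure(list(
    trials = purrr::map(res, "trial"),
    truths = purrr::map(res, "truth"),
    info = dplyr::mutate(grid,
                         trial_id = seq_len(ntr),
                         participant = purrr::map_chr(res, ~ .x$trial$meta$participant),
                         technique = techniques,
                         seed = draws$seeds)
  ), class = "ski_cohort")
}

#' @export
print.ski_cohort <- function(x, ...) {
  cat(sprintf("<ski_cohort> %d trials (%s)\n", length(x$trials),
              paste(table(x$info$skill)[skill_levels()], collapse = "/")))
  invisible(x)
}

#' Generate a synthetic GNSS track recording
#'
#' A closed oval (2:1 ellipse scaled to the requested lap length) repeated
#' `n_laps` times with a sinusoidal elevation profile of amplitude
#' `elevation_change_m / 2`, sampled at `rate_hz`, with optional additive
#' noise and linear positional drift. Ground-truth lap boundaries are
#' returned alongside.
#'
#' @param n_laps number of laps (>= 1).
#' @param lap_length_m lap length (metres).
#' @param elevation_change_m total elevation range over a lap (metres).
#' @param rate_hz sampling rate (default 4 Hz).
#' @param noise_sd_m positional noise SD (metres).
#' @param drift_m_per_s linear drift (metres/second).
#' @param lap_time_s lap duration (seconds).
#' @param seed integer seed.
#' @return list of class `ski_gnss`: `series` tibble
#'   (`time_s, x_m, y_m, elev_m`), integer `lap_boundaries` (start sample of
#'   each lap), and the lap parameters.
#' @export
generate_gnss_track <- function(n_laps, lap_length_m = 600,
                                elevation_change_m = 20, rate_hz = 4,
                                noise_sd_m = 1, drift_m_per_s = 0,
                                lap_time_s = 150, seed = 1L) {
  if (n_laps < 1) abort("`n_laps` must be >= 1")
  m <- round(rate_hz * lap_time_s)
  ntot <- m * n_laps
  s <- (seq_len(ntot) - 1) / m # lap fraction, repeats each lap
  a <- 1; b <- 0.5
  fine <- seq(0, 2 * pi, length.out = 20001)
  per <- sum(sqrt(diff(a * cos(fine))^2 + diff(b * sin(fine))^2))
  sc <- lap_length_m / per
  withr::with_seed(seed, {
    x <- sc * a * cos(2 * pi * s)
    y <- sc * b * sin(2 * pi * s)
    elev <- elevation_change_m / 2 * sin(2 * pi * (s %% 1))
    t <- (seq_len(ntot) - 1) / rate_hz
    if (noise_sd_m > 0) {
      x <- x + rnorm(ntot, 0, noise_sd_m)
      y <- y + rnorm(ntot, 0, noise_sd_m)
      elev <- elev + rnorm(ntot, 0, noise_sd_m)
    }
    if (drift_m_per_s > 0) {
      x <- x + drift_m_per_s * t / sqrt(2)
      y <- y + drift_m_per_s * t / sqrt(2)
    }
    structure(list(
      series = tibble::tibble(time_s = t, x_m = x, y_m = y, elev_m = elev),
      lap_boundaries = as.integer(seq(1L, by = m, length.out = n_laps)),
      lap_time_s = lap_time_s, lap_length_m = lap_length_m
    ), class = "ski_gnss")
  })
}
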