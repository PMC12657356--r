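# fixture builders shared across test files; everything is generated in code

# a pose whose pelvis frame coincides exactly with the global frame
# (PSIS raised to ASIS height so the forward axis is horizontal)
identity_pose <- function() {
  pose <- base_pose() # metres
  pose[c("psis_l", "psis_r"), "z"] <- pose["asis_l", "z"]
  pose
}

# static trial: the identity pose repeated, in millimetres
static_trial <- function(n_frames = 10, rate = 240, pose = identity_pose()) {
  coords <- array(rep(pose * 1000, each = n_frames), c(n_frames, 76L, 3L),
                  dimnames = list(NULL, rownames(pose), c("x", "y", "z")))
  ski_trial(coords, seq(0, by = 1 / rate, length.out = n_frames),
            matrix(0, n_frames, 5),
            meta = list(participant = "T1", skill = "beginner",
                        effort = "medium", body_mass_kg = 75))
}

# trial whose left toe follows a sagittal loop of radius r0 + r1*cos(w t - pi)
# about its centre; the toe's distance from its trial mean is then a periodic
# signal with exactly one local maximum per period (mid-period)
toe_loop_trial <- function(duration_s, period_s, r0_mm, r1_mm, rate = 240) {
  n <- round(duration_s * rate)
  tr <- static_trial(n_frames = n, rate = rate)
  t <- tr$time_s
  ph <- 2 * pi * t / period_s - pi
  r <- (r0_mm + r1_mm * cos(ph))
  tr$coords[, "toe_l", 1] <- tr$coords[, "toe_l", 1] + r * cos(ph)
  tr$coords[, "toe_l", 3] <- tr$coords[, "toe_l", 3] + r * sin(ph)
  tr
}

# rotate a whole trial by `deg` about the global vertical axis
rotate_trial_z <- function(trial, deg) {
  a <- deg * pi / 180
  x <- trial$coords[, , 1]; y <- trial$coords[, , 2]
  trial$coords[, , 1] <- cos(a) * x - sin(a) * y
  trial$coords[, , 2] <- sin(a) * x + cos(a) * y
  trial
}

# add a constant offset (mm) to every coordinate
offset_trial <- function(trial, off) {
  for (ax in 1:3) trial$coords[, , ax] <- trial$coords[, , ax] + off[ax]
  trial
}

# small synthetic cycle database built from hand-made cycles
toy_cycles <- function(n_cycles = 6, ns = 11, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_cycles), function(i) {
      structure(list(
        time_norm = seq(0, 1, length.out = ns),
        duration_s = 1 + 0.1 * i,
        coords = array(rnorm(ns * 76 * 3, sd = 50),
                       c(ns, 76L, 3L),
                       dimnames = list(NULL, point_model()$label,
                                       c("x", "y", "z"))),
        power = matrix(abs(rnorm(ns * 5, 100, 20)), ns, 5,
                       dimnames = list(NULL, c("shoulder_l", "shoulder_r",
                                               "knee_l", "knee_r", "rta"))),
        meta = list(participant = paste0("P", i %% 3),
                    skill = skill_levels()[(i %% 4) + 1],
                    effort = "medium", body_mass_kg = 75,
                    technique = "double_pole")
      ), class = "ski_cycle")
    })
  })
}

# one small preprocessed cohort, computed lazily and cached for the session
.cohort_cache <- new.env(parent = emptyenv())
small_cohort_pipeline <- function() {
  if (!is.null(.cohort_cache$res)) return(.cohort_cache$res)
  cohort <- generate_cohort(2, seed = 404, n_cycles = 8)
  pps <- lapply(cohort$trials, function(tr) {
    suppressWarnings(preprocess_trial(tr))
  })
  db <- amplitude_normalize(build_cycle_database(pps))
  model <- fit_pca(db)
  .cohort_cache$res <- list(cohort = cohort, preprocessed = pps,
                            db = db, model = model)
  .cohort_cache$res
}
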