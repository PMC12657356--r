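#' Frontal area of one frame as two stacked rectangles
#'
#' A drag proxy: the sum of two rectangles in the frontal (y-z) plane, one
#' spanning the upper-body points and one the lower-body points, each
#' mediolateral extent x vertical extent (max - min per axis). Equipment
#' points are excluded. Input coordinates are millimetres in the aligned
#' frame (x forward, y mediolateral, z vertical); the area is returned in
#' square metres. A group collapsed to a point or line contributes zero.
#'
#' @param frame_coords 76 x 3 numeric matrix (mm) with labelled rows.
#' @param model a [point_model()].
#' @return scalar area (m^2).
#' @export
frontal_area <- function(frame_coords, model = point_model()) {
  area_of <- function(group) {
    labs <- model$label[model$group == group]
    pts <- frame_coords[labs, , drop = FALSE]
    ml <- diff(range(pts[, 2]))
    vert <- diff(range(pts[, 3]))
    ml * vert
  }
  (area_of("upper_body") + area_of("lower_body")) / 1e6
}

#' Frontal-area time series over a cycle
#'
#' @param cycle a `ski_cycle` (or any list with a `coords` array in mm).
#' @param model a [point_model()].
#' @return numeric vector, one area (m^2) per sample.
#' @export
frontal_area_series <- function(cycle, model = point_model()) {
  ns <- dim(cycle$coords)[1]
  vapply(seq_len(ns), function(i) {
    fr <- cycle$coords[i, , ]
    rownames(fr) <- dimnames(cycle$coords)[[2]]
    frontal_area(fr, model)
  }, numeric(1))
}

#' Transverse-plane ski external-rotation angle
#'
#' Signed angle between the ski axis (tip minus tail, projected onto the
#' transverse x-y plane) and the forward axis, with external rotation
#' (tip pointing away from the body midline) positive for both sides.
#' A vertically oriented ski has no transverse projection; such samples are
#' returned as NA with a warning.
#'
#' @param cycle a `ski_cycle` in the aligned frame.
#' @param side `"l"` or `"r"`.
#' @param model a [point_model()].
#' @return numeric vector of angles in degrees, one per sample, in
#'   (-180, 180].
#' @export
ski_angle_series <- function(cycle, side = c("l", "r"), model = point_model()) {
  side <- match.arg(side)
  grab <- function(lab) {
    m <- cycle$coords[, lab, , drop = FALSE]
    dim(m) <- c(dim(cycle$coords)[1], 3L)
    m
  }
  tip <- grab(paste0("ski_tip_", side))
  tail_ <- grab(paste0("ski_tail_", side))
  dx <- tip[, 1] - tail_[, 1]
  dy <- tip[, 2] - tail_[, 2]
  len <- sqrt(dx^2 + dy^2)
  bad <- len < 1e-9
  if (any(bad)) {
    warn(sprintf("%d sample(s) with vertically oriented %s ski skipped",
                 sum(bad), side))
  }
  sgn <- if (side == "l") 1 else -1 # external = tip toward +y (left) / -y (right)
  ang <- sgn * rad2deg(atan2(dy, dx))
  ang[bad] <- NA_real_
  wrap_deg(ang)
}

#' Mass-normalized upper and lower body power
#'
#' Upper power is the bilateral shoulder sum; gross lower-body power sums both
#' knees and the thorax-abdomen (RTA) channel. Both are divided by body mass.
#'
#' @param power matrix with columns `shoulder_l, shoulder_r, knee_l, knee_r,
#'   rta` (watts).
#' @param body_mass_kg positive mass (kg).
#' @return tibble `upper_wkg, lower_wkg`, one row per sample.
#' @export
summed_power <- function(power, body_mass_kg) {
  stopifnot_scalar_number(body_mass_kg, "body_mass_kg", 0, strict = TRUE)
  tibble::tibble(
    upper_wkg = (power[, "shoulder_l"] + power[, "shoulder_r"]) / body_mass_kg,
    lower_wkg = (power[, "knee_l"] + power[, "knee_r"] + power[, "rta"]) / body_mass_kg
  )
}

#' All interpretive metrics for one cycle
#'
#' @param cycle a `ski_cycle`.
#' @param model a [point_model()].
#' @return list of class `ski_metrics`: series (`frontal_area_m2`,
#'   `ski_angle_l_deg`, `ski_angle_r_deg`, `upper_wkg`, `lower_wkg`) and
#'   scalars (`peak_upper_wkg, peak_lower_wkg, mean_area_m2,
#'   mean_abs_ski_angle_deg`).
#' @export
cycle_metrics <- function(cycle, model = point_model()) {
  area <- frontal_area_series(cycle, model)
  al <- ski_angle_series(cycle, "l", model)
  ar <- ski_angle_series(cycle, "r", model)
  pw <- summed_power(cycle$power, cycle$meta$body_mass_kg %||% 1)
  structure(list(
    frontal_area_m2 = area,
    ski_angle_l_deg = al, ski_angle_r_deg = ar,
    upper_wkg = pw$upper_wkg, lower_wkg = pw$lower_wkg,
    peak_upper_wkg = max(pw$upper_wkg), peak_lower_wkg = max(pw$lower_wkg),
    mean_area_m2 = mean(area),
    mean_abs_ski_angle_deg = mean(abs(c(al, ar)), na.rm = TRUE)
  ), class = "ski_metrics")
}

#' Side-by-side metrics for the beginner / elite avatars
#'
#' Computes all interpretive metrics on both reconstructed avatars. The
#' reconstruction's power block is already bilateral and mass-normalized
#' (upper, lower = knees, RTA), so avatar power series are `upper` and
#' `lower + rta`.
#'
#' @param rec a `ski_mcr` from [mcr_reconstruct()].
#' @param model a [point_model()].
#' @return tibble with one row per avatar: `avatar, mean_area_m2,
#'   mean_abs_ski_angle_deg, peak_upper_wkg, peak_lower_wkg`.
#' @export
metrics_for_reconstruction <- function(rec, model = point_model()) {
  purrr::map_dfr(c("beginner", "elite"), function(av) {
    cyc <- rec$unscaled[[av]]
    pseudo <- list(coords = cyc$coords, meta = list())
    area <- frontal_area_series(pseudo, model)
    al <- ski_angle_series(pseudo, "l", model)
    ar <- ski_angle_series(pseudo, "r", model)
    upper <- cyc$power[, "upper"]
    lower <- cyc$power[, "lower"] + cyc$power[, "rta"]
    tibble::tibble(avatar = av,
                   mean_area_m2 = mean(area),
                   mean_abs_ski_angle_deg = mean(abs(c(al, ar)), na.rm = TRUE),
                   peak_upper_wkg = max(upper),
                   peak_lower_wkg = max(lower))
  })
}
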