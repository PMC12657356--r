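#' The 76-point full-body + equipment marker registry
#'
#' The analysis operates on a fixed cloud of 76 labelled points: body landmarks
#' derived from a full-body inertial motion-capture model plus points on both
#' skis and poles. The exact label list of commercial suits is vendor-specific,
#' so the registry ships a documented default and accepts user remapping: any
#' 76 unique labels may be supplied as long as the landmarks the pipeline
#' relies on (pelvis origin and pelvis-frame landmarks, the T12 spinous
#' process, the left toe, and tip/tail pairs for both skis) are present and
#' grouped.
#'
#' @param labels character vector of exactly 76 unique point labels.
#' @param groups named character vector or list mapping every label to one of
#'   `"upper_body"`, `"lower_body"`, `"equipment"`.
#'
#' @return A tibble of class `ski_point_model` with columns `label` and
#'   `group`, in registry order.
#' @export
#'
#' @examples
#' pm <- point_model()
#' dplyr::count(pm, group)
point_model <- function(labels = NULL, groups = NULL) {
  if (is.null(labels)) {
    reg <- default_point_registry()
  } else {
    if (is.null(groups)) abort("`groups` must be supplied when `labels` is.")
    groups <- unlist(groups)
    reg <- tibble::tibble(label = as.character(labels),
                          group = as.character(groups[labels]))
  }
  validate_point_model(reg)
}

required_point_labels <- function() {
  c("t12", "pelvis_origin", "toe_l",
    "asis_l", "asis_r", "psis_l", "psis_r",
    "ski_tip_l", "ski_tail_l", "ski_tip_r", "ski_tail_r")
}

validate_point_model <- function(reg) {
  if (nrow(reg) != 76L) {
    abort(sprintf("a point model must have exactly 76 labels, got %d", nrow(reg)))
  }
  if (anyDuplicated(reg$label)) abort("point labels must be unique")
  bad <- setdiff(reg$group, c("upper_body", "lower_body", "equipment"))
  if (length(bad) || anyNA(reg$group)) {
    abort("every label must map to upper_body, lower_body or equipment")
  }
  missing <- setdiff(required_point_labels(), reg$label)
  if (length(missing)) {
    abort(sprintf("point model is missing required label(s): %s",
                  paste(missing, collapse = ", ")))
  }
  class(reg) <- c("ski_point_model", class(reg))
  reg
}

default_point_registry <- function() {
  mirror <- function(x) as.vector(rbind(paste0(x, "_l"), paste0(x, "_r")))
  upper <- c(
    "head_top", "head_front", "head_back",
    mirror("ear"), mirror("eye"),
    "c7", "t1", "sternum", "t4", "t8", "t12", "l3",
    mirror(c("clavicle", "shoulder", "upper_arm", "elbow_lat", "elbow_med",
             "forearm", "wrist_rad", "wrist_uln", "hand", "finger"))
  )
  lower <- c(
    "pelvis_origin", "sacrum", mirror(c("asis", "psis")),
    mirror(c("hip", "thigh", "knee_lat", "knee_med", "shank",
             "ankle_lat", "ankle_med", "heel", "toe", "mt1", "mt5",
             "foot_mid"))
  )
  equip <- mirror(c("ski_tip", "ski_mid", "ski_tail",
                    "pole_tip", "pole_mid", "pole_grip"))
  tibble::tibble(
    label = c(upper, lower, equip),
    group = rep(c("upper_body", "lower_body", "equipment"),
                c(length(upper), length(lower), length(equip)))
  )
}

#' Neutral standing pose for the default registry
#'
#' A plausible static full-body pose (metres, pelvis-forward frame: x forward,
#' y left, z up) used by the synthetic skier as the template skeleton. The
#' coordinates are invented for simulation; they are not anthropometric
#' measurements.
#'
#' @param model a [point_model()] (default registry only).
#' @return a 76 x 3 matrix (metres) with row names equal to the model labels.
#' @export
base_pose <- function(model = point_model()) {
  p <- list(
    head_top = c(0.00, 0.00, 1.75), head_front = c(0.10, 0.00, 1.65),
    head_back = c(-0.10, 0.00, 1.65),
    ear_l = c(0.00, 0.08, 1.63), eye_l = c(0.08, 0.04, 1.66),
    c7 = c(-0.05, 0.00, 1.50), t1 = c(-0.05, 0.00, 1.48),
    sternum = c(0.08, 0.00, 1.40), t4 = c(-0.06, 0.00, 1.40),
    t8 = c(-0.06, 0.00, 1.27), t12 = c(-0.06, 0.00, 1.15),
    l3 = c(-0.05, 0.00, 1.08),
    clavicle_l = c(0.02, 0.10, 1.45), shoulder_l = c(0.00, 0.20, 1.45),
    upper_arm_l = c(0.00, 0.22, 1.30), elbow_lat_l = c(0.00, 0.24, 1.15),
    elbow_med_l = c(0.00, 0.18, 1.15), forearm_l = c(0.05, 0.23, 1.05),
    wrist_rad_l = c(0.10, 0.24, 0.95), wrist_uln_l = c(0.10, 0.20, 0.95),
    hand_l = c(0.15, 0.22, 0.90), finger_l = c(0.20, 0.22, 0.87),
    pelvis_origin = c(0.00, 0.00, 1.00), sacrum = c(-0.08, 0.00, 0.98),
    asis_l = c(0.10, 0.12, 1.00), psis_l = c(-0.10, 0.05, 1.02),
    hip_l = c(0.00, 0.09, 0.95), thigh_l = c(0.02, 0.10, 0.70),
    knee_lat_l = c(0.00, 0.12, 0.50), knee_med_l = c(0.00, 0.06, 0.50),
    shank_l = c(0.02, 0.10, 0.30), ankle_lat_l = c(0.00, 0.11, 0.10),
    ankle_med_l = c(0.00, 0.07, 0.10), heel_l = c(-0.05, 0.09, 0.05),
    toe_l = c(0.15, 0.09, 0.03), mt1_l = c(0.10, 0.06, 0.03),
    mt5_l = c(0.10, 0.13, 0.03), foot_mid_l = c(0.05, 0.09, 0.04),
    ski_tip_l = c(0.90, 0.09, 0.05), ski_mid_l = c(0.00, 0.09, 0.01),
    ski_tail_l = c(-0.60, 0.09, 0.02),
    pole_tip_l = c(-0.30, 0.30, 0.00), pole_mid_l = c(-0.15, 0.28, 0.70),
    pole_grip_l = c(0.00, 0.26, 1.40)
  )
  out <- matrix(NA_real_, nrow = nrow(model), ncol = 3,
                dimnames = list(model$label, c("x", "y", "z")))
  for (lab in model$label) {
    if (lab %in% names(p)) {
      out[lab, ] <- p[[lab]]
    } else if (grepl("_r$", lab)) {
      left <- sub("_r$", "_l", lab)
      if (!left %in% names(p)) abort(sprintf("no pose for label %s", lab))
      out[lab, ] <- p[[left]] * c(1, -1, 1)
    } else {
      abort(sprintf("no pose for label %s", lab))
    }
  }
  out
}
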