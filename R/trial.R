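#' Construct a kinematic trial
#'
#' A trial is one continuous over-ground recording: a `T x 76 x 3` point cloud
#' in millimetres at a nominal 240 Hz, five joint-power channels (left/right
#' shoulder, left/right knee, and the thorax-abdomen channel "RTA") in watts,
#' and participant metadata.
#'
#' @param coords numeric array `T x 76 x 3` (millimetres); the second dimension
#'   must carry the point-model labels as dimnames, the third `c("x","y","z")`.
#' @param time_s strictly increasing numeric vector of length `T` (seconds).
#' @param power numeric matrix `T x 5` with columns
#'   `shoulder_l, shoulder_r, knee_l, knee_r, rta` (watts); must be finite.
#' @param meta list with `participant`, `skill` (one of beginner,
#'   intermediate, advanced, elite), `effort` (easy, medium, hard) and
#'   `body_mass_kg`.
#' @return an object of class `ski_trial`.
#' @export
ski_trial <- function(coords, time_s, power, meta) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 76L || dim(coords)[3] != 3L) {
    abort("`coords` must be a T x 76 x 3 array")
  }
  n <- dim(coords)[1]
  if (n < 1L) abort("a trial must contain at least one frame")
  if (length(time_s) != n) abort("`time_s` length must match frame count")
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing")
  if (anyNA(coords) || any(!is.finite(coords))) abort("coordinates must be finite (no missing frames)")
  power <- as.matrix(power)
  if (nrow(power) != n || ncol(power) != 5L) abort("`power` must be a T x 5 matrix")
  if (any(!is.finite(power))) abort("power channels must be finite")
  colnames(power) <- power_channel_names()
  meta$skill <- match.arg(meta$skill, skill_levels())
  meta$effort <- match.arg(meta$effort %||% "medium", effort_levels())
  stopifnot_scalar_number(meta$body_mass_kg, "body_mass_kg", 0, strict = TRUE)
  structure(list(coords = coords, time_s = as.numeric(time_s),
                 power = power, meta = meta),
            class = "ski_trial")
}

power_channel_names <- function() c("shoulder_l", "shoulder_r", "knee_l", "knee_r", "rta")

#' Controlled vocabularies of the pipeline
#'
#' Ordered skill levels, effort levels, and the sub-technique taxonomy
#' (skating absorbs its G2/G3/G4 variants; classification additionally uses
#' an `unknown` catch-all).
#'
#' @return character vector.
#' @export
skill_levels <- function() c("beginner", "intermediate", "advanced", "elite")

#' @rdname skill_levels
#' @export
effort_levels <- function() c("easy", "medium", "hard")

#' @rdname skill_levels
#' @export
technique_levels <- function() {
  c("double_pole", "kick_double_pole", "diagonal_stride",
    "standing_glide", "free_glide", "skating")
}

#' @export
print.ski_trial <- function(x, ...) {
  cat(sprintf("<ski_trial> %d frames @ %.0f Hz, %.1f s | %s / %s / %s (%.0f kg)\n",
              length(x$time_s),
              1 / median(diff(x$time_s)),
              diff(range(x$time_s)),
              x$meta$participant %||% "?", x$meta$skill, x$meta$effort,
              x$meta$body_mass_kg))
  invisible(x)
}

#' @export
dim.ski_trial <- function(x) dim(x$coords)

#' Long-table view of a trial's point cloud
#'
#' @param x a `ski_trial`.
#' @param ... unused.
#' @return tibble with columns `frame, time_s, label, x_mm, y_mm, z_mm`.
#' @export
as_tibble.ski_trial <- function(x, ...) {
  n <- dim(x$coords)[1]
  labels <- dimnames(x$coords)[[2]]
  tibble::tibble(
    frame = rep(seq_len(n), times = 76L),
    time_s = rep(x$time_s, times = 76L),
    label = rep(labels, each = n),
    x_mm = as.vector(x$coords[, , 1]),
    y_mm = as.vector(x$coords[, , 2]),
    z_mm = as.vector(x$coords[, , 3])
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# coordinates of one labelled point as a T x 3 matrix
point_xyz <- function(trial, label) {
  if (!label %in% dimnames(trial$coords)[[2]]) {
    abort(sprintf("trial does not contain required label '%s'", label))
  }
  m <- trial$coords[, label, , drop = FALSE]
  dim(m) <- c(dim(trial$coords)[1], 3L)
  colnames(m) <- c("x", "y", "z")
  m
}
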