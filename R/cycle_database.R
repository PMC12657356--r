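#' Assemble the structured cycle database
#'
#' Every row is one time-normalized cycle; columns are ordered as
#' `[time(1-101) | x(point 1-76), y(point 1-76), z(point 1-76), each 1-101 |
#' power upper, lower, RTA, each 1-101]`, i.e. `101 * (1 + 228 + 3) = 23,432`
#' features. The time block carries elapsed time within the cycle (seconds),
#' preserving cadence information. Power is summed bilaterally (upper =
#' left + right shoulder; lower = left + right knee; RTA kept separate) and
#' normalized to body mass (W/kg). Per-row metadata (participant, skill,
#' effort, technique slot) ride along for the statistical stages.
#'
#' @param cycles a `ski_cycles` object, a list of them (one per trial), or a
#'   plain list of `ski_cycle` objects.
#' @return list of class `ski_cycle_db`: numeric matrix `X` (n x 23432),
#'   `col_info` tibble (`block, channel, sample`), `block_scalars`
#'   (all 1 until [amplitude_normalize()]), `meta` tibble.
#' @export
build_cycle_database <- function(cycles) {
  cyc_list <- flatten_cycles(cycles)
  n <- length(cyc_list)
  if (n < 1L) abort("no cycles to assemble")
  ns <- length(cyc_list[[1]]$time_norm)
  labels <- dimnames(cyc_list[[1]]$coords)[[2]]
  p <- ns * (1L + 3L * length(labels) + 3L)

  channels <- c("time",
                paste0(rep(c("x", "y", "z"), each = length(labels)), ".",
                       rep(labels, times = 3L)),
                "power.upper", "power.lower", "power.rta")
  col_info <- tibble::tibble(
    block = rep(c("time", rep("coord", 3L * length(labels)), rep("power", 3L)),
                each = ns),
    channel = rep(channels, each = ns),
    sample = rep(seq_len(ns), times = length(channels))
  )

  X <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) X[i, ] <- cycle_feature_row(cyc_list[[i]], ns)
  meta <- purrr::map_dfr(cyc_list, function(cy) {
    tibble::tibble(participant = cy$meta$participant %||% NA_character_,
                   skill = cy$meta$skill %||% NA_character_,
                   effort = cy$meta$effort %||% NA_character_,
                   technique = cy$meta$technique %||% NA_character_,
                   body_mass_kg = cy$meta$body_mass_kg %||% NA_real_,
                   duration_s = cy$duration_s)
  })
  meta$cycle_id <- seq_len(n)
  structure(list(X = X, col_info = col_info,
                 block_scalars = c(time = 1, coord = 1, power = 1),
                 meta = meta),
            class = "ski_cycle_db")
}

flatten_cycles <- function(cycles) {
  if (inherits(cycles, "ski_cycles")) return(cycles$cycles)
  if (inherits(cycles, "ski_cycle")) return(list(cycles))
  out <- list()
  for (el in cycles) {
    if (inherits(el, "ski_cycles")) out <- c(out, el$cycles)
    else if (inherits(el, "ski_cycle")) out <- c(out, list(el))
    else abort("`cycles` must contain ski_cycle / ski_cycles objects")
  }
  out
}

cycle_feature_row <- function(cy, ns) {
  mass <- cy$meta$body_mass_kg %||% 1
  c(cy$time_norm * cy$duration_s,
    as.vector(cy$coords[, , 1]), as.vector(cy$coords[, , 2]),
    as.vector(cy$coords[, , 3]),
    (cy$power[, "shoulder_l"] + cy$power[, "shoulder_r"]) / mass,
    (cy$power[, "knee_l"] + cy$power[, "knee_r"]) / mass,
    cy$power[, "rta"] / mass)
}

#' @export
print.ski_cycle_db <- function(x, ...) {
  cat(sprintf("<ski_cycle_db> %d cycles x %d features (block scalars: %s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s=%.3g", names(x$block_scalars), x$block_scalars),
                    collapse = ", ")))
  invisible(x)
}

#' Amplitude-normalize the database blocks
#'
#' The time, coordinate and power blocks carry different units (seconds,
#' millimetres, W/kg). Each block is multiplied by one scalar so its pooled
#' amplitude range matches the coordinate block's range, making the PCA
#' variance budget comparable across units. Scalars are stored for exact
#' inversion; a zero-range block gets scalar 1 with a warning.
#'
#' @param db a `ski_cycle_db` from [build_cycle_database()].
#' @return the database with scaled `X` and updated `block_scalars`.
#' @export
amplitude_normalize <- function(db) {
  if (any(db$block_scalars != 1)) abort("database is already amplitude-normalized")
  ranges <- vapply(c("time", "coord", "power"), function(b) {
    v <- db$X[, db$col_info$block == b, drop = FALSE]
    diff(range(v))
  }, numeric(1))
  target <- ranges[["coord"]]
  scalars <- vapply(names(ranges), function(b) {
    if (ranges[[b]] <= 0) {
      warn(sprintf("block '%s' has zero amplitude range; scalar set to 1", b))
      return(1)
    }
    target / ranges[[b]]
  }, numeric(1))
  for (b in names(scalars)) {
    db$X[, db$col_info$block == b] <- db$X[, db$col_info$block == b] * scalars[[b]]
  }
  db$block_scalars <- scalars
  db
}

#' @rdname amplitude_normalize
#' @export
invert_amplitude <- function(db) {
  for (b in names(db$block_scalars)) {
    db$X[, db$col_info$block == b] <-
      db$X[, db$col_info$block == b] / db$block_scalars[[b]]
  }
  db$block_scalars <- c(time = 1, coord = 1, power = 1)
  db
}
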