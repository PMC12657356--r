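#' Write / read a trial as a long-table file pair
#'
#' The interchange format is a diff-able pair of delimited tables sharing a
#' path stem: `<stem>_points.csv` (one row per frame x point: `frame, time_s,
#' label, x_mm, y_mm, z_mm`), `<stem>_power.csv` (one row per frame with the
#' five joint-power channels in watts) and `<stem>_meta.csv` (key/value
#' metadata). Units are carried in the column names; a table whose coordinate
#' columns do not declare units is rejected rather than guessed at.
#'
#' @param trial a [ski_trial()].
#' @param stem path stem (without the `_points.csv` suffix).
#' @return `write_trial()` returns `stem` invisibly; `read_trial()` a
#'   `ski_trial`.
#' @export
write_trial <- function(trial, stem) {
  if (!inherits(trial, "ski_trial")) abort("`trial` must be a ski_trial")
  if (dim(trial$coords)[1] == 0L) abort("refusing to write an empty trial (T = 0)")
  if (any(!is.finite(trial$coords))) abort("refusing to write non-finite coordinates")
  readr::write_csv(as_tibble(trial), paste0(stem, "_points.csv"))
  pw <- tibble::as_tibble(trial$power)
  names(pw) <- paste0(names(pw), "_w")
  pw <- dplyr::bind_cols(tibble::tibble(frame = seq_along(trial$time_s),
                                        time_s = trial$time_s), pw)
  readr::write_csv(pw, paste0(stem, "_power.csv"))
  meta <- tibble::tibble(
    key = c("participant", "skill", "effort", "body_mass_kg"),
    value = c(as.character(trial$meta$participant),
              trial$meta$skill, trial$meta$effort,
              format(trial$meta$body_mass_kg, digits = 15))
  )
  readr::write_csv(meta, paste0(stem, "_meta.csv"))
  invisible(stem)
}

#' @param model a [point_model()]; loading is label-keyed, so row order in the
#'   file does not matter, but every registry label must be present.
#' @rdname write_trial
#' @export
read_trial <- function(stem, model = point_model()) {
  pts_path <- paste0(stem, "_points.csv")
  if (!file.exists(pts_path)) abort(sprintf("no such file: %s", pts_path))
  pts <- readr::read_csv(pts_path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "time_s", "x_mm", "y_mm", "z_mm", "label")
  if (!all(need %in% names(pts))) {
    miss <- setdiff(need, names(pts))
    if (any(c("x_mm", "y_mm", "z_mm", "time_s") %in% miss)) {
      abort(sprintf(
        "point table lacks unit-bearing column(s) %s; units are never guessed",
        paste(miss, collapse = ", ")))
    }
    abort(sprintf("point table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  missing_labels <- setdiff(model$label, unique(pts$label))
  if (length(missing_labels)) {
    abort(sprintf("trial is missing required label(s): %s",
                  paste(missing_labels, collapse = ", ")))
  }
  pts <- dplyr::arrange(pts, .data$time_s, .data$frame)
  frames <- sort(unique(pts$frame))
  n <- length(frames)
  coords <- array(NA_real_, c(n, 76L, 3L),
                  dimnames = list(NULL, model$label, c("x", "y", "z")))
  fidx <- match(pts$frame, frames)
  lidx <- match(pts$label, model$label)
  coords[cbind(fidx, lidx, 1L)] <- pts$x_mm
  coords[cbind(fidx, lidx, 2L)] <- pts$y_mm
  coords[cbind(fidx, lidx, 3L)] <- pts$z_mm
  if (anyNA(coords)) abort("point table has missing frame x label combinations")
  time_s <- vapply(frames, function(f) pts$time_s[match(f, pts$frame)], numeric(1))

  pw <- readr::read_csv(paste0(stem, "_power.csv"), show_col_types = FALSE,
                        progress = FALSE)
  wcols <- paste0(power_channel_names(), "_w")
  if (!all(wcols %in% names(pw))) {
    abort(sprintf("power table lacks unit-bearing channel column(s): %s",
                  paste(setdiff(wcols, names(pw)), collapse = ", ")))
  }
  pw <- dplyr::arrange(pw, .data$frame)
  power <- as.matrix(pw[match(frames, pw$frame), wcols])
  colnames(power) <- power_channel_names()

  mt <- readr::read_csv(paste0(stem, "_meta.csv"), show_col_types = FALSE,
                        progress = FALSE, col_types = readr::cols(.default = "c"))
  meta <- as.list(setNames(mt$value, mt$key))
  meta$body_mass_kg <- as.numeric(meta$body_mass_kg)
  ski_trial(coords, time_s, power, meta)
}

#' Write / read a ground-truth sidecar table
#'
#' The simulator's per-cycle oracle: boundary frame, start/end frames,
#' technique label and realized embedded effects.
#'
#' @param truth a `ski_ground_truth` (see [generate_trial()]).
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(as_tibble(truth), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  new_ground_truth(
    cycle_boundaries = df$boundary_frame,
    technique_labels = df$technique,
    effects = dplyr::select(df, "cycle", "frontal_area_m2", "ski_angle_deg",
                            "peak_upper_wkg", "peak_lower_wkg")
  )
}

#' Write / read a GNSS series table
#'
#' Plain delimited table with columns `time_s, x_m, y_m, elev_m` (4 Hz local
#' coordinates plus elevation).
#'
#' @param series a tibble with those columns (e.g. from
#'   [generate_gnss_track()]).
#' @param path file path.
#' @export
write_gnss <- function(series, path) {
  need <- c("time_s", "x_m", "y_m", "elev_m")
  if (!all(need %in% names(series))) {
    abort(sprintf("GNSS series must have columns %s", paste(need, collapse = ", ")))
  }
  readr::write_csv(series[need], path)
  invisible(path)
}

#' @rdname write_gnss
#' @export
read_gnss <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "x_m", "y_m", "elev_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("GNSS table missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  if (any(diff(df$time_s) <= 0)) abort("GNSS time must be strictly increasing")
  if (any(!is.finite(as.matrix(df[need])))) abort("GNSS coordinates must be finite")
  tibble::as_tibble(df[need])
}

#' Load a run configuration with validated defaults
#'
#' Reads a YAML configuration organised by module section and resolves every
#' threshold against the pipeline defaults: segmentation threshold 10 mm, 101
#' samples per cycle, 90% variance retention, alpha = 0.05. Unknown keys and
#' type mismatches are hard errors (named by key path), never silently
#' ignored.
#'
#' @param path path to a YAML file; an empty or absent-but-`NULL` path yields
#'   all defaults.
#' @return a named list of module settings.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    preprocess = list(threshold_mm = 10, n_samples = 101, max_cycle_s = 10),
    pca = list(retention = 90),
    stats = list(alpha = 0.05),
    classify = list(folds = 5, cost = 1)
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  for (section in names(user)) {
    if (!section %in% names(defaults)) {
      abort(sprintf("unknown config section '%s'", section))
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(defaults[[section]])) {
        abort(sprintf("unknown config key '%s.%s'", section, key))
      }
      val <- user[[section]][[key]]
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
        abort(sprintf("config key '%s.%s' must be a single number", section, key))
      }
      defaults[[section]][[key]] <- val
    }
  }
  r <- defaults$pca$retention
  if (r <= 0 || r > 100) abort("config key 'pca.retention' must be in (0, 100]")
  a <- defaults$stats$alpha
  if (a <= 0 || a >= 1) abort("config key 'stats.alpha' must be in (0, 1)")
  if (defaults$preprocess$threshold_mm < 0) abort("config key 'preprocess.threshold_mm' must be >= 0")
  defaults
}
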