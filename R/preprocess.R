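#' Align a trial to the pelvis-fixed reference frame
#'
#' At every frame a proper 3x3 rotation is computed from the pelvis landmarks
#' (left/right ASIS and PSIS): the mediolateral axis joins the ASIS pair, the
#' forward axis is the ASIS-midpoint minus PSIS-midpoint direction
#' orthogonalized against it, and the vertical axis completes the right-handed
#' triad. All 76 points are re-expressed by applying the inverse rotation, so
#' heading changes around the track are removed while translations are left to
#' [reference_to_t12()]. Applying a constant global rotation to the input
#' leaves the output unchanged.
#'
#' @param trial a [ski_trial()].
#' @return the aligned `ski_trial`, with an `alignment` element storing the
#'   per-frame rotations and the reference labels used.
#' @export
align_to_pelvis <- function(trial) {
  asl <- point_xyz(trial, "asis_l"); asr <- point_xyz(trial, "asis_r")
  psl <- point_xyz(trial, "psis_l"); psr <- point_xyz(trial, "psis_r")
  ml <- asr - asl                      # rightward
  fwd_raw <- (asl + asr) / 2 - (psl + psr) / 2
  ml_n <- sqrt(rowSums(ml^2))
  proj <- rowSums(fwd_raw * ml) / pmax(ml_n^2, 1e-300)
  fwd <- fwd_raw - ml * proj
  fwd_n <- sqrt(rowSums(fwd^2))
  bad <- which(ml_n < 1e-6 | fwd_n < 1e-6)
  if (length(bad)) {
    abort(sprintf("degenerate pelvis geometry at frame %d", bad[1]))
  }
  x_ax <- fwd / fwd_n                  # forward
  y_ax <- -ml / ml_n                   # leftward
  z_ax <- cross3_rows(x_ax, y_ax)      # up; det +1 by construction

  nt <- dim(trial$coords)[1]
  out <- trial$coords
  for (j in seq_len(dim(trial$coords)[2])) {
    p <- trial$coords[, j, ]
    if (nt == 1L) dim(p) <- c(1L, 3L)
    out[, j, 1L] <- rowSums(p * x_ax)
    out[, j, 2L] <- rowSums(p * y_ax)
    out[, j, 3L] <- rowSums(p * z_ax)
  }
  trial$coords <- out
  trial$alignment <- list(
    rotation = list(x = x_ax, y = y_ax, z = z_ax),
    reference_labels = c("asis_l", "asis_r", "psis_l", "psis_r"),
    t12_referenced = isTRUE(trial$alignment$t12_referenced)
  )
  trial
}

#' Reference a trial to the T12 spinous process
#'
#' Subtracts the T12 position from every point at every frame, removing small
#' linear translations of the point cloud through the trial. After this step
#' T12 sits exactly at the origin in every frame; inter-point vectors are
#' preserved exactly.
#'
#' @param trial a [ski_trial()] (usually already pelvis-aligned).
#' @return the referenced `ski_trial`.
#' @export
reference_to_t12 <- function(trial) {
  t12 <- point_xyz(trial, "t12")
  for (ax in 1:3) {
    trial$coords[, , ax] <- trial$coords[, , ax] - t12[, ax]
  }
  if (is.null(trial$alignment)) trial$alignment <- list()
  trial$alignment$t12_referenced <- TRUE
  trial
}

#' Segment propulsion cycles from left-toe displacement
#'
#' Computes the per-frame Euclidean norm of the left toe's displacement about
#' its trial-mean position and detects local maxima exceeding the threshold
#' (default 10 mm = 1 cm). A two-pass rule suppresses noise doublets: after a
#' first pass, peaks closer than 0.25 x the median inter-peak interval are
#' pruned keeping the higher peak. Cycles are the half-open spans between
#' consecutive qualifying peaks.
#'
#' Before peak detection the norm signal is conditioned with a centred
#' moving average of `smooth_s` seconds (default 0.1 s): sensor noise turns
#' every wiggle riding on the displacement curve into a local maximum whose
#' height clears the threshold, so some smoothing is required by the
#' segmentation itself; 0.1 s is an order of magnitude below any plausible
#' propulsion period and does not move well-separated peaks.
#'
#' @param trial an aligned, referenced [ski_trial()].
#' @param threshold_mm displacement-norm threshold (millimetres).
#' @param smooth_s width of the moving-average window (seconds); 0 disables
#'   smoothing.
#' @return a tibble with one row per cycle: `cycle, start_frame, end_frame`
#'   (the next peak; spans are `[start, end)`), `duration_s`; the qualifying
#'   peak frames are attached as attribute `"peaks"`. Zero or one peak yields
#'   an empty tibble.
#' @export
segment_cycles <- function(trial, threshold_mm = 10, smooth_s = 0.1) {
  if (dim(trial$coords)[1] < 2L) abort("trial must have at least 2 frames")
  toe <- point_xyz(trial, "toe_l")
  disp <- sweep(toe, 2, colMeans(toe))
  nrm <- sqrt(rowSums(disp^2))
  if (smooth_s > 0) {
    rate <- 1 / median(diff(trial$time_s))
    nrm <- moving_average(nrm, max(1L, round(smooth_s * rate)))
  }
  peaks <- find_norm_peaks(nrm, threshold_mm)
  empty <- tibble::tibble(cycle = integer(), start_frame = integer(),
                          end_frame = integer(), duration_s = numeric())
  attr(empty, "peaks") <- integer()
  if (length(peaks) < 2L) return(empty)
  out <- tibble::tibble(
    cycle = seq_len(length(peaks) - 1L),
    start_frame = peaks[-length(peaks)],
    end_frame = peaks[-1],
    duration_s = trial$time_s[peaks[-1]] - trial$time_s[peaks[-length(peaks)]]
  )
  attr(out, "peaks") <- peaks
  out
}

# centred moving average with edge-value padding (length preserved)
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, rep(1 / (2 * half + 1), 2 * half + 1)))[
    (half + 1):(half + length(x))]
}

# local maxima above `threshold`: candidate peaks are merged when the valley
# separating two neighbours is shallower than threshold/2 (one excursion, not
# two), then pruned by the two-pass minimum-distance rule
find_norm_peaks <- function(x, threshold) {
  pk <- pracma::findpeaks(x, minpeakheight = threshold)
  if (is.null(pk)) return(integer())
  pos <- sort(as.integer(pk[, 2]))
  repeat {
    if (length(pos) < 2L) break
    merged <- FALSE
    i <- 1L
    while (i < length(pos)) {
      valley <- min(x[pos[i]:pos[i + 1]])
      if (min(x[pos[i]], x[pos[i + 1]]) - valley < threshold / 2) {
        drop <- if (x[pos[i]] < x[pos[i + 1]]) i else i + 1L
        pos <- pos[-drop]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  if (length(pos) >= 3L) {
    mindist <- 0.25 * median(diff(pos))
    keep <- order(-x[pos])            # prune by height, keep the taller
    kept <- integer()
    for (i in keep) {
      if (!length(kept) || all(abs(pos[kept] - pos[i]) >= mindist)) {
        kept <- c(kept, i)
      }
    }
    pos <- sort(pos[kept])
  }
  pos
}

#' Time-normalize one segmented cycle to 101 samples
#'
#' Resamples every coordinate channel (76 x 3) and the five power channels to
#' `n_samples` evenly spaced points across the segment using a shape-preserving
#' piecewise cubic Hermite interpolant (PCHIP). Endpoint samples reproduce the
#' segment's endpoint values exactly and the original duration is stored.
#'
#' @param trial an aligned [ski_trial()].
#' @param start_frame,end_frame inclusive frame bounds of the segment (the
#'   segment's peaks).
#' @param n_samples number of output samples (default 101).
#' @return a list of class `ski_cycle`: `time_norm` (0..1), `duration_s`,
#'   `coords` (`n_samples x 76 x 3`, mm), `power` (`n_samples x 5`, W), `meta`.
#' @export
time_normalize <- function(trial, start_frame, end_frame, n_samples = 101L) {
  idx <- start_frame:end_frame
  if (length(idx) < 4L) {
    abort("segment shorter than 4 samples cannot be interpolated")
  }
  ti <- trial$time_s[idx]
  tq <- seq(ti[1], ti[length(ti)], length.out = n_samples)
  nc <- dim(trial$coords)[2]
  coords <- array(NA_real_, c(n_samples, nc, 3L),
                  dimnames = list(NULL, dimnames(trial$coords)[[2]], c("x", "y", "z")))
  for (j in seq_len(nc)) {
    for (ax in 1:3) {
      coords[, j, ax] <- pracma::pchip(ti, trial$coords[idx, j, ax], tq)
    }
  }
  power <- matrix(NA_real_, n_samples, 5L,
                  dimnames = list(NULL, power_channel_names()))
  for (k in 1:5) power[, k] <- pracma::pchip(ti, trial$power[idx, k], tq)
  structure(list(
    time_norm = seq(0, 1, length.out = n_samples),
    duration_s = ti[length(ti)] - ti[1],
    coords = coords, power = power,
    meta = trial$meta
  ), class = "ski_cycle")
}

#' @export
print.ski_cycle <- function(x, ...) {
  cat(sprintf("<ski_cycle> %.3f s, %d samples | %s / %s\n", x$duration_s,
              length(x$time_norm), x$meta$skill %||% "?", x$meta$technique %||% "?"))
  invisible(x)
}

#' Align, reference, segment and time-normalize a trial
#'
#' The full preprocessing chain in its fixed order: pelvis alignment, T12
#' referencing, left-toe segmentation, PCHIP time normalization. Segments
#' shorter than 4 samples or longer than `max_cycle_s` (glide coasting, not
#' propulsion) are discarded with a warning.
#'
#' @param trial a raw [ski_trial()].
#' @param threshold_mm segmentation threshold (mm).
#' @param n_samples samples per normalized cycle.
#' @param max_cycle_s maximum admissible cycle duration (seconds).
#' @return list of class `ski_cycles`: `cycles` (list of `ski_cycle`) and
#'   `segments` (the tibble from [segment_cycles()], restricted to kept rows).
#' @export
preprocess_trial <- function(trial, threshold_mm = 10, n_samples = 101L,
                             max_cycle_s = 10, smooth_s = 0.1) {
  aligned <- reference_to_t12(align_to_pelvis(trial))
  seg <- segment_cycles(aligned, threshold_mm, smooth_s)
  keep <- rep(TRUE, nrow(seg))
  for (i in seq_len(nrow(seg))) {
    len <- seg$end_frame[i] - seg$start_frame[i] + 1L
    if (len < 4L || seg$duration_s[i] > max_cycle_s) keep[i] <- FALSE
  }
  if (any(!keep)) {
    warn(sprintf("discarded %d segment(s) shorter than 4 samples or longer than %g s",
                 sum(!keep), max_cycle_s))
  }
  kept <- seg[keep, , drop = FALSE]
  cycles <- purrr::map(seq_len(nrow(kept)), function(i) {
    time_normalize(aligned, kept$start_frame[i], kept$end_frame[i], n_samples)
  })
  structure(list(cycles = cycles, segments = kept), class = "ski_cycles")
}

#' Cycle-duration (cadence) summary and one-way ANOVA across skill
#'
#' Summarizes per-skill cycle-duration distributions (for violin plotting) and
#' tests for a mean difference with a fixed-effects one-way ANOVA. Groups with
#' fewer than 2 cycles are excluded with a warning. When between- and
#' within-group variance are both zero the test is undefined; by convention
#' the p-value is reported as 1.
#'
#' @param durations numeric vector of cycle durations (seconds).
#' @param skill factor/character of the same length (skill level per cycle).
#' @return list of class `ski_cadence`: `groups` tibble (`skill, n, mean_s,
#'   sd_s, durations` list-column) and `anova` tibble (`f_statistic, df1,
#'   df2, p_value`).
#' @export
cadence_summary <- function(durations, skill) {
  df <- tibble::tibble(duration_s = durations,
                       skill = factor(skill, levels = skill_levels()))
  df <- df[stats::complete.cases(df), ]
  counts <- table(droplevels(df$skill))
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warn(sprintf("excluding group(s) with < 2 cycles: %s",
                 paste(small, collapse = ", ")))
    df <- df[!df$skill %in% small, ]
  }
  df$skill <- droplevels(df$skill)
  if (nlevels(df$skill) < 2L) abort("cadence ANOVA needs at least 2 groups with >= 2 cycles")
  groups <- df |>
    dplyr::group_by(.data$skill) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_s = mean(.data$duration_s),
                     sd_s = sd(.data$duration_s),
                     durations = list(.data$duration_s),
                     .groups = "drop")
  test <- oneway_f(df$duration_s, df$skill)
  structure(list(groups = groups,
                 anova = tibble::tibble(f_statistic = test$f, df1 = test$df1,
                                        df2 = test$df2, p_value = test$p)),
            class = "ski_cadence")
}

# classic fixed-effects one-way ANOVA; degenerate zero-variance case -> p = 1
oneway_f <- function(y, g) {
  g <- droplevels(factor(g))
  k <- nlevels(g); n <- length(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df1 <- k - 1; df2 <- n - k
  if (ssw < 1e-300 * max(1, abs(mean(y)))^2) {
    if (ssb < 1e-300 * max(1, abs(mean(y)))^2) {
      return(list(f = 0, df1 = df1, df2 = df2, p = 1))
    }
    return(list(f = Inf, df1 = df1, df2 = df2, p = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
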