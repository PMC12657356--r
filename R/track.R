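#' Segment GNSS samples into track laps
#'
#' Lap boundaries are recurrent closest approaches to the start point: local
#' minima of the distance-to-start series that fall inside the gate radius,
#' pruned so no two boundaries are closer than half the median inter-boundary
#' spacing. The first sample always opens lap 1. If no recurrence is found
#' the whole series is returned as a single lap with a warning.
#'
#' @param series GNSS tibble (`time_s, x_m, y_m, elev_m`) or a `ski_gnss`.
#' @param gate_radius_m gate radius around the start point (default 5 m).
#' @return integer vector of lap-start sample indices (first element 1).
#' @export
segment_laps <- function(series, gate_radius_m = 5) {
  if (inherits(series, "ski_gnss")) series <- series$series
  d <- sqrt((series$x_m - series$x_m[1])^2 + (series$y_m - series$y_m[1])^2)
  n <- length(d)
  inside <- which(d < gate_radius_m)
  # group in-gate samples into passages (noise may flicker in and out, so
  # gaps of a few samples stay within one passage); one boundary per passage,
  # at its closest approach
  grp <- cumsum(c(1L, diff(inside) > 5L))
  cand <- vapply(split(inside, grp), function(ix) ix[which.min(d[ix])],
                 integer(1))
  cand <- unname(cand[cand > 2L & cand < n - 1L]) # interior passages only
  if (!length(cand)) {
    warn("no recurrence at the start gate; returning a single lap")
    return(1L)
  }
  if (length(cand) >= 2L) {
    mindist <- 0.5 * median(diff(cand))
    keep <- order(d[cand]) # prune by closeness to the gate
    kept <- integer()
    for (i in keep) {
      if (!length(kept) || all(abs(cand[kept] - cand[i]) >= mindist)) {
        kept <- c(kept, i)
      }
    }
    cand <- sort(cand[kept])
  }
  b <- c(1L, cand)
  # a trailing fragment (the final closing approach) is not a lap of its own
  while (length(b) > 1L &&
         (n - b[length(b)]) < 0.5 * median(diff(c(b, n)))) {
    b <- b[-length(b)]
  }
  b
}

#' Demean laps and average them into a mean lap
#'
#' Each lap is demeaned (its mean x/y/elevation removed, discarding
#' positional drift between revolutions), resampled to a common equal
#' arc-length parameterization, and averaged point-wise into the mean lap.
#'
#' @param series GNSS tibble or `ski_gnss`.
#' @param boundaries lap-start indices from [segment_laps()] (computed if
#'   omitted).
#' @param n_points resampling resolution per lap (default 400).
#' @param gate_radius_m forwarded to [segment_laps()] when boundaries are
#'   computed here.
#' @return object of class `ski_track`: `laps` (list of resampled, demeaned
#'   tibbles `s, x_m, y_m, elev_m`), `mean_lap`, `lap_boundaries`.
#' @export
demean_laps <- function(series, boundaries = NULL, n_points = 400L,
                        gate_radius_m = 5) {
  if (inherits(series, "ski_gnss")) series <- series$series
  if (is.null(boundaries)) boundaries <- segment_laps(series, gate_radius_m)
  ends <- c(boundaries[-1] - 1L, nrow(series))
  laps <- purrr::map(seq_along(boundaries), function(i) {
    seg <- series[boundaries[i]:ends[i], , drop = FALSE]
    x <- seg$x_m - mean(seg$x_m)
    y <- seg$y_m - mean(seg$y_m)
    e <- seg$elev_m - mean(seg$elev_m)
    # arc length measured on a lightly smoothed path: positional noise
    # inflates raw chord lengths and jitters the common parameterization
    xs <- moving_average(x, 5L); ys <- moving_average(y, 5L)
    arc <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
    if (arc[length(arc)] <= 0) abort("degenerate lap with zero path length")
    frac <- arc / arc[length(arc)]
    sq <- seq(0, 1, length.out = n_points)
    tibble::tibble(s = sq,
                   x_m = approx(frac, x, sq, ties = mean)$y,
                   y_m = approx(frac, y, sq, ties = mean)$y,
                   elev_m = approx(frac, e, sq, ties = mean)$y)
  })
  mean_lap <- laps[[1]]
  if (length(laps) > 1L) {
    for (cn in c("x_m", "y_m", "elev_m")) {
      mean_lap[[cn]] <- rowMeans(do.call(cbind, purrr::map(laps, cn)))
    }
  }
  structure(list(laps = laps, mean_lap = mean_lap,
                 lap_boundaries = as.integer(boundaries)),
            class = "ski_track")
}

#' @export
print.ski_track <- function(x, ...) {
  cat(sprintf("<ski_track> %d lap(s), mean lap of %d points\n",
              length(x$laps), nrow(x$mean_lap)))
  invisible(x)
}

#' Export / read a reconstructed track as 3D polylines
#'
#' Long table with `lap` (0 = mean lap), `s` (arc-length fraction) and the
#' demeaned 3D coordinates; the round trip is exact to CSV precision.
#'
#' @param model a `ski_track`.
#' @param path output CSV path.
#' @export
export_track <- function(model, path) {
  if (!inherits(model, "ski_track") || !length(model$laps)) {
    abort("`model` must be a non-empty ski_track")
  }
  rows <- dplyr::bind_rows(
    dplyr::mutate(model$mean_lap, lap = 0L),
    purrr::imap_dfr(model$laps, ~ dplyr::mutate(.x, lap = .y))
  )
  readr::write_csv(rows[, c("lap", "s", "x_m", "y_m", "elev_m")], path)
  invisible(path)
}

#' @rdname export_track
#' @export
read_track <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  laps <- purrr::map(sort(unique(df$lap[df$lap > 0])), function(l) {
    tibble::as_tibble(df[df$lap == l, c("s", "x_m", "y_m", "elev_m")])
  })
  structure(list(laps = laps,
                 mean_lap = tibble::as_tibble(
                   df[df$lap == 0, c("s", "x_m", "y_m", "elev_m")]),
                 lap_boundaries = NA_integer_),
            class = "ski_track")
}
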