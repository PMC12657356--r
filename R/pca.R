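#' Principal component decomposition of the cycle database
#'
#' Column-mean-centred PCA via singular value decomposition of the centred
#' matrix (no per-column standardization: the blocks were amplitude-normalized
#' instead). Loadings are orthonormal; explained variances come from the
#' singular values; a fixed sign convention (each loading's largest-magnitude
#' element made positive) makes score signs, and therefore the 95th/5th
#' percentile tail choices downstream, reproducible.
#'
#' @param db a `ski_cycle_db` (usually after [amplitude_normalize()]), or a
#'   plain numeric matrix of cycle rows.
#' @param retention cumulative explained-variance retention threshold
#'   (percent, default 90).
#' @return object of class `ski_pca`: `mean`, `loadings` (p x k, orthonormal),
#'   `explained_var` (percent, non-increasing), `scores` (n x k, zero column
#'   means), `singular_values`, `retained_k`, plus the database `col_info`,
#'   `block_scalars` and `meta` carried through.
#' @export
fit_pca <- function(db, retention = 90) {
  if (is.matrix(db)) {
    db <- structure(list(
      X = db,
      col_info = tibble::tibble(block = "coord",
                                channel = paste0("f", seq_len(ncol(db))),
                                sample = 1L),
      block_scalars = c(time = 1, coord = 1, power = 1),
      meta = tibble::tibble(cycle_id = seq_len(nrow(db)))
    ), class = "ski_cycle_db")
  }
  if (!inherits(db, "ski_cycle_db")) abort("`db` must be a ski_cycle_db or matrix")
  n <- nrow(db$X)
  if (n < 2L) abort("PCA needs at least 2 cycles")
  mu <- colMeans(db$X)
  Xc <- sweep(db$X, 2, mu)
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  if (total < 1e-12) {
    k <- 0L
    expl <- rep(0, length(sv$d))
  } else {
    expl <- 100 * sv$d^2 / total
    k <- NULL
  }
  # fixed sign convention: largest |loading| element positive
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  retained <- if (is.null(k)) retain_components(expl, retention) else 0L
  structure(list(mean = mu, loadings = sv$v, explained_var = expl,
                 scores = scores, singular_values = sv$d,
                 retained_k = retained, retention = retention,
                 col_info = db$col_info, block_scalars = db$block_scalars,
                 meta = db$meta),
            class = "ski_pca")
}

#' @export
print.ski_pca <- function(x, ...) {
  cat(sprintf("<ski_pca> %d cycles, %d features | %d PCs retained (%.1f%% of variance at %.0f%% threshold)\n",
              nrow(x$scores), length(x$mean), x$retained_k,
              sum(x$explained_var[seq_len(x$retained_k)]), x$retention))
  invisible(x)
}

#' Number of components retained at a cumulative-variance threshold
#'
#' @param explained_var per-component explained variances (percent,
#'   nonnegative).
#' @param threshold cumulative percentage to reach (default 90).
#' @return the smallest K whose cumulative sum reaches the threshold; if the
#'   total never reaches it, the full length with a warning.
#' @export
retain_components <- function(explained_var, threshold = 90) {
  if (any(explained_var < 0)) abort("explained variances must be nonnegative")
  cum <- cumsum(explained_var)
  k <- which(cum >= threshold - 1e-9)
  if (!length(k)) {
    warn(sprintf("total explained variance %.2f%% never reaches %.0f%%; retaining all %d components",
                 cum[length(cum)], threshold, length(explained_var)))
    return(length(explained_var))
  }
  k[1]
}

#' Retained PC scores with cycle metadata
#'
#' @param model a `ski_pca`.
#' @param k number of leading components (default the retained count).
#' @return tibble: metadata columns plus `PC1..PCk`.
#' @export
pc_scores <- function(model, k = model$retained_k) {
  k <- max(1L, min(k, ncol(model$scores)))
  sc <- model$scores[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(model$meta, tibble::as_tibble(sc))
}

#' Multi-component reconstruction of beginner / elite avatars
#'
#' Implements the reconstruction `x_hat = x_bar + sum_j u_j * z_j` where each
#' selected component contributes its 95th-percentile score when its
#' relationship with skill is positive (5th when negative) for the "elite"
#' avatar, and the opposite tail for the "beginner" avatar. Percentiles are
#' computed over all cycles' scores with linear interpolation between order
#' statistics. With an empty selection both avatars equal the grand mean (with
#' a warning).
#'
#' @param model a `ski_pca`.
#' @param pcs integer indices of selected components (within the retained set).
#' @param directions numeric vector of +1/-1, the sign of each component's
#'   relationship with skill.
#' @return object of class `ski_mcr`: feature-space avatars `elite` and
#'   `beginner`, the `z` tail scores used, and `unscaled` cycle-shaped
#'   versions (block scaling inverted: time in s, coordinates in mm, power in
#'   W/kg) for animation.
#' @export
mcr_reconstruct <- function(model, pcs, directions) {
  if (length(pcs) == 0L) {
    warn("empty PC selection: both avatars equal the mean cycle")
    z <- numeric(0)
    elite <- beginner <- model$mean
  } else {
    if (length(directions) != length(pcs)) abort("one direction per selected PC is required")
    if (any(pcs > model$retained_k)) {
      abort("selected PCs must lie within the retained set")
    }
    z_hi <- vapply(pcs, function(j) quantile(model$scores[, j], 0.95,
                                             names = FALSE, type = 7), numeric(1))
    z_lo <- vapply(pcs, function(j) quantile(model$scores[, j], 0.05,
                                             names = FALSE, type = 7), numeric(1))
    if (any(z_hi - z_lo < 1e-12)) abort("degenerate score distribution for a selected PC")
    z_elite <- ifelse(directions > 0, z_hi, z_lo)
    z_beginner <- ifelse(directions > 0, z_lo, z_hi)
    U <- model$loadings[, pcs, drop = FALSE]
    elite <- model$mean + as.vector(U %*% z_elite)
    beginner <- model$mean + as.vector(U %*% z_beginner)
    z <- tibble::tibble(pc = pcs, direction = directions,
                        z_elite = z_elite, z_beginner = z_beginner)
  }
  structure(list(
    elite = elite, beginner = beginner, pcs = pcs,
    directions = if (length(pcs)) directions else numeric(0), z = z,
    unscaled = list(elite = feature_to_cycle(elite, model),
                    beginner = feature_to_cycle(beginner, model)),
    col_info = model$col_info
  ), class = "ski_mcr")
}

# reshape one feature vector back to cycle form, inverting block scaling
feature_to_cycle <- function(x, model) {
  ci <- model$col_info
  for (b in names(model$block_scalars)) {
    x[ci$block == b] <- x[ci$block == b] / model$block_scalars[[b]]
  }
  if (!any(ci$block == "time")) return(list(features = x))
  ns <- max(ci$sample)
  coord_ch <- unique(ci$channel[ci$block == "coord"])
  labels <- unique(sub("^[xyz]\\.", "", coord_ch))
  coords <- array(NA_real_, c(ns, length(labels), 3L),
                  dimnames = list(NULL, labels, c("x", "y", "z")))
  for (ax in c("x", "y", "z")) {
    for (lab in labels) {
      coords[, lab, ax] <- x[ci$channel == paste0(ax, ".", lab)]
    }
  }
  list(time_s = x[ci$channel == "time"],
       coords = coords,
       power = cbind(upper = x[ci$channel == "power.upper"],
                     lower = x[ci$channel == "power.lower"],
                     rta = x[ci$channel == "power.rta"]))
}

#' Export avatar animations as a long-table frame sequence
#'
#' Writes 101 frames of the 76-point cloud for both avatars (columns `avatar,
#' frame, label, x_mm, y_mm, z_mm`), numerically identical to the
#' reconstruction's unscaled coordinates.
#'
#' @param rec a `ski_mcr` from [mcr_reconstruct()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_animation <- function(rec, path) {
  rows <- purrr::map_dfr(c("beginner", "elite"), function(av) {
    cyc <- rec$unscaled[[av]]
    ns <- dim(cyc$coords)[1]
    labels <- dimnames(cyc$coords)[[2]]
    tibble::tibble(avatar = av,
                   frame = rep(seq_len(ns), times = length(labels)),
                   label = rep(labels, each = ns),
                   x_mm = as.vector(cyc$coords[, , 1]),
                   y_mm = as.vector(cyc$coords[, , 2]),
                   z_mm = as.vector(cyc$coords[, , 3]))
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname export_animation
#' @export
read_animation <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
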