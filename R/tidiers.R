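#' Tidy a fitted PCA model
#'
#' @param x a `ski_pca`.
#' @param ... unused.
#' @return tibble `pc, explained_var, cumulative_var, retained`.
#' @export
tidy.ski_pca <- function(x, ...) {
  tibble::tibble(pc = seq_along(x$explained_var),
                 explained_var = x$explained_var,
                 cumulative_var = cumsum(x$explained_var),
                 retained = seq_along(x$explained_var) <= x$retained_k)
}

#' @rdname tidy.ski_pca
#' @export
glance.ski_pca <- function(x, ...) {
  tibble::tibble(n_cycles = nrow(x$scores),
                 n_features = length(x$mean),
                 retained_k = x$retained_k,
                 retention_threshold = x$retention,
                 cumulative_retained = sum(x$explained_var[seq_len(x$retained_k)]))
}

#' Tidy per-PC skill ANOVA results
#'
#' @param x a `ski_anova`.
#' @param ... unused.
#' @return the underlying tibble without the list-column of group means.
#' @export
tidy.ski_anova <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$group_means <- NULL
  out
}

#' @rdname tidy.ski_anova
#' @export
glance.ski_anova <- function(x, ...) {
  tibble::tibble(n_pcs = nrow(x),
                 alpha = attr(x, "alpha"),
                 n_significant = sum(x$significant),
                 n_selected = sum(x$selected))
}

#' Tidy a classifier evaluation
#'
#' @param x a `ski_eval`.
#' @param ... unused.
#' @return per-class tibble with accuracy/AUC.
#' @export
tidy.ski_eval <- function(x, ...) x$per_class

#' @rdname tidy.ski_eval
#' @export
glance.ski_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc_macro = x$auc_macro,
                 n = sum(x$confusion))
}

#' Scree plot of a PCA model
#'
#' @param object a `ski_pca`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ski_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc, y = .data$explained_var,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_var), linewidth = 0.4) +
    ggplot2::labs(x = "Principal component", y = "Explained variance (%)",
                  fill = "Retained") +
    ggplot2::theme_minimal()
}

#' Violin plot of cycle-duration distributions by skill
#'
#' @param object a `ski_cadence` from [cadence_summary()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ski_cadence <- function(object, ...) {
  df <- tidyr::unnest(object$groups, "durations")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$skill, y = .data$durations)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA) +
    ggplot2::labs(x = "Skill level", y = "Cycle duration (s)",
                  subtitle = sprintf("one-way ANOVA p = %.3g",
                                     object$anova$p_value)) +
    ggplot2::theme_minimal()
}

#' Technique-mix bar chart by skill level
#'
#' @param object tibble from [technique_by_skill()].
#' @return a ggplot.
#' @export
plot_technique_mix <- function(object) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$skill, y = .data$prop,
                                       fill = .data$technique)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Skill level", y = "Proportion of cycles",
                  fill = "Technique") +
    ggplot2::theme_minimal()
}

#' Frontal-plane stick view of the reconstructed avatars
#'
#' @param object a `ski_mcr`.
#' @param frame sample index (1-101) to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ski_mcr <- function(object, frame = 51L, ...) {
  df <- purrr::map_dfr(c("beginner", "elite"), function(av) {
    fr <- object$unscaled[[av]]$coords[frame, , ]
    tibble::tibble(avatar = av, label = rownames(fr),
                   y_mm = fr[, 2], z_mm = fr[, 3])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y_mm, y = .data$z_mm,
                                   colour = .data$avatar)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Mediolateral (mm)", y = "Vertical (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' 3D-ish track view (plan view coloured by elevation)
#'
#' @param object a `ski_track`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ski_track <- function(object, ...) {
  ggplot2::ggplot(object$mean_lap,
                  ggplot2::aes(x = .data$x_m, y = .data$y_m,
                               colour = .data$elev_m)) +
    ggplot2::geom_path(linewidth = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "Elevation (m)") +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves for a classifier evaluation
#'
#' @param model a `ski_svm`.
#' @param scores held-out scores.
#' @param labels held-out labels.
#' @return a ggplot of per-class ROC curves.
#' @export
plot_roc_curves <- function(model, scores, labels) {
  pred <- classify_all(model, scores, probabilities = TRUE)
  prob <- attr(pred, "prob")
  y <- factor(as.character(labels), levels = model$classes)
  classes <- intersect(colnames(prob), unique(as.character(y)))
  df <- purrr::map_dfr(classes, function(cl) {
    rc <- roc_curve(prob[, cl], y == cl)
    dplyr::mutate(rc, class = cl)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
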