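#' Train the quadratic-kernel SVM sub-technique classifier
#'
#' Fits a degree-2 polynomial-kernel support vector machine on the manually
#' labelled subset of cycles, using the retained PC scores as inputs. Score
#' columns are standardized (centre/scale stored with the model) before the
#' kernel; the regularization constant defaults to 1. The label taxonomy is
#' the six sub-techniques plus `unknown`; skating absorbs its G2/G3/G4
#' variants. The model predicts only classes seen in training.
#'
#' @param scores numeric matrix or data frame (n x K) of PC scores for the
#'   labelled subset (columns `PC1..PCK`).
#' @param labels character/factor of length n; each class needs >= 3 examples.
#' @param cost regularization constant (default 1).
#' @return object of class `ski_svm`.
#' @export
train_technique_svm <- function(scores, labels, cost = 1) {
  X <- as.matrix(scores)
  storage.mode(X) <- "double"
  y <- factor(as.character(labels))
  if (nrow(X) != length(y)) abort("`scores` and `labels` lengths differ")
  if (nlevels(y) < 2L) abort("training needs at least 2 classes")
  counts <- table(y)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    abort(sprintf("class(es) with fewer than 3 labelled examples: %s",
                  paste(small, collapse = ", ")))
  }
  centre <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- scale(X, centre, scale_)
  fit <- e1071::svm(Xs, y, kernel = "polynomial", degree = 2, coef0 = 1,
                    gamma = 1 / ncol(Xs), cost = cost, probability = TRUE,
                    scale = FALSE)
  structure(list(fit = fit, centre = centre, scale = scale_,
                 classes = levels(y), k = ncol(X), cost = cost),
            class = "ski_svm")
}

#' @export
print.ski_svm <- function(x, ...) {
  cat(sprintf("<ski_svm> quadratic kernel on %d PC scores | classes: %s\n",
              x$k, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Classify cycles with a trained technique model
#'
#' @param model a `ski_svm`.
#' @param scores PC-score matrix/data frame with the same K columns used in
#'   training.
#' @param probabilities return the per-class probability matrix as attribute
#'   `"prob"`.
#' @return factor of predicted labels, one per row; deterministic.
#' @export
classify_all <- function(model, scores, probabilities = FALSE) {
  X <- as.matrix(scores)
  if (ncol(X) != model$k) abort(sprintf("expected %d score columns", model$k))
  Xs <- scale(X, model$centre, model$scale)
  pr <- predict(model$fit, Xs, probability = TRUE)
  out <- factor(as.character(pr), levels = model$classes)
  if (probabilities) {
    attr(out, "prob") <- attr(pr, "probabilities")[, model$classes, drop = FALSE]
  }
  out
}

#' Evaluate a technique classifier on held-out cycles
#'
#' Reports accuracy, a confusion table, and the macro-averaged one-vs-rest
#' ROC AUC obtained by trapezoidal integration of each class's ROC curve
#' (using the SVM's class-probability scores). The `unknown` catch-all class
#' is excluded from the macro AUC by default; classes absent from the held-out
#' set are excluded with a warning.
#'
#' @param model a `ski_svm`.
#' @param scores held-out PC scores (rows disjoint from training).
#' @param labels held-out true labels.
#' @param include_unknown include `unknown` in the macro AUC.
#' @return object of class `ski_eval`: `accuracy`, `auc_macro`, `per_class`
#'   tibble (class, n, auc), `confusion` table.
#' @export
evaluate_classifier <- function(model, scores, labels, include_unknown = FALSE) {
  y <- factor(as.character(labels), levels = model$classes)
  pred <- classify_all(model, scores, probabilities = TRUE)
  prob <- attr(pred, "prob")
  acc <- mean(as.character(pred) == as.character(y))
  conf <- table(truth = y, predicted = factor(as.character(pred),
                                              levels = model$classes))
  auc_classes <- model$classes
  if (!include_unknown) auc_classes <- setdiff(auc_classes, "unknown")
  absent <- auc_classes[!auc_classes %in% as.character(y)]
  if (length(absent)) {
    warn(sprintf("class(es) absent from held-out set excluded from macro AUC: %s",
                 paste(absent, collapse = ", ")))
    auc_classes <- setdiff(auc_classes, absent)
  }
  per_class <- purrr::map_dfr(auc_classes, function(cl) {
    tibble::tibble(class = cl,
                   n = sum(y == cl),
                   auc = roc_auc(prob[, cl], y == cl))
  })
  structure(list(accuracy = acc,
                 auc_macro = mean(per_class$auc),
                 per_class = per_class,
                 confusion = conf),
            class = "ski_eval")
}

#' @export
print.ski_eval <- function(x, ...) {
  cat(sprintf("<ski_eval> accuracy %.3f | macro one-vs-rest AUC %.3f (%d classes)\n",
              x$accuracy, x$auc_macro, nrow(x$per_class)))
  invisible(x)
}

#' ROC curve and AUC by trapezoidal integration
#'
#' One-vs-rest ROC from a numeric score (higher = more positive). Tied scores
#' are handled by collapsing to unique thresholds, so the trapezoidal area
#' equals the rank-statistic (Mann-Whitney) AUC.
#'
#' @param score numeric vector.
#' @param positive logical vector of the same length.
#' @return `roc_curve()`: tibble `threshold, fpr, tpr`; `roc_auc()`: scalar.
#' @export
roc_curve <- function(score, positive) {
  positive <- as.logical(positive)
  o <- order(score, decreasing = TRUE)
  s <- score[o]; p <- positive[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(s, fromLast = TRUE) # one point per unique threshold
  np <- sum(positive); nn <- sum(!positive)
  tibble::tibble(threshold = c(Inf, s[last]),
                 fpr = c(0, fp[last] / max(nn, 1)),
                 tpr = c(0, tp[last] / max(np, 1)))
}

#' @rdname roc_curve
#' @export
roc_auc <- function(score, positive) {
  rc <- roc_curve(score, positive)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' Stratified cross-validation of the technique classifier
#'
#' The paper-style headline numbers come from a labelled subset; this defines
#' the validation protocol explicitly: stratified k-fold cross-validation on
#' the labelled cycles, reporting mean held-out accuracy and macro AUC, with
#' resubstitution accuracy reported separately. Folds are seeded; held-out
#' rows never overlap their fold's training rows.
#'
#' @param scores PC scores of the labelled subset.
#' @param labels labels of the subset.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the stratified fold assignment.
#' @param cost SVM regularization constant.
#' @return tibble with one row: `folds, accuracy, auc_macro,
#'   resubstitution_accuracy`, plus per-fold results in attribute `"folds"`.
#' @export
cross_validate_technique <- function(scores, labels, folds = 5, seed = 1L,
                                     cost = 1) {
  X <- as.matrix(scores)
  y <- factor(as.character(labels))
  fold_id <- withr::with_seed(seed, stratified_folds(y, folds))
  res <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- fold_id != f
    model <- train_technique_svm(X[tr, , drop = FALSE], y[tr], cost = cost)
    ev <- suppressWarnings(
      evaluate_classifier(model, X[!tr, , drop = FALSE], y[!tr]))
    tibble::tibble(fold = f, accuracy = ev$accuracy, auc_macro = ev$auc_macro)
  })
  full <- train_technique_svm(X, y, cost = cost)
  resub <- mean(as.character(classify_all(full, X)) == as.character(y))
  out <- tibble::tibble(folds = folds,
                        accuracy = mean(res$accuracy),
                        auc_macro = mean(res$auc_macro),
                        resubstitution_accuracy = resub)
  attr(out, "folds") <- res
  out
}

# fold ids 1..k, stratified by class; requires >= k members per class to
# guarantee every fold sees every class in training
stratified_folds <- function(y, k) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(k), length(idx))
  }
  id
}

#' Stratified labelling of a cycle subset
#'
#' Emulates the manual-labelling step: selects a fraction of cycles for
#' labelling, stratified by true class with a floor per class, so every
#' sub-technique is represented without labelling everything.
#'
#' @param truth_labels character vector of true labels for all cycles.
#' @param fraction fraction of cycles to label (default 0.04).
#' @param min_per_class minimum labelled examples per class present.
#' @param seed integer seed.
#' @return integer indices of the labelled subset.
#' @export
stratified_label_subset <- function(truth_labels, fraction = 0.04,
                                    min_per_class = 3L, seed = 1L) {
  y <- factor(truth_labels)
  n_target <- max(1L, round(fraction * length(y)))
  withr::with_seed(seed, {
    per_class <- pmax(min_per_class,
                      round(n_target * as.vector(table(y)) / length(y)))
    names(per_class) <- levels(y)
    idx <- unlist(purrr::map(levels(y), function(cl) {
      pool <- which(y == cl)
      sample(pool, min(per_class[[cl]], length(pool)))
    }))
    sort(idx)
  })
}

#' Technique usage proportions by skill level
#'
#' @param labels technique label per cycle (factor/character).
#' @param skill skill level per cycle.
#' @return tibble `skill, technique, n, prop`; proportions sum to 1 within
#'   each skill.
#' @export
technique_by_skill <- function(labels, skill) {
  df <- tibble::tibble(technique = as.character(labels),
                       skill = factor(skill, levels = skill_levels()))
  df |>
    dplyr::count(.data$skill, .data$technique, .drop = TRUE) |>
    dplyr::group_by(.data$skill) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
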