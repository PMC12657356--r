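#' One-way ANOVA of each PC score against skill level
#'
#' Fits a fixed-effects general-linear-model one-way ANOVA per principal
#' component with skill level (beginner to elite) as the factor. A component
#' is *selected* for reconstruction when it is significant (raw p < alpha,
#' matching the convention of reporting unadjusted per-PC p-values) and its
#' four group means are *stepwise*, i.e. strictly monotone across the skill
#' ordering. A Holm-adjusted column is reported for reference but does not
#' drive selection. Cycles are treated as independent observations; with
#' few athletes per group this pseudo-replicates participants, which is
#' reported, not corrected.
#'
#' @param scores matrix/data frame (n x K) of PC scores, columns `PC1..PCK`,
#'   or a `ski_pca` (its retained scores are used).
#' @param skill skill level per cycle (beginner/intermediate/advanced/elite);
#'   ignored when `scores` is a `ski_pca` carrying metadata.
#' @param alpha significance level (default 0.05).
#' @return tibble of class `ski_anova`, one row per PC: `pc, f_statistic,
#'   p_value, p_holm, group_means` (list-column ordered beginner to elite),
#'   `stepwise, direction, significant, selected`.
#' @export
anova_per_pc <- function(scores, skill = NULL, alpha = 0.05) {
  if (inherits(scores, "ski_pca")) {
    skill <- scores$meta$skill
    k <- max(1L, scores$retained_k)
    scores <- scores$scores[, seq_len(k), drop = FALSE]
  }
  X <- as.matrix(scores)
  g <- factor(skill, levels = skill_levels())
  if (anyNA(g)) abort("unrecognized skill level")
  counts <- table(droplevels(g))
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warn(sprintf("dropping skill group(s) with < 2 cycles: %s",
                 paste(small, collapse = ", ")))
    keep <- !g %in% small
    X <- X[keep, , drop = FALSE]
    g <- droplevels(g[keep])
  } else {
    g <- droplevels(g)
  }
  if (nlevels(g) < 2L) abort("need at least 2 skill groups with >= 2 cycles")
  res <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    ft <- oneway_f(y, g)
    means <- tapply(y, g, mean)[levels(g)]
    st <- if (nlevels(g) >= 3L) stepwise_flag(means) else
      list(stepwise = NA, direction = 0)
    tibble::tibble(pc = j, f_statistic = ft$f, p_value = ft$p,
                   group_means = list(means),
                   stepwise = isTRUE(st$stepwise),
                   direction = st$direction)
  })
  res$p_holm <- p.adjust(res$p_value, "holm")
  res$significant <- res$p_value < alpha
  res$selected <- res$significant & res$stepwise
  res <- res[, c("pc", "f_statistic", "p_value", "p_holm", "group_means",
                 "stepwise", "direction", "significant", "selected")]
  class(res) <- c("ski_anova", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "groups") <- levels(g)
  res
}

#' Stepwise (strict monotone) trend flag for ordered group means
#'
#' @param group_means numeric vector of >= 3 group means in skill order.
#' @return list with `stepwise` (TRUE iff strictly monotone; ties are not
#'   monotone) and `direction` (+1 increasing, -1 decreasing, 0 otherwise).
#' @export
stepwise_flag <- function(group_means) {
  m <- as.numeric(group_means)
  if (length(m) < 3L) abort("stepwise trend needs at least 3 group means")
  d <- diff(m)
  if (any(d == 0)) return(list(stepwise = FALSE, direction = 0))
  if (all(d > 0)) return(list(stepwise = TRUE, direction = 1))
  if (all(d < 0)) return(list(stepwise = TRUE, direction = -1))
  list(stepwise = FALSE, direction = 0)
}

#' Per-group score samples and kernel densities for violin plots
#'
#' @param score numeric vector of one PC's scores.
#' @param skill skill level per cycle.
#' @param bw_floor minimum kernel bandwidth, as a fraction of the overall
#'   score range (guards single-point / zero-variance groups).
#' @return tibble: `skill, n, median, values` (list-column) and `density`
#'   (list-column of tibbles `x, y`); each density integrates to 1.
#' @export
violin_data <- function(score, skill, bw_floor = 0.01) {
  g <- factor(skill, levels = skill_levels())
  rng <- diff(range(score))
  floor_bw <- max(bw_floor * max(rng, 1e-8), 1e-8)
  purrr::map_dfr(levels(droplevels(g)), function(lv) {
    v <- score[g == lv]
    bw <- if (length(v) >= 2 && sd(v) > 0) max(bw.nrd0(v), floor_bw) else floor_bw
    d <- density(v, bw = bw)
    tibble::tibble(skill = lv, n = length(v), median = median(v),
                   values = list(v),
                   density = list(tibble::tibble(x = d$x, y = d$y)))
  })
}

#' Select significant, stepwise PCs for multi-component reconstruction
#'
#' @param results a `ski_anova` from [anova_per_pc()].
#' @return list with `pcs` (indices) and `directions` (+1/-1 per PC); empty
#'   selection is allowed with a warning.
#' @export
select_pcs_for_mcr <- function(results) {
  sel <- results[results$selected %in% TRUE, ]
  if (!nrow(sel)) {
    warn("no PC is both significant and stepwise; selection is empty")
    return(list(pcs = integer(), directions = numeric()))
  }
  list(pcs = sel$pc, directions = sel$direction)
}
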