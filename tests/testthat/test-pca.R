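test_that("amplitude normalization equalizes block ranges and inverts exactly", {
  db <- build_cycle_database(toy_cycles())
  r0 <- sapply(c("time", "coord", "power"),
               function(b) diff(range(db$X[, db$col_info$block == b])))
  expect_gt(max(r0) / min(r0), 5) # genuinely heterogeneous before scaling

  dbn <- amplitude_normalize(db)
  r1 <- sapply(c("time", "coord", "power"),
               function(b) diff(range(dbn$X[, dbn$col_info$block == b])))
  expect_lt(diff(range(r1)) / mean(r1), 0.01)
  expect_equal(unname(dbn$block_scalars["coord"]), 1)

  back <- invert_amplitude(dbn)
  expect_equal(back$X, db$X, tolerance = 1e-12)
})

test_that("already-equal block ranges leave scalars at one", {
  db <- build_cycle_database(toy_cycles())
  for (b in c("time", "coord", "power")) {
    cols <- which(db$col_info$block == b)
    db$X[, cols[1]] <- 0
    db$X[, cols[2]] <- 1
    db$X[, cols[-(1:2)]] <- 0.5
  }
  dbn <- amplitude_normalize(db)
  expect_equal(unname(dbn$block_scalars), c(1, 1, 1))
})

test_that("database layout matches the documented column budget", {
  db <- build_cycle_database(toy_cycles(n_cycles = 3, ns = 101))
  expect_equal(ncol(db$X), 23432L)
  expect_equal(nrow(db$X), 3L)
  expect_equal(sum(db$col_info$block == "time"), 101L)
  expect_equal(sum(db$col_info$block == "coord"), 101L * 228L)
  expect_equal(sum(db$col_info$block == "power"), 303L)
})

test_that("PCA recovers a known two-feature eigenstructure", {
  X <- withr::with_seed(8, cbind(rnorm(10000, sd = 3), rnorm(10000, sd = 1)))
  m <- fit_pca(X)
  expect_equal(m$explained_var[1], 90, tolerance = 1)
  expect_equal(m$explained_var[2], 10, tolerance = 1)
})

test_that("PCA satisfies its structural invariants on random data", {
  X <- withr::with_seed(9, matrix(rnorm(60 * 20), 60, 20))
  m <- fit_pca(X)
  expect_equal(crossprod(m$loadings), diag(20), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(m$explained_var) <= 1e-8))
  expect_true(all(m$explained_var >= 0))
  expect_equal(sum(m$explained_var), 100, tolerance = 1e-8)
  expect_lt(max(abs(colMeans(m$scores))), 1e-8)
  # full-rank reconstruction identity
  Xhat <- sweep(m$scores %*% t(m$loadings), 2, m$mean, "+")
  expect_equal(Xhat, X, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("SVD route matches a brute-force covariance eigendecomposition", {
  X <- withr::with_seed(10, matrix(rnorm(200 * 50), 200, 50))
  m <- fit_pca(X)
  ev <- eigen(stats::cov(scale(X, center = TRUE, scale = FALSE)), symmetric = TRUE)
  var_svd <- m$singular_values^2 / (nrow(X) - 1)
  expect_equal(var_svd, ev$values, tolerance = 1e-6)
  sc_oracle <- scale(X, center = TRUE, scale = FALSE) %*% ev$vectors
  for (j in 1:50) {
    agree <- min(max(abs(m$scores[, j] - sc_oracle[, j])),
                 max(abs(m$scores[, j] + sc_oracle[, j])))
    expect_lt(agree, 1e-6)
  }
})

test_that("an all-identical database has zero variance and retains nothing", {
  X <- matrix(5, 10, 8)
  m <- fit_pca(X)
  expect_true(all(m$explained_var == 0))
  expect_equal(m$retained_k, 0L)
  expect_error(fit_pca(X[1, , drop = FALSE]), "at least 2")
})

test_that("loading signs follow the largest-element-positive convention", {
  X <- withr::with_seed(12, matrix(rnorm(300), 30, 10))
  m1 <- fit_pca(X)
  m2 <- fit_pca(X)
  expect_identical(m1$loadings, m2$loadings)
  for (j in 1:10) {
    expect_gt(m1$loadings[which.max(abs(m1$loadings[, j])), j], 0)
  }
})

test_that("retention rule picks the smallest sufficient component count", {
  expect_equal(retain_components(c(50, 30, 20), 90), 3)
  expect_equal(retain_components(c(95, 5), 90), 1)
  expect_warning(k <- retain_components(c(40, 30), 90), "never reaches")
  expect_equal(k, 2)
  expect_error(retain_components(c(-1, 50)), "nonnegative")
})

test_that("MCR reproduces the mean with zero scores and scales linearly", {
  res <- small_cohort_pipeline()
  m <- res$model

  # empty selection -> both avatars are exactly the mean
  expect_warning(rec0 <- mcr_reconstruct(m, integer(), numeric()), "empty")
  expect_equal(rec0$elite, m$mean)
  expect_equal(rec0$beginner, m$mean)

  # single PC: offset parallel to the loading, magnitude = the tail score
  rec1 <- mcr_reconstruct(m, 1L, 1)
  d <- rec1$elite - m$mean
  z95 <- quantile(m$scores[, 1], 0.95, names = FALSE)
  expect_equal(d, m$loadings[, 1] * z95, tolerance = 1e-9)
  # beginner avatar uses the opposite tail
  z05 <- quantile(m$scores[, 1], 0.05, names = FALSE)
  expect_equal(rec1$beginner - m$mean, m$loadings[, 1] * z05, tolerance = 1e-9)

  # reflection: negating the direction swaps the avatars' tails
  rec_neg <- mcr_reconstruct(m, 1L, -1)
  expect_equal(rec_neg$elite, rec1$beginner, tolerance = 1e-12)
  expect_equal(rec_neg$beginner, rec1$elite, tolerance = 1e-12)

  expect_error(mcr_reconstruct(m, m$retained_k + 1L, 1), "retained")
})

test_that("unscaling inverts block scaling exactly and exports round-trip", {
  res <- small_cohort_pipeline()
  m <- res$model
  rec <- mcr_reconstruct(m, 1:2, c(1, -1))
  # re-apply block scalars to the unscaled time block: identity check
  t_scaled <- rec$unscaled$elite$time_s * m$block_scalars[["time"]]
  expect_equal(t_scaled, rec$elite[m$col_info$block == "time"][1:101],
               tolerance = 1e-12)

  path <- file.path(withr::local_tempdir(), "avatars.csv")
  export_animation(rec, path)
  anim <- read_animation(path)
  expect_equal(nrow(anim), 2 * 101 * 76)
  el <- anim[anim$avatar == "elite" & anim$label == "toe_l", ]
  expect_equal(el$x_mm, rec$unscaled$elite$coords[, "toe_l", 1],
               tolerance = 1e-9)
})

test_that("pc_scores and tidiers expose the model consistently", {
  res <- small_cohort_pipeline()
  m <- res$model
  sc <- pc_scores(m)
  expect_equal(nrow(sc), nrow(m$scores))
  expect_true(all(paste0("PC", seq_len(m$retained_k)) %in% names(sc)))
  td <- tidy(m)
  expect_equal(td$cumulative_var[nrow(td)], 100, tolerance = 1e-8)
  expect_equal(sum(td$retained), m$retained_k)
  gl <- glance(m)
  expect_equal(gl$retained_k, m$retained_k)
  expect_gte(gl$cumulative_retained, 90 - 1e-9)
})
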