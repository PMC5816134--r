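feature_tbl <- function(m, ids = sprintf("s%02d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% paste0("f", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(stimulus = ids), tibble::as_tibble(m))
}

test_that("feature standardization gives zero mean and unit population sd", {
  tab <- feature_tbl(cbind(a = c(0, 2, 0, 2), b = c(1, 2, 3, 4)))
  z <- standardize_features(tab)
  expect_equal(z$a, c(-1, 1, -1, 1))
  expect_equal(mean(z$b), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$b^2)), 1, tolerance = 1e-12)
  # already standardized input is unchanged
  z2 <- standardize_features(z)
  expect_equal(as.matrix(z2[, -1]), as.matrix(z[, -1]), tolerance = 1e-12)
  expect_error(standardize_features(feature_tbl(cbind(a = rep(3, 4)))),
               "constant feature")
})

test_that("weighted distances follow the weighted Euclidean formula", {
  set.seed(2)
  m <- matrix(rnorm(40), 10, 4)
  tab <- standardize_features(feature_tbl(m))
  x <- as.matrix(tab[, -1])
  d_unit <- weighted_distance_matrix(tab, rep(1, 4))
  expect_equal(unname(d_unit), unname(as.matrix(dist(x))), tolerance = 1e-12)

  w <- c(0, 2, 0, 0)
  d_one <- weighted_distance_matrix(tab, w)
  expect_equal(unname(d_one), unname(2 * abs(outer(x[, 2], x[, 2], "-"))),
               tolerance = 1e-12)
  expect_error(weighted_distance_matrix(tab, c(-1, 1, 1, 1)), "nonnegative")
  expect_error(weighted_distance_matrix(tab, rep(0, 4)), "zero")
})

test_that("matrix correlation equals the direct upper-triangle formula", {
  set.seed(3)
  d1 <- as.matrix(dist(matrix(rnorm(8), 4)))
  d2 <- as.matrix(dist(matrix(rnorm(8), 4)))
  expect_equal(matrix_correlation(d1, d1), 1)
  expect_equal(matrix_correlation(d1, 2 * d1), 1)
  v1 <- d1[upper.tri(d1)]; v2 <- d2[upper.tri(d2)]
  direct <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(matrix_correlation(d1, d2), direct, tolerance = 1e-12)
  expect_error(matrix_correlation(d1, matrix(0, 4, 4)), "constant")
})

test_that("matrix correlation agrees with vegan's Mantel statistic", {
  set.seed(4)
  d1 <- as.matrix(dist(matrix(rnorm(30), 15)))
  d2 <- as.matrix(dist(matrix(rnorm(30), 15)))
  r_pkg <- matrix_correlation(d1, d2)
  mt <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 0)
  expect_equal(r_pkg, unname(mt$statistic), tolerance = 1e-10)
  res <- matrix_correlation(d1, d2, permutations = 199, seed = 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("weight optimization recovers a noiseless reference exactly", {
  set.seed(5)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4)
  tab <- standardize_features(feature_tbl(X))
  Xs <- as.matrix(tab[, -1])
  w_true <- c(2, 1.5, 1, 0.5)
  ref <- as.matrix(dist(sweep(Xs, 2, w_true, "*")))
  dimnames(ref) <- list(tab$stimulus, tab$stimulus)
  mw <- optimize_weights(tab, ref, seed = 1)
  expect_gte(mw$achieved_correlation, 0.999)
  w_hat <- mw$weights$weight
  expect_equal(w_hat / w_hat[1], w_true / w_true[1], tolerance = 0.05)
})

test_that("weight optimization never falls below the uniform baseline", {
  set.seed(6)
  for (i in 1:3) {
    tab <- standardize_features(feature_tbl(matrix(rnorm(40 * 5), 40)))
    ref <- as.matrix(dist(matrix(rnorm(40 * 2), 40)))
    dimnames(ref) <- list(tab$stimulus, tab$stimulus)
    mw <- suppressWarnings(optimize_weights(tab, ref, n_starts = 2, seed = i))
    unif <- matrix_correlation(weighted_distance_matrix(tab, rep(1, 5)), ref)
    expect_gte(mw$achieved_correlation, unif - 1e-12)
  }
})

test_that("random references yield near-zero achievable correlation", {
  set.seed(7)
  tab <- standardize_features(feature_tbl(matrix(rnorm(60 * 3), 60)))
  ref <- as.matrix(dist(matrix(rnorm(60), 60)))   # independent 1-D distances
  dimnames(ref) <- list(tab$stimulus, tab$stimulus)
  mw <- suppressWarnings(optimize_weights(tab, ref, n_starts = 2, seed = 2))
  expect_lt(mw$achieved_correlation, 0.25)
})

test_that("acoustic PCA satisfies its algebraic contracts", {
  set.seed(8)
  # rank-1 data: one component carries everything
  u <- rnorm(30); v <- rnorm(5)
  tab1 <- feature_tbl(outer(u, v))
  p1 <- suppressWarnings(acoustic_pca(tab1, k = 2))
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-10)

  m <- matrix(rnorm(200 * 6), 200, 6)
  tab <- feature_tbl(m)
  pc <- acoustic_pca(tab, k = 6)
  # orthonormal loadings
  expect_equal(unname(crossprod(pc$loadings)), diag(6), tolerance = 1e-10)
  # full-rank reconstruction
  recon <- pc$pc_scores %*% t(pc$loadings)
  centred <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(unname(recon), matrix(centred, nrow(m)), tolerance = 1e-8)
  expect_equal(sum(pc$all_variance), 1, tolerance = 1e-12)
  # shares agree with prcomp
  pr <- prcomp(m)
  expect_equal(pc$all_variance, pr$sdev^2 / sum(pr$sdev^2), tolerance = 1e-10)
  # sign convention: largest-magnitude loading entry is positive
  for (j in 1:6) {
    col <- pc$loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("isotropic two-feature data splits variance evenly", {
  set.seed(9)
  tab <- feature_tbl(matrix(rnorm(4000 * 2), 4000, 2))
  pc <- acoustic_pca(tab, k = 2)
  expect_equal(pc$explained_variance, c(0.5, 0.5), tolerance = 0.05)
})

test_that("decision map separates classes and respects contracts", {
  set.seed(10)
  a <- cbind(rnorm(40, -4), rnorm(40, 0))
  b <- cbind(rnorm(40, 4), rnorm(40, 0))
  scores <- rbind(a, b)
  labels <- rep(c("x", "y"), each = 40)
  dm <- multinomial_decision_map(scores, labels, grid_resolution = 30)
  expect_equal(dm$training_accuracy, 1)

  # three classes at equilateral-triangle centres: each centre sits in its
  # own decision region
  centers <- rbind(c(0, 2), c(-sqrt(3), -1), c(sqrt(3), -1)) * 3
  pts <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(60, 0, 0.3), 30, 2), 2, centers[k, ], "+")
  }))
  lab3 <- rep(c("a", "b", "c"), each = 30)
  dm3 <- multinomial_decision_map(pts, lab3, grid_resolution = 20)
  pred_centers <- predict(dm3$model,
                          data.frame(PC1 = centers[, 1], PC2 = centers[, 2]))
  expect_equal(as.character(pred_centers), c("a", "b", "c"))

  # shuffled labels: accuracy near chance
  dm_sh <- multinomial_decision_map(pts, sample(lab3), grid_resolution = 10)
  expect_lt(dm_sh$training_accuracy, 1 / 3 + 0.15)
  expect_error(multinomial_decision_map(pts, rep("a", 90)), "2 classes")
})

test_that("call-type classifier learns separable labels and fails shuffled ones", {
  w <- fixture_world()
  ac <- simulate_acoustics(w, seed = 3)
  feats <- standardize_features(ac)
  # labels defined by a single feature threshold are nearly perfectly learnable
  thr_labels <- setNames(ifelse(feats$pitch_median > 0, "hi", "lo"),
                         feats$stimulus)
  res_thr <- calltype_classifier_accuracy(feats, thr_labels, seed = 1)
  expect_gte(res_thr$accuracy, 0.95)

  truth <- setNames(w$stimuli$true_type, w$stimuli$stimulus)
  res <- calltype_classifier_accuracy(feats, truth, pooling = "full", seed = 1)
  expect_gt(res$accuracy, res$majority_baseline + 0.2)

  set.seed(11)
  perm <- setNames(sample(unname(truth)), names(truth))
  res_perm <- calltype_classifier_accuracy(feats, perm, pooling = "full",
                                           seed = 1)
  expect_lt(abs(res_perm$accuracy - res_perm$majority_baseline), 0.12)
})

test_that("major7 pooling maps synonyms onto the six major call types", {
  w <- fixture_world()
  tr <- fixture_naming()
  lex <- fixture_lexicon()
  ac <- simulate_acoustics(w, seed = 3)
  feats <- standardize_features(ac)
  modal <- modal_clusters(tr, lex$sound_labels, "sound")
  labels <- setNames(modal$modal_label, modal$stimulus)
  res <- suppressWarnings(
    calltype_classifier_accuracy(feats, labels, pooling = "major7", seed = 2))
  expect_true(all(rownames(res$confusion) %in%
                    c("laugh", "cry", "scream", "moan", "sigh", "roar",
                      "other")))
  expect_gt(res$accuracy, res$majority_baseline + 0.2)
})
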