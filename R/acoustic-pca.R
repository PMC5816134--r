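#' PCA of the weighted acoustic feature matrix
#'
#' Principal components of the (standardized, weight-scaled) feature
#' matrix via singular value decomposition. Loading signs are fixed so
#' that each column's largest-magnitude entry is positive, making the
#' components reproducible across platforms.
#'
#' @param weighted_features tibble of standardized features already
#'   multiplied by their weights (or any feature tibble).
#' @param k number of components to keep.
#' @return object of class `acoustic_embedding`: `pc_scores`
#'   (stimulus x k), `loadings` (feature x k, orthonormal columns),
#'   `explained_variance`.
#' @export
acoustic_pca <- function(weighted_features, k = 2) {
  m <- feature_matrix(weighted_features)
  k <- check_count(k, "k")
  m_c <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(m_c)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > rank) {
    warn(sprintf("rank is %d; truncating k from %d", rank, k))
    k <- rank
  }
  load <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2, function(col) sign(col[which.max(abs(col))]))
  load <- sweep(load, 2, flip, "*")
  scores <- m_c %*% load
  dimnames(load) <- list(colnames(m), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(k)))
  ev <- sv$d^2 / sum(sv$d^2)
  structure(
    list(pc_scores = scores, loadings = load,
         explained_variance = ev[seq_len(k)], all_variance = ev),
    class = "acoustic_embedding"
  )
}

#' @export
print.acoustic_embedding <- function(x, ...) {
  cat(sprintf("<acoustic_embedding> %d stimuli x %d PCs (%s of variance)\n",
              nrow(x$pc_scores), ncol(x$pc_scores),
              sprintf("%.0f%%", 100 * sum(x$explained_variance))))
  invisible(x)
}

#' Multinomial decision map over the first two acoustic components
#'
#' Fits a multinomial logistic model of the call-type label on two PC
#' scores (penalized by a small ridge via `nnet::multinom` weight decay so
#' separable classes stay finite) and evaluates the predicted class over a
#' rectangular grid — the shaded decision regions drawn behind acoustic
#' scatterplots.
#'
#' @param pc_scores_2d stimulus x 2 matrix of PC scores.
#' @param labels class label per stimulus (>= 2 classes).
#' @param grid_resolution grid points per axis.
#' @param decay ridge penalty for the multinomial fit.
#' @return list of class `decision_map`: `model`, `grid` (tibble with
#'   `PC1`, `PC2`, `predicted`), `training_accuracy`, `classes`.
#' @export
multinomial_decision_map <- function(pc_scores_2d, labels,
                                     grid_resolution = 100, decay = 1e-4) {
  if (ncol(pc_scores_2d) != 2) abort("scores must have exactly 2 columns")
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("need at least 2 classes")
  df <- data.frame(PC1 = pc_scores_2d[, 1], PC2 = pc_scores_2d[, 2],
                   label = labels)
  fit <- nnet::multinom(label ~ PC1 + PC2, data = df, decay = decay,
                        maxit = 500, trace = FALSE)
  acc <- mean(predict(fit, df) == labels)
  rng1 <- range(df$PC1); rng2 <- range(df$PC2)
  pad1 <- 0.05 * diff(rng1); pad2 <- 0.05 * diff(rng2)
  grid <- tidyr::expand_grid(
    PC1 = seq(rng1[1] - pad1, rng1[2] + pad1, length.out = grid_resolution),
    PC2 = seq(rng2[1] - pad2, rng2[2] + pad2, length.out = grid_resolution)
  )
  grid$predicted <- predict(fit, grid)
  structure(
    list(model = fit, grid = grid, training_accuracy = acc,
         classes = levels(labels)),
    class = "decision_map"
  )
}

#' @export
print.decision_map <- function(x, ...) {
  cat(sprintf("<decision_map> %d classes, training accuracy %.1f%%\n",
              length(x$classes), 100 * x$training_accuracy))
  invisible(x)
}

# default synonym map from fine-grained labels to the six major call
# types + "other"; unseen labels fall into "other"
MAJOR7 <- c("laugh", "cry", "scream", "moan", "sigh", "roar")

default_major7_map <- function() {
  maps <- lapply(SOUND_LABELS, function(v) {
    setNames(sub("[0-9]+$", "", names(v)), unname(v))
  })
  out <- unlist(unname(maps))
  out[!duplicated(names(out))]
}

#' Call-type classification from acoustic features
#'
#' Random-forest classification of the per-stimulus call-type label (e.g.
#' the modal sound name) from the acoustic feature table, evaluated by
#' stratified cross-validation. With `pooling = "major7"` the labels are
#' first pooled through a synonym map into the six major call types
#' (laugh, cry, scream, moan, sigh, roar) plus a residual "other"
#' category.
#'
#' @param features feature tibble (`stimulus` + numeric columns).
#' @param labels named character vector (or vector in table order):
#'   label per stimulus.
#' @param pooling "full" (labels as given) or "major7".
#' @param synonym_map named character vector label -> major category used
#'   by "major7" pooling; defaults to the built-in lexicon map.
#' @param cv_folds,num_trees,seed forest settings.
#' @return a `classifier_result` (see [emotion_from_name_accuracy()]).
#' @export
calltype_classifier_accuracy <- function(features, labels,
                                         pooling = c("full", "major7"),
                                         synonym_map = default_major7_map(),
                                         cv_folds = 5, num_trees = 500,
                                         seed = 1) {
  pooling <- match.arg(pooling)
  m <- feature_matrix(features)
  y <- if (!is.null(names(labels))) as.character(labels[rownames(m)]) else as.character(labels)
  if (length(y) != nrow(m) || any(is.na(y))) {
    abort("`labels` must provide one label per stimulus")
  }
  if (pooling == "major7") {
    pooled <- unname(synonym_map[y])
    y <- ifelse(is.na(pooled) | !pooled %in% MAJOR7, "other", pooled)
  }
  if (length(unique(y)) < 2) abort("need at least 2 classes")
  run_forest_cv(m, y, cv_folds, num_trees, seed)
}
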