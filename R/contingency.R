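#' Sound-name by emotion-name contingency table
#'
#' Counts how often each (sound name, emotion name) combination was chosen
#' within the same trial: a trial that carries several labels of either
#' kind contributes one count per label pair. Pearson's chi-square on the
#' table (no continuity correction, df = (R-1)(C-1)) tests whether the
#' acoustic and emotional classifications are independent. Rows and
#' columns are also ordered by average-linkage hierarchical clustering of
#' their profiles, the ordering used to draw co-occurrence heatmaps.
#'
#' @param trials naming-trial tibble.
#' @param sound_labels,emotion_labels full label inventories.
#' @return list of class `contingency_result`: `table` (sound x emotion
#'   count matrix), `chi_square`, `df`, `p_value`, `row_order`,
#'   `col_order`.
#' @export
sound_emotion_contingency <- function(trials, sound_labels, emotion_labels) {
  s_labs <- split_labels(trials$sound_names)
  e_labs <- split_labels(trials$emotion_names)
  keep <- lengths(s_labs) > 0 & lengths(e_labs) > 0
  if (!any(keep)) abort("no trials with both a sound name and an emotion name")
  pairs <- purrr::map2_dfr(s_labs[keep], e_labs[keep], function(s, e) {
    tidyr::expand_grid(sound = s, emotion = e)
  })
  bad_s <- setdiff(pairs$sound, sound_labels)
  bad_e <- setdiff(pairs$emotion, emotion_labels)
  if (length(bad_s) || length(bad_e)) {
    abort(paste("labels outside the inventories:",
                paste(c(bad_s, bad_e), collapse = ", ")))
  }
  tab <- table(factor(pairs$sound, levels = sound_labels),
               factor(pairs$emotion, levels = emotion_labels))
  tab <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                dimnames = list(sound_labels, emotion_labels))

  # chi-square over rows/columns that actually occur
  use <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  suppressWarnings(ct <- chisq.test(use, correct = FALSE))

  order_by_profiles <- function(m) {
    if (nrow(m) < 3) return(rownames(m))
    prof <- m / pmax(rowSums(m), 1)
    hc <- hclust(dist(prof), method = "average")
    rownames(m)[hc$order]
  }
  structure(
    list(table = tab,
         chi_square = unname(ct$statistic),
         df = unname(ct$parameter),
         p_value = unname(ct$p.value),
         row_order = order_by_profiles(use),
         col_order = order_by_profiles(t(use))),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> %d x %d table, X-squared = %.1f, df = %d\n",
              nrow(x$table), ncol(x$table), x$chi_square, x$df))
  invisible(x)
}

# deterministic stratified cross-validation folds; classes smaller than
# the requested fold count shrink the fold count with a warning
stratified_folds <- function(labels, cv_folds, seed) {
  min_class <- min(table(labels))
  if (min_class < cv_folds) {
    cv_folds <- max(2L, as.integer(min_class))
    warn(sprintf("smallest class has %d members; reducing folds to %d",
                 min_class, cv_folds))
  }
  withr::local_seed(derive_seed(seed, 8L))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  list(fold = fold, k = cv_folds)
}

#' Predict the emotion name from the chosen sound names
#'
#' Trains a random-forest classifier on sound-name indicator features
#' (one 0/1 column per sound label, multi-label answers setting several
#' indicators) to predict the primary emotion name of each trial, and
#' evaluates it by stratified cross-validation. Quantifies how much of the
#' emotional interpretation is carried by the acoustic category alone.
#'
#' @param trials naming-trial tibble.
#' @param sound_labels sound-name inventory (feature columns).
#' @param cv_folds number of stratified folds (default 5).
#' @param num_trees forest size (default 500).
#' @param seed integer seed.
#' @return list of class `classifier_result`: `accuracy`, `folds`,
#'   `confusion` (true x predicted counts), `per_class_recall`,
#'   `majority_baseline`.
#' @export
emotion_from_name_accuracy <- function(trials, sound_labels, cv_folds = 5,
                                       num_trees = 500, seed = 1) {
  s_labs <- split_labels(trials$sound_names)
  e_labs <- split_labels(trials$emotion_names)
  keep <- lengths(s_labs) > 0 & lengths(e_labs) > 0
  y <- vapply(e_labs[keep], `[`, character(1), 1)   # primary emotion name
  if (length(unique(y)) < 2) abort("need at least 2 emotion classes")
  X <- t(vapply(s_labs[keep], function(s) as.numeric(sound_labels %in% s),
                numeric(length(sound_labels))))
  colnames(X) <- paste0("name_", seq_along(sound_labels))
  run_forest_cv(X, y, cv_folds, num_trees, seed)
}

# shared stratified-CV random-forest evaluation (ranger backend)
run_forest_cv <- function(X, y, cv_folds, num_trees, seed) {
  y <- factor(y)
  df <- data.frame(X, check.names = TRUE)
  fl <- stratified_folds(as.character(y), cv_folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (k in seq_len(fl$k)) {
    tr <- fl$fold != k
    fit <- ranger::ranger(
      x = df[tr, , drop = FALSE], y = y[tr], num.trees = num_trees,
      seed = derive_seed(seed, 9L + k), num.threads = 1,
      respect.unordered.factors = TRUE
    )
    pred[!tr] <- predict(fit, df[!tr, , drop = FALSE],
                         num.threads = 1)$predictions
  }
  confusion <- table(true = y, predicted = pred)
  recall <- diag(as.matrix(confusion)) / pmax(rowSums(confusion), 1)
  structure(
    list(accuracy = mean(pred == y),
         folds = fl$k,
         confusion = confusion,
         per_class_recall = recall,
         majority_baseline = max(table(y)) / length(y)),
    class = "classifier_result"
  )
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf(
    "<classifier_result> accuracy %.1f%% (majority baseline %.1f%%, %d folds)\n",
    100 * x$accuracy, 100 * x$majority_baseline, x$folds))
  invisible(x)
}

#' @export
glance.classifier_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 majority_baseline = x$majority_baseline,
                 folds = x$folds, n_classes = nrow(x$confusion))
}
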