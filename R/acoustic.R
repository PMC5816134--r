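# extract the numeric feature matrix (with stimulus rownames) from a
# feature tibble whose first column is `stimulus`
feature_matrix <- function(table) {
  stopifnot("stimulus" %in% names(table))
  m <- as.matrix(dplyr::select(table, -"stimulus"))
  if (!is.numeric(m)) abort("feature columns must be numeric")
  if (any(!is.finite(m))) abort("feature table contains missing or non-finite values")
  if (anyDuplicated(colnames(m))) abort("feature names must be unique")
  rownames(m) <- table$stimulus
  m
}

#' Standardize acoustic features
#'
#' Centres every feature at zero and scales it to unit standard deviation
#' (population sd, i.e. divisor n), so that learned feature weights are
#' comparable across features measured in different units.
#'
#' @param table feature tibble: `stimulus` column + numeric feature
#'   columns.
#' @return tibble of the same shape with standardized features.
#' @export
standardize_features <- function(table) {
  m <- feature_matrix(table)
  n <- nrow(m)
  mu <- colMeans(m)
  sds <- sqrt(colMeans(sweep(m, 2, mu)^2))
  if (any(sds == 0)) {
    abort(paste("constant feature(s):",
                paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  z <- sweep(sweep(m, 2, mu), 2, sds, "/")
  dplyr::bind_cols(tibble::tibble(stimulus = table$stimulus),
                   tibble::as_tibble(z))
}

#' Weighted Euclidean distance matrix over acoustic features
#'
#' \eqn{d(s,t) = \sqrt{\sum_f (w_f (x_{sf} - x_{tf}))^2}}: distances in
#' the feature space after multiplying each (standardized) feature by its
#' nonnegative weight. A weight of zero drops the feature.
#'
#' @param table standardized feature tibble.
#' @param weights nonnegative numeric vector, one per feature column
#'   (recycled scalar allowed); named vectors are matched to columns.
#' @return distance matrix over the stimuli.
#' @export
weighted_distance_matrix <- function(table, weights) {
  m <- feature_matrix(table)
  if (length(weights) == 1) weights <- rep(weights, ncol(m))
  if (!is.null(names(weights))) {
    if (!all(colnames(m) %in% names(weights))) {
      abort("`weights` names do not cover every feature")
    }
    weights <- weights[colnames(m)]
  }
  if (length(weights) != ncol(m)) abort("one weight per feature required")
  if (any(weights < 0)) abort("weights must be nonnegative")
  if (all(weights == 0)) abort("all weights are zero")
  coords_to_distances(sweep(m, 2, weights, "*"))
}

#' Correlation between two distance matrices
#'
#' Pearson correlation over the strict upper triangles (Mantel-style),
#' with an optional permutation test that permutes the rows and columns
#' of the second matrix jointly.
#'
#' @param d1,d2 distance matrices over the same stimuli in the same
#'   order.
#' @param permutations number of Mantel permutations (0 = no test).
#' @param seed integer seed for the permutation test.
#' @return the correlation; with `permutations > 0` a list
#'   `(r, p_value, permutations)`.
#' @export
matrix_correlation <- function(d1, d2, permutations = 0, seed = 1) {
  validate_distance_matrix(d1, "d1")
  validate_distance_matrix(d2, "d2")
  if (nrow(d1) != nrow(d2)) abort("matrices differ in size")
  v1 <- upper_tri_values(d1)
  v2 <- upper_tri_values(d2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("correlation undefined: a matrix has constant off-diagonal entries")
  }
  r <- cor(v1, v2)
  if (permutations <= 0) return(r)
  withr::local_seed(derive_seed(seed, 10L))
  n <- nrow(d1)
  perm_r <- vapply(seq_len(permutations), function(i) {
    p <- sample.int(n)
    cor(v1, upper_tri_values(d2[p, p]))
  }, double(1))
  list(r = r, p_value = (1 + sum(perm_r >= r)) / (permutations + 1),
       permutations = permutations)
}

#' Learn feature weights aligning acoustic and perceptual distances
#'
#' Finds nonnegative per-feature weights maximising the Mantel-style
#' correlation between the weighted acoustic distance matrix and a
#' reference distance matrix (e.g. the averaged semantic space of sound
#' names). Optimisation is multi-start Nelder-Mead on log-weights,
#' followed by greedy zero-weight moves that drop any feature whose
#' removal does not hurt the correlation — so feature-subset selection and
#' weighting happen in one mechanism. Never returns a solution worse than
#' uniform weights.
#'
#' @param features standardized feature tibble.
#' @param reference_distances reference distance matrix (same stimuli,
#'   same order).
#' @param n_starts number of random restarts.
#' @param max_eval Nelder-Mead evaluation budget per start.
#' @param seed integer seed.
#' @return object of class `metric_weights`: tibble `weights` (feature,
#'   weight), `achieved_correlation`, `uniform_correlation`,
#'   `improved` flag.
#' @export
optimize_weights <- function(features, reference_distances, n_starts = 4,
                             max_eval = 400, seed = 1) {
  m <- feature_matrix(features)
  validate_distance_matrix(reference_distances)
  if (nrow(reference_distances) != nrow(m)) {
    abort("feature table and reference distances differ in stimuli")
  }
  ref <- upper_tri_values(reference_distances)
  p <- ncol(m)

  # pairwise squared differences per feature: n_pairs x p, so the
  # objective is a cheap matrix-vector product in w^2
  pair_idx <- which(upper.tri(diag(nrow(m))), arr.ind = TRUE)
  sqdiff <- (m[pair_idx[, 1], , drop = FALSE] -
               m[pair_idx[, 2], , drop = FALSE])^2

  r_of_w <- function(w) {
    d <- sqrt(drop(sqdiff %*% w^2))
    if (sd(d) == 0) return(-1)
    cor(d, ref)
  }
  uniform_r <- r_of_w(rep(1, p))

  withr::local_seed(derive_seed(seed, 11L))
  best_w <- rep(1, p)
  best_r <- uniform_r
  for (s in seq_len(n_starts)) {
    w0 <- if (s == 1) rep(1, p) else exp(rnorm(p, 0, 0.7))
    opt <- optim(log(w0), function(lw) -r_of_w(exp(lw)),
                 method = "Nelder-Mead",
                 control = list(maxit = max_eval, reltol = 1e-10))
    w <- exp(opt$par)
    r <- r_of_w(w)
    # greedy zero-drop moves: set single weights to exactly zero while
    # the correlation does not decrease
    repeat {
      improved <- FALSE
      for (j in which(w > 0)) {
        wj <- w; wj[j] <- 0
        if (any(wj > 0)) {
          rj <- r_of_w(wj)
          if (rj >= r + 1e-12) {
            w <- wj; r <- rj; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    if (r > best_r) { best_r <- r; best_w <- w }
  }

  improved <- best_r >= uniform_r
  if (!improved) {
    warn("optimizer failed to improve on uniform weights; returning uniform")
    best_w <- rep(1, p)
    best_r <- uniform_r
  }
  # scale is irrelevant to the correlation; normalise max weight to 1..2
  # range seen in practice by fixing the mean of nonzero weights to 1
  nz <- best_w > 0
  best_w[nz] <- best_w[nz] / mean(best_w[nz])
  structure(
    list(weights = tibble::tibble(feature = colnames(m), weight = best_w),
         achieved_correlation = best_r,
         uniform_correlation = uniform_r,
         improved = improved),
    class = "metric_weights"
  )
}

#' @export
print.metric_weights <- function(x, ...) {
  cat(sprintf("<metric_weights> r = %.3f (uniform %.3f), %d/%d features kept\n",
              x$achieved_correlation, x$uniform_correlation,
              sum(x$weights$weight > 0), nrow(x$weights)))
  invisible(x)
}

#' @export
tidy.metric_weights <- function(x, ...) x$weights

#' @export
glance.metric_weights <- function(x, ...) {
  tibble::tibble(achieved_correlation = x$achieved_correlation,
                 uniform_correlation = x$uniform_correlation,
                 n_features = nrow(x$weights),
                 n_kept = sum(x$weights$weight > 0))
}
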