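#' Co-occurrence distances between stimuli
#'
#' Pairwise Euclidean distances between the label-choice profile rows of
#' two stimuli: the more often participants chose the same name for two
#' sounds, the closer their profiles and the smaller the distance.
#'
#' @param profiles a [name_profile_matrix()] result (stimulus x label
#'   proportions).
#' @return symmetric stimulus x stimulus distance matrix with zero
#'   diagonal.
#' @export
cooccurrence_distances <- function(profiles) {
  stopifnot(is.matrix(profiles))
  d <- as.matrix(dist(profiles))
  validate_distance_matrix(as_distance_matrix(d, rownames(profiles)))
  as_distance_matrix(d, rownames(profiles))
}

#' Average distance matrices across languages
#'
#' Element-wise arithmetic mean of several distance matrices over the same
#' stimuli (used to pool the per-language semantic spaces into one
#' cross-linguistic reference).
#'
#' @param matrices list of distance matrices with identical stimulus
#'   ordering (checked via dimnames when present).
#' @return a single averaged distance matrix.
#' @export
average_distance_matrices <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0) {
    abort("`matrices` must be a nonempty list of distance matrices")
  }
  ref <- matrices[[1]]
  validate_distance_matrix(ref)
  ids <- rownames(ref)
  for (m in matrices[-1]) {
    validate_distance_matrix(m)
    if (nrow(m) != nrow(ref)) abort("matrices differ in size")
    if (!is.null(ids) && !is.null(rownames(m)) && !identical(rownames(m), ids)) {
      abort("matrices do not share the same stimulus ordering")
    }
  }
  out <- Reduce(`+`, matrices) / length(matrices)
  as_distance_matrix(out, ids)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson's classical MDS: double-centre \eqn{-\frac{1}{2}D^2},
#' eigendecompose, and keep the top-k nonnegative eigenpairs. On distances
#' computed from genuine k-dimensional Euclidean coordinates the embedding
#' reproduces every pairwise distance exactly. Explained variance is each
#' retained eigenvalue's share of the sum of all nonnegative eigenvalues.
#'
#' @param distances a distance matrix; with `method = "pca_on_profiles"`,
#'   a [name_profile_matrix()] instead (for Euclidean profile distances
#'   the two routes give the same configuration up to sign).
#' @param k number of dimensions to keep (at most n - 1). If `k` exceeds
#'   the number of strictly positive eigenvalues the result is truncated
#'   with a warning.
#' @param method `"classical_mds"` (default) or `"pca_on_profiles"`.
#' @return object of class `space_embedding`: list with `coords`
#'   (stimulus x k), `explained_variance`, `eigenvalues`, `method`.
#' @export
embed_space <- function(distances, k = 3,
                        method = c("classical_mds", "pca_on_profiles")) {
  method <- match.arg(method)
  if (method == "pca_on_profiles") {
    return(embed_profiles_pca(distances, k))
  }
  validate_distance_matrix(distances)
  n <- nrow(distances)
  k <- check_count(k, "k")
  if (k > n - 1) abort("`k` must be at most n - 1")

  b <- -0.5 * distances^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  eig <- e$values
  pos <- which(eig > 1e-10 * max(abs(eig), 1e-300))
  if (k > length(pos)) {
    warn(sprintf("only %d positive eigenvalues; truncating k from %d",
                 length(pos), k))
    k <- max(length(pos), 1L)
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig[seq_len(k)], 0)), k)
  rownames(coords) <- rownames(distances)
  colnames(coords) <- paste0("dim", seq_len(k))
  ev <- if (length(pos)) pmax(eig[seq_len(k)], 0) / sum(eig[pos]) else rep(0, k)
  structure(
    list(coords = coords, explained_variance = ev,
         eigenvalues = eig, method = "classical_mds"),
    class = "space_embedding"
  )
}

# PCA on centred label profiles; coincides with classical MDS of the
# Euclidean profile distances up to column signs
embed_profiles_pca <- function(profiles, k) {
  stopifnot(is.matrix(profiles))
  n <- nrow(profiles)
  k <- check_count(k, "k")
  if (k > n - 1) abort("`k` must be at most n - 1")
  ctr <- scale(profiles, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  eig <- sv$d^2
  pos <- which(eig > 1e-10 * max(eig, 1e-300))
  if (k > length(pos)) {
    warn(sprintf("only %d positive eigenvalues; truncating k from %d",
                 length(pos), k))
    k <- max(length(pos), 1L)
  }
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(coords) <- rownames(profiles)
  colnames(coords) <- paste0("dim", seq_len(k))
  structure(
    list(coords = coords,
         explained_variance = eig[seq_len(k)] / sum(eig[pos]),
         eigenvalues = eig, method = "pca_on_profiles"),
    class = "space_embedding"
  )
}

#' @export
print.space_embedding <- function(x, ...) {
  cat(sprintf("<space_embedding> %d stimuli in %d dims (%s)\n",
              nrow(x$coords), ncol(x$coords), x$method))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Prototypicality-weighted cluster centroids
#'
#' Weighted mean of the embedding coordinates of the stimuli in each
#' cluster, with weight = (mean subjective certainty of the stimulus) x
#' (proportion of its most common name). Centroids therefore sit near the
#' most confidently and consistently named members of each cluster.
#'
#' @param embedding a [embed_space()] object or a coordinate matrix.
#' @param assignment named character/factor vector: cluster per stimulus.
#' @param certainty named numeric: mean certainty per stimulus.
#' @param modal_proportion named numeric: modal-name proportion per
#'   stimulus.
#' @return tibble with `cluster`, `n`, and one column per dimension.
#' @export
weighted_centroids <- function(embedding, assignment, certainty,
                               modal_proportion) {
  coords <- if (inherits(embedding, "space_embedding")) embedding$coords else embedding
  ids <- rownames(coords)
  if (is.null(ids)) abort("embedding coordinates need stimulus row names")
  w <- certainty[ids] * modal_proportion[ids]
  if (any(is.na(w)) || any(w < 0)) {
    abort("weights must be nonnegative and defined for every stimulus")
  }
  cl <- as.character(assignment[ids])
  out <- lapply(split(seq_along(ids), cl), function(rows) {
    ws <- w[rows]
    if (sum(ws) <= 0) abort("a cluster has all-zero weights")
    colSums(coords[rows, , drop = FALSE] * ws) / sum(ws)
  })
  cent <- do.call(rbind, out)
  if (is.null(colnames(cent))) {
    colnames(cent) <- paste0("V", seq_len(ncol(cent)))
  }
  dplyr::bind_cols(
    tibble::tibble(cluster = rownames(cent),
                   n = as.integer(table(cl)[rownames(cent)])),
    tibble::as_tibble(cent)
  )
}
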