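#' Mean silhouette index of a partition
#'
#' For each point, a = mean distance to the other members of its own
#' cluster and b = the smallest mean distance to any other cluster;
#' s = (b - a) / max(a, b). Singleton clusters get s = 0, and so does the
#' degenerate case a = b = 0. Returns the mean over all points.
#'
#' @param distances distance matrix.
#' @param assignment cluster label per stimulus (named or in matrix order).
#' @return mean silhouette in \[-1, 1\].
#' @export
silhouette_index <- function(distances, assignment) {
  validate_distance_matrix(distances)
  n <- nrow(distances)
  cl <- align_assignment(assignment, rownames(distances), n)
  levels_ <- unique(cl)
  if (length(levels_) < 2) abort("silhouette needs at least 2 clusters")

  # mean distance from every point to every cluster
  member <- outer(cl, levels_, "==") * 1          # n x k indicator
  sums <- distances %*% member
  sizes <- colSums(member)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(cl[i], levels_)
    if (sizes[own] == 1) { s[i] <- 0; next }
    a <- sums[i, own] / (sizes[own] - 1)
    b <- min(sums[i, -own] / sizes[-own])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table of the two partitions: 1 for identical partitions (up to
#' relabelling), approximately 0 for independent ones.
#'
#' @param assignment_a,assignment_b cluster labels over the same items
#'   (named vectors are matched by name).
#' @return the ARI, a number less than or equal to 1.
#' @export
adjusted_rand <- function(assignment_a, assignment_b) {
  if (length(assignment_a) != length(assignment_b)) {
    abort("partitions must cover the same items")
  }
  if (!is.null(names(assignment_a)) && !is.null(names(assignment_b))) {
    if (!setequal(names(assignment_a), names(assignment_b))) {
      abort("partitions must cover the same items")
    }
    assignment_b <- assignment_b[names(assignment_a)]
  }
  tab <- table(as.character(assignment_a), as.character(assignment_b))
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)      # both partitions all-singletons or single-cluster
  (sum_ij - expected) / (max_index - expected)
}

align_assignment <- function(assignment, ids, n) {
  cl <- as.character(assignment)
  if (!is.null(names(assignment)) && !is.null(ids)) {
    if (!all(ids %in% names(assignment))) {
      abort("assignment is missing some stimuli")
    }
    cl <- as.character(assignment[ids])
  }
  if (length(cl) != n) abort("assignment length does not match the matrix")
  cl
}

#' Average-linkage cladogram
#'
#' Agglomerative hierarchical clustering with average linkage (UPGMA) over
#' any distance matrix — stimuli, cluster centroids, or contingency-table
#' profiles. Ties in merge height are broken deterministically by lowest
#' item index. The result can be exported as Newick text.
#'
#' @param items_distances distance matrix over at least 2 items.
#' @return object of class `cladogram`: list with the `hclust` fit
#'   (`merge`, `height`, `order`, `labels`) and item ids.
#' @export
hierarchical_cladogram <- function(items_distances) {
  validate_distance_matrix(items_distances, "items_distances")
  if (nrow(items_distances) < 2) abort("need at least 2 items")
  hc <- hclust(as.dist(items_distances), method = "average")
  structure(list(hclust = hc,
                 items = rownames(items_distances) %||% hc$labels),
            class = "cladogram")
}

#' @export
print.cladogram <- function(x, ...) {
  cat(sprintf("<cladogram> %d items, average linkage\n",
              length(x$hclust$labels %||% x$items)))
  invisible(x)
}

#' Export a cladogram as Newick text
#'
#' @param cladogram a [hierarchical_cladogram()] object.
#' @param path optional file path; when omitted the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(cladogram, path = NULL) {
  stopifnot(inherits(cladogram, "cladogram"))
  phy <- ape::as.phylo(cladogram$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
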