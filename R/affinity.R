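#' Affinity propagation clustering of a distance matrix
#'
#' Exemplar-based clustering by responsibility/availability message
#' passing (Frey & Dueck). Similarities are negative squared distances;
#' every self-similarity (the "preference") is set to the `q` sample
#' quantile of the off-diagonal similarities, so `q` tunes the algorithm's
#' propensity to split (high q, many exemplars) or lump (low q, few).
#'
#' @param distances distance matrix.
#' @param q preference quantile in \[0, 1\].
#' @param damping message damping in \[0.5, 1).
#' @param max_iter maximum number of iterations.
#' @param conv_iter iterations the exemplar set must stay unchanged to
#'   declare convergence.
#' @return object of class `cluster_solution`: list with `assignment`
#'   (named exemplar id per stimulus), `exemplars`, `n_clusters`, `q`,
#'   `damping`, `converged`, `iterations`, `net_similarity`.
#' @export
affinity_propagation <- function(distances, q = 0.5, damping = 0.9,
                                 max_iter = 1000, conv_iter = 50) {
  validate_distance_matrix(distances)
  if (q < 0 || q > 1) abort("`q` must be in [0, 1]")
  if (damping < 0.5 || damping >= 1) abort("`damping` must be in [0.5, 1)")
  n <- nrow(distances)
  ids <- rownames(distances) %||% as.character(seq_len(n))

  s <- -distances^2
  if (n == 1L) {
    return(new_cluster_solution(setNames(ids, ids), ids, q, damping,
                                TRUE, 0L, 0))
  }
  off <- s[row(s) != col(s)]
  pref <- as.numeric(quantile(off, q, names = FALSE, type = 7))
  # tiny deterministic similarity jitter, as in the reference
  # implementations, to break degenerate oscillations of the messages
  withr::local_seed(20230L)
  s <- s + (1e-12 * max(abs(s), 1e-300)) * matrix(rnorm(n * n), n, n)
  diag(s) <- pref

  r <- matrix(0, n, n)
  a <- matrix(0, n, n)
  exemplars_prev <- NULL
  stable <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    as_ <- a + s
    first_idx <- max.col(as_, ties.method = "first")
    first_max <- as_[cbind(seq_len(n), first_idx)]
    tmp <- as_
    tmp[cbind(seq_len(n), first_idx)] <- -Inf
    second_max <- apply(tmp, 1, max)
    rnew <- s - first_max
    rnew[cbind(seq_len(n), first_idx)] <- s[cbind(seq_len(n), first_idx)] -
      second_max
    r <- damping * r + (1 - damping) * rnew

    # availabilities: a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    # and a(k,k) = sum_{i' != k} max(0, r(i',k))
    posr <- pmax(r, 0)
    diag(posr) <- 0
    colsum <- colSums(posr)
    anew <- pmin(sweep(-posr, 2, colsum + diag(r), "+"), 0)
    diag(anew) <- colsum
    a <- damping * a + (1 - damping) * anew

    ex <- which(diag(r) + diag(a) > 0)
    if (identical(ex, exemplars_prev)) {
      stable <- stable + 1L
      if (stable >= conv_iter && length(ex) > 0) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
      exemplars_prev <- ex
    }
  }

  ex <- which(diag(r) + diag(a) > 0)
  if (length(ex) == 0) ex <- which.max(diag(r) + diag(a))
  # final assignment with exemplar refinement (as in the reference
  # implementations): points join their most similar exemplar, then each
  # cluster re-elects the member maximising total within-cluster similarity
  assign_to <- function(ex) {
    idx <- ex[max.col(s[, ex, drop = FALSE], ties.method = "first")]
    idx[ex] <- ex
    idx
  }
  assign_idx <- assign_to(ex)
  for (k in seq_along(ex)) {
    members <- which(assign_idx == ex[k])
    sums <- colSums(s[members, members, drop = FALSE])
    ex[k] <- members[which.max(sums)]
  }
  assign_idx <- assign_to(ex)
  assignment <- setNames(ids[assign_idx], ids)
  # net similarity on the noise-free similarities
  s0 <- -distances^2
  diag(s0) <- pref
  net <- sum(s0[cbind(seq_len(n), assign_idx)])
  if (!converged) {
    warn(sprintf("affinity propagation did not converge in %d iterations", it))
  }
  new_cluster_solution(assignment, ids[ex], q, damping, converged, it, net)
}

new_cluster_solution <- function(assignment, exemplars, q, damping,
                                 converged, iterations, net_similarity) {
  structure(
    list(assignment = assignment, exemplars = exemplars,
         n_clusters = length(exemplars), q = q, damping = damping,
         converged = converged, iterations = iterations,
         net_similarity = net_similarity),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d clusters (q = %.2f, %s, %d iter)\n",
              x$n_clusters, x$q,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Sweep the affinity-propagation preference quantile
#'
#' Runs [affinity_propagation()] for every value of `q_grid` (duplicates
#' removed) and scores each solution by its mean silhouette on the input
#' distances and, optionally, its adjusted Rand index against a reference
#' partition such as the modal-name clusters.
#'
#' @param distances distance matrix.
#' @param reference_assignment optional named vector: reference partition
#'   for the ARI column.
#' @param q_grid numeric vector of quantiles in \[0, 1\].
#' @param damping message damping.
#' @return tibble with `q`, `n_clusters`, `silhouette`, `ari`, `converged`,
#'   plus a `solutions` list-column with the full `cluster_solution`s.
#' @export
q_sweep <- function(distances, reference_assignment = NULL,
                    q_grid = seq(0, 1, by = 0.1), damping = 0.9) {
  if (length(q_grid) == 0) abort("`q_grid` must be nonempty")
  if (any(q_grid < 0 | q_grid > 1)) abort("`q_grid` values must be in [0, 1]")
  q_grid <- sort(unique(q_grid))
  sols <- lapply(q_grid, function(q) {
    withCallingHandlers(
      affinity_propagation(distances, q = q, damping = damping),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  ids <- rownames(distances)
  res <- tibble::tibble(
    q = q_grid,
    n_clusters = vapply(sols, function(s) s$n_clusters, integer(1)),
    silhouette = vapply(sols, function(s) {
      if (s$n_clusters < 2) NA_real_ else silhouette_index(distances, s$assignment)
    }, double(1)),
    ari = if (is.null(reference_assignment)) NA_real_ else
      vapply(sols, function(s) {
        adjusted_rand(s$assignment[ids], reference_assignment[ids])
      }, double(1)),
    converged = vapply(sols, function(s) s$converged, logical(1)),
    solutions = sols
  )
  class(res) <- c("q_sweep", class(res))
  res
}
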