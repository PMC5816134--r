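#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib vocalspace, .registration = TRUE
#' @importFrom rlang .data abort warn %||%
#' @importFrom generics tidy glance
#' @importFrom stats quantile rnorm runif rlogis rbinom sd var cor dist
#'   cmdscale hclust as.dist chisq.test median setNames qlogis plogis
#'   predict optim update
#' @importFrom utils head modifyList
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Validate a stimulus-by-stimulus distance matrix
#'
#' Checks the invariants every distance matrix in the package must satisfy:
#' square, symmetric, zero diagonal, nonnegative, finite, with stimulus ids
#' as dimnames.
#'
#' @param d numeric matrix.
#' @param arg name used in error messages.
#' @return the matrix, invisibly, after validation.
#' @export
validate_distance_matrix <- function(d, arg = "distances") {
  if (!is.matrix(d) || !is.numeric(d)) {
    abort(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (nrow(d) != ncol(d)) abort(sprintf("`%s` must be square", arg))
  if (any(!is.finite(d))) abort(sprintf("`%s` contains non-finite values", arg))
  if (any(d < 0)) abort(sprintf("`%s` has negative entries", arg))
  if (max(abs(d - t(d))) > 1e-8) abort(sprintf("`%s` is not symmetric", arg))
  if (any(abs(diag(d)) > 1e-10)) abort(sprintf("`%s` has a nonzero diagonal", arg))
  invisible(d)
}

# symmetrise tiny numerical asymmetries and zero the diagonal
as_distance_matrix <- function(d, ids = NULL) {
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  d
}

upper_tri_values <- function(d) d[upper.tri(d)]

# Euclidean distance matrix from a coordinate matrix (rows = points)
coords_to_distances <- function(x) {
  d <- as.matrix(dist(x))
  dimnames(d) <- list(rownames(x), rownames(x))
  as_distance_matrix(d)
}

check_count <- function(x, arg, min = 1L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", arg, min))
  }
  as.integer(x)
}

check_positive <- function(x, arg) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", arg))
  }
  as.numeric(x)
}

# derive a stream-specific seed from a base seed, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483629L
}
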