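#' Choice probabilities for one triad
#'
#' Probability of choosing each of the three pairs of a triad given the
#' pairwise distances: a softmax over negative distances,
#' \eqn{P(p) = e^{-d_p/\tau} / \sum_q e^{-d_q/\tau}}. The closest pair is
#' always the most likely choice; the temperature controls how decisive
#' the choice is (as \eqn{\tau \to 0} the minimum-distance pair is chosen
#' with certainty).
#'
#' @param d_ij,d_ik,d_jk nonnegative distances (vectorized).
#' @param temperature positive softmax temperature.
#' @return an n x 3 matrix of probabilities over the pairs
#'   (i,j), (i,k), (j,k); rows sum to 1.
#' @examples
#' triad_choice_prob(1, 2, 3)   # ~ (0.665, 0.245, 0.090)
#' @export
triad_choice_prob <- function(d_ij, d_ik, d_jk, temperature = 1) {
  temperature <- check_positive(temperature, "temperature")
  if (any(c(d_ij, d_ik, d_jk) < 0)) abort("distances must be nonnegative")
  a <- cbind(-d_ij, -d_ik, -d_jk) / temperature
  mx <- apply(a, 1, max)
  e <- exp(a - mx)
  p <- e / rowSums(e)
  colnames(p) <- c("ij", "ik", "jk")
  p
}

#' Sampler configuration for the triad embedding
#'
#' @param d embedding dimensionality (>= 1).
#' @param temperature softmax temperature, fixed at 1 by default (the
#'   distance scale is absorbed by the coordinates under the prior).
#' @param prior_sd sd of the independent normal prior on each coordinate.
#' @param chains,warmup,samples MCMC settings (per chain; `samples` are
#'   post-warmup saved draws).
#' @param thin sweeps between saved draws.
#' @param min_triads_per_participant participants contributing fewer
#'   triads are dropped (incomplete online sessions).
#' @param seed integer seed.
#' @return list of class `embedding_config`.
#' @export
embedding_config <- function(d = 3, temperature = 1, prior_sd = 1,
                             chains = 2, warmup = 500, samples = 500,
                             thin = 2, min_triads_per_participant = 10,
                             seed = 1) {
  structure(
    list(d = check_count(d, "d"), temperature = check_positive(temperature, "temperature"),
         prior_sd = check_positive(prior_sd, "prior_sd"),
         chains = check_count(chains, "chains"),
         warmup = check_count(warmup, "warmup"),
         samples = check_count(samples, "samples"),
         thin = check_count(thin, "thin"),
         min_triads_per_participant = check_count(min_triads_per_participant,
                                                  "min_triads_per_participant",
                                                  min = 1L),
         seed = seed),
    class = "embedding_config"
  )
}

# parse a triad tibble into 1-based index matrices against the stimulus set
parse_triads <- function(triads, stimuli = NULL) {
  need <- c("item1", "item2", "item3", "chosen1", "chosen2")
  missing_cols <- setdiff(need, names(triads))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  its <- cbind(triads$item1, triads$item2, triads$item3)
  if (any(apply(its, 1, anyDuplicated) > 0)) {
    abort("triads with duplicate items found")
  }
  ids <- stimuli %||% sort(unique(as.vector(its)))
  absent <- setdiff(ids, as.vector(its))
  if (length(absent)) {
    abort(paste("stimuli absent from all triads:", paste(absent, collapse = ", ")))
  }
  unknown <- setdiff(as.vector(its), ids)
  if (length(unknown)) {
    abort(paste("triad items outside the stimulus set:",
                paste(unique(unknown), collapse = ", ")))
  }
  items <- matrix(match(its, ids), ncol = 3)
  ch <- cbind(match(triads$chosen1, ids), match(triads$chosen2, ids))
  chosen <- integer(nrow(items))
  for (t in seq_len(nrow(items))) {
    pair <- sort(match(ch[t, ], items[t, ]))
    if (any(is.na(pair))) abort("chosen pair must be a subset of the triad items")
    chosen[t] <- if (identical(pair, c(1L, 2L))) 1L
                 else if (identical(pair, c(1L, 3L))) 2L else 3L
  }
  list(items = items, chosen = chosen, ids = ids)
}

#' Fit the Bayesian triad embedding
#'
#' Embeds every stimulus in a d-dimensional space under independent
#' normal(0, prior_sd) coordinate priors; each triad contributes a
#' [triad_choice_prob()] likelihood term, so the chosen pair pulls its two
#' stimuli together relative to the third. Sampling is adaptive
#' random-walk Metropolis over per-stimulus coordinate blocks, run as
#' independent chains. Because the likelihood is invariant under global
#' isometries, all summaries are distance-based: the reported distance
#' matrix is the posterior mean of the pairwise distances computed per
#' draw (not the distances of the mean coordinates, which would shrink
#' under rotation ambiguity).
#'
#' @param triads triad-trial tibble (`participant`, `item1..3`,
#'   `chosen1..2`).
#' @param config an [embedding_config()].
#' @param stimuli optional full stimulus id vector; an error lists any
#'   stimulus absent from all triads.
#' @return object of class `embedding_posterior`: `draws`
#'   (samples x stimuli x d array), `mean_distance_matrix`,
#'   `pointwise_loglik` (samples x triads), `diagnostics`, `ids`,
#'   `config`, `n_triads`.
#' @export
fit_embedding <- function(triads, config = embedding_config(),
                          stimuli = NULL) {
  stopifnot(inherits(config, "embedding_config"))
  if ("participant" %in% names(triads)) {
    n_by_part <- table(triads$participant)
    keep_part <- names(n_by_part)[n_by_part >= config$min_triads_per_participant]
    triads <- dplyr::filter(triads, .data$participant %in% keep_part)
  }
  if (nrow(triads) == 0) abort("no triads left after the participation filter")
  pt <- parse_triads(triads, stimuli)
  n <- length(pt$ids)

  all_draws <- vector("list", config$chains)
  acc <- numeric(0)
  for (ch in seq_len(config$chains)) {
    withr::local_seed(derive_seed(config$seed, 20L + ch))
    X0 <- matrix(rnorm(n * config$d, 0, config$prior_sd), n, config$d)
    res <- triad_rwm_cpp(X0, pt$items, pt$chosen,
                         config$temperature, config$prior_sd,
                         as.integer(config$warmup),
                         as.integer(config$samples),
                         as.integer(config$thin), 0.5)
    all_draws[[ch]] <- res$draws
    acc <- c(acc, res$acceptance)
  }
  draws <- do.call(abind_first, all_draws)

  ll <- pointwise_loglik_from_draws(draws, pt$items, pt$chosen,
                                    config$temperature)
  if (any(!is.finite(ll))) abort("non-finite pointwise log-likelihoods")

  mean_dist <- draws_mean_distances(draws, pt$ids)

  # convergence diagnostics on an isometry-invariant scalar per chain
  scalar_by_chain <- lapply(all_draws, function(dr) {
    apply(dr, 1, function(x) mean(dist(matrix(x, n, config$d))))
  })
  ess <- sum(vapply(scalar_by_chain, ess_draws, double(1)))
  rhat <- rhat_chains(scalar_by_chain)
  diagnostics <- tibble::tibble(
    mean_acceptance = mean(acc), ess_mean_distance = ess, rhat_mean_distance = rhat
  )
  if (ess < 50 || (is.finite(rhat) && rhat > 1.1)) {
    warn(sprintf("embedding sampler diagnostics are weak (ESS %.0f, Rhat %.2f)",
                 ess, rhat))
  }

  structure(
    list(draws = draws, mean_distance_matrix = mean_dist,
         pointwise_loglik = ll, diagnostics = diagnostics,
         ids = pt$ids, config = config, n_triads = nrow(pt$items)),
    class = "embedding_posterior"
  )
}

# posterior mean of per-draw pairwise distance matrices
draws_mean_distances <- function(draws, ids) {
  n_draws <- dim(draws)[1]
  n <- dim(draws)[2]
  msum <- matrix(0, n, n)
  for (s in seq_len(n_draws)) {
    x <- draws[s, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    msum <- msum + as.matrix(dist(x))
  }
  as_distance_matrix(msum / n_draws, ids)
}

# bind draw arrays (draws x n x d) along the first dimension
abind_first <- function(...) {
  arrs <- list(...)
  d2 <- dim(arrs[[1]])[2]; d3 <- dim(arrs[[1]])[3]
  flat <- do.call(rbind, lapply(arrs, function(a) {
    matrix(a, nrow = dim(a)[1])
  }))
  array(flat, dim = c(nrow(flat), d2, d3))
}

rhat_chains <- function(chains) {
  if (length(chains) < 2) return(NA_real_)
  n <- min(lengths(chains))
  chains <- lapply(chains, function(x) x[seq_len(n)])
  means <- vapply(chains, mean, double(1))
  vars <- vapply(chains, var, double(1))
  b <- n * var(means)
  w <- mean(vars)
  if (w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

pointwise_loglik_from_draws <- function(draws, items, chosen, temperature) {
  n_draws <- dim(draws)[1]
  m <- nrow(items)
  ll <- matrix(NA_real_, n_draws, m)
  pick <- cbind(seq_len(m), chosen)
  for (s in seq_len(n_draws)) {
    X <- draws[s, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1)
    d1 <- sqrt(rowSums((X[items[, 1], , drop = FALSE] -
                          X[items[, 2], , drop = FALSE])^2))
    d2 <- sqrt(rowSums((X[items[, 1], , drop = FALSE] -
                          X[items[, 3], , drop = FALSE])^2))
    d3 <- sqrt(rowSums((X[items[, 2], , drop = FALSE] -
                          X[items[, 3], , drop = FALSE])^2))
    a <- cbind(-d1, -d2, -d3) / temperature
    mx <- pmax(a[, 1], a[, 2], a[, 3])
    lse <- mx + log(exp(a[, 1] - mx) + exp(a[, 2] - mx) + exp(a[, 3] - mx))
    ll[s, ] <- a[pick] - lse
  }
  ll
}

#' @export
print.embedding_posterior <- function(x, ...) {
  cat(sprintf("<embedding_posterior> %d stimuli in d = %d, %d draws, %d triads\n",
              length(x$ids), x$config$d, dim(x$draws)[1], x$n_triads))
  print(x$diagnostics)
  invisible(x)
}

#' Posterior-mean distance matrix of an embedding
#'
#' Pairwise distances computed per posterior draw and averaged over
#' draws — an isometry-invariant summary of the inferred configuration.
#'
#' @param posterior an [fit_embedding()] object.
#' @return distance matrix over the stimuli.
#' @export
posterior_distance_matrix <- function(posterior) {
  stopifnot(inherits(posterior, "embedding_posterior"))
  posterior$mean_distance_matrix
}

#' Watanabe-Akaike information criterion
#'
#' Fully Bayesian predictive-fit estimate from the pointwise posterior
#' log-likelihood matrix: lppd = sum over observations of the log of the
#' mean (over draws) likelihood; the effective number of parameters
#' p_waic = sum of the per-observation variances of the log-likelihood
#' across draws (computed with the 1/S divisor, so the estimate is
#' invariant to duplicating the draw set); WAIC = -2 (lppd - p_waic).
#' Lower is better.
#'
#' @param pointwise_loglik draws x observations matrix of log-likelihoods.
#' @return list with `waic`, `lppd`, `p_waic`, `se` (pointwise standard
#'   error of WAIC).
#' @export
waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 2) abort("need at least 2 posterior draws")
  if (any(!is.finite(ll))) abort("non-finite log-likelihoods")
  lppd_i <- apply(ll, 2, logsumexp) - log(nrow(ll))
  p_i <- apply(ll, 2, function(x) mean((x - mean(x))^2))
  waic_i <- -2 * (lppd_i - p_i)
  list(waic = sum(waic_i), lppd = sum(lppd_i), p_waic = sum(p_i),
       se = sqrt(ncol(ll) * var(waic_i)))
}

#' Sweep the embedding dimensionality
#'
#' Fits the triad embedding for every dimensionality in `d_values` and
#' tabulates WAIC (plus a normalized negative WAIC convenient for
#' plotting: 1 for the best-fitting model, 0 for the worst) and, when
#' reference distance matrices are supplied, the Mantel-style correlation
#' of each fitted distance matrix with each reference.
#'
#' @param triads triad-trial tibble.
#' @param d_values integer vector of dimensionalities.
#' @param config an [embedding_config()]; its `d` is overridden.
#' @param reference_matrices optional named list of distance matrices over
#'   the same stimuli.
#' @return tibble with `d`, `waic`, `lppd`, `p_waic`, `neg_waic_norm`, one
#'   `r_<name>` column per reference, and a `fits` list-column.
#' @export
dimension_sweep <- function(triads, d_values, config = embedding_config(),
                            reference_matrices = NULL) {
  if (length(d_values) == 0) abort("`d_values` must be nonempty")
  fits <- lapply(d_values, function(dd) {
    cfg <- config
    cfg$d <- check_count(dd, "d")
    fit_embedding(triads, cfg)
  })
  ws <- lapply(fits, function(f) waic(f$pointwise_loglik))
  out <- tibble::tibble(
    d = as.integer(d_values),
    waic = vapply(ws, `[[`, double(1), "waic"),
    lppd = vapply(ws, `[[`, double(1), "lppd"),
    p_waic = vapply(ws, `[[`, double(1), "p_waic")
  )
  rng <- range(-out$waic)
  out$neg_waic_norm <- if (diff(rng) == 0) rep(1, nrow(out)) else
    (-out$waic - rng[1]) / diff(rng)
  for (nm in names(reference_matrices %||% list())) {
    ref <- reference_matrices[[nm]]
    out[[paste0("r_", nm)]] <- vapply(fits, function(f) {
      ids <- f$ids
      matrix_correlation(f$mean_distance_matrix,
                         ref[ids, ids, drop = FALSE])
    }, double(1))
  }
  out$fits <- fits
  class(out) <- c("dimension_sweep", class(out))
  out
}

#' Procrustes alignment of two configurations
#'
#' Least-squares superimposition of configuration `b` onto configuration
#' `a` allowing translation, rotation/reflection and uniform scaling
#' (used only for display; inference summaries stay distance-based).
#' Disparity is the symmetric Procrustes sum of squared residuals after
#' both configurations are centred and scaled to unit sum of squares.
#'
#' @param coords_a,coords_b matrices of identical shape.
#' @return list with `aligned` (b mapped onto a), `disparity`,
#'   `rotation`, `scale`.
#' @export
procrustes_align <- function(coords_a, coords_b) {
  if (!all(dim(coords_a) == dim(coords_b))) {
    abort("configurations must have the same shape")
  }
  if (sd(as.vector(coords_a)) == 0 || sd(as.vector(coords_b)) == 0) {
    abort("degenerate configuration: all points identical")
  }
  pr <- vegan::procrustes(coords_a, coords_b, scale = TRUE, symmetric = TRUE)
  full <- vegan::procrustes(coords_a, coords_b, scale = TRUE,
                            symmetric = FALSE)
  list(aligned = full$Yrot, disparity = pr$ss,
       rotation = full$rotation, scale = full$scale)
}
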