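#' Normalized Shannon entropy of label choices
#'
#' Consistency of naming for one stimulus:
#' \deqn{-\sum_i \frac{a_i}{\sum a}\log_2\frac{a_i}{\sum a} \Big/
#'   \log_2(\mathrm{n\_alternatives}) \times 100}
#' where `a` is the vector of choice counts over the full label inventory
#' and zero counts contribute nothing. 0% means everyone chose the same
#' label; 100% means choices were uniform over all alternatives.
#'
#' @param counts nonnegative integer vector of choice counts, one entry per
#'   alternative label.
#' @param n_alternatives number of alternative labels (defaults to
#'   `length(counts)`).
#' @return entropy as a percentage in \[0, 100\].
#' @examples
#' normalized_entropy(c(5, 5, 5, 5))   # 100
#' normalized_entropy(c(10, 0, 0, 0))  # 0
#' @export
normalized_entropy <- function(counts, n_alternatives = length(counts)) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("`counts` must be finite and nonnegative")
  }
  if (length(counts) != n_alternatives) {
    abort("`counts` must have one entry per alternative")
  }
  if (n_alternatives < 2) abort("need at least 2 alternatives")
  tot <- sum(counts)
  if (tot == 0) abort("all-zero counts: no choices recorded")
  p <- counts / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(n_alternatives) * 100
}

#' Per-stimulus naming entropies from trials
#'
#' Computes [normalized_entropy()] for every stimulus, for sound names and
#' emotion names, from pooled label-choice counts (multi-label answers
#' count each chosen label once).
#'
#' @param trials naming-trial tibble.
#' @param sound_labels,emotion_labels full label inventories.
#' @return tibble with `stimulus`, `entropy_sound`, `entropy_emotion`.
#' @export
naming_entropies <- function(trials, sound_labels, emotion_labels) {
  count_mat <- function(kind, labels) {
    stimuli <- unique(trials$stimulus)
    labs <- split_labels(trials[[paste0(kind, "_names")]])
    tab <- table(factor(rep(trials$stimulus, lengths(labs)), levels = stimuli),
                 factor(unlist(labs), levels = labels))
    apply(tab, 1, normalized_entropy, n_alternatives = length(labels))
  }
  es <- count_mat("sound", sound_labels)
  ee <- count_mat("emotion", emotion_labels)
  tibble::tibble(stimulus = names(es), entropy_sound = unname(es),
                 entropy_emotion = unname(ee))
}

#' Paired contrast of naming entropies
#'
#' Bayesian Gaussian model on paired per-stimulus differences (emotion
#' minus sound entropy): difference mean with a flat-ish normal prior and
#' half-normal prior on the residual sd, sampled by Gibbs/slice updates.
#' Reports the posterior mean difference, 95% credible interval and the
#' standardized effect size (Cohen's d = mean / sd of the differences).
#'
#' @param entropies_sound,entropies_emotion paired numeric vectors (one
#'   entry per stimulus, equal length >= 3).
#' @param n_draws posterior draws (after warmup).
#' @param seed integer seed.
#' @return a `hierarchical_fit` object; fixed effect `difference` is
#'   emotion minus sound, plus `cohens_d`.
#' @export
entropy_contrast <- function(entropies_sound, entropies_emotion,
                             n_draws = 2000, seed = 1) {
  if (length(entropies_sound) != length(entropies_emotion)) {
    abort("entropy vectors must be paired (equal length)")
  }
  n <- length(entropies_sound)
  if (n < 3) abort("need at least 3 paired stimuli")
  diffs <- entropies_emotion - entropies_sound

  withr::local_seed(derive_seed(seed, 5L))
  # conjugate-style Gibbs: mu | sigma ~ normal, sigma via slice under
  # half-normal(0, 2 * sd(diffs)) prior
  prior_mu_sd <- 100
  sigma_scale <- 2 * max(sd(diffs), 1e-6)
  mu <- mean(diffs)
  sigma <- max(sd(diffs), 1e-6)
  draws <- matrix(NA_real_, n_draws, 2, dimnames = list(NULL, c("mu", "sigma")))
  warmup <- 500
  for (t in seq_len(warmup + n_draws)) {
    prec <- n / sigma^2 + 1 / prior_mu_sd^2
    mu <- rnorm(1, (sum(diffs) / sigma^2) / prec, sqrt(1 / prec))
    sigma <- slice_sample_sd(sum((diffs - mu)^2), n, sigma, sigma_scale)
    if (t > warmup) draws[t - warmup, ] <- c(mu, sigma)
  }
  d_draws <- draws[, "mu"] / draws[, "sigma"]
  new_hierarchical_fit(
    fixed = list(difference = draws[, "mu"], cohens_d = d_draws),
    sd_draws = list(residual = draws[, "sigma"]),
    model = "entropy_contrast", n_obs = n
  )
}

# univariate slice sampler for a residual sd with half-normal(0, scale)
# prior given a Gaussian sum of squares `ss` over `n` observations
slice_sample_sd <- function(ss, n, current, scale) {
  logpost <- function(sg) {
    if (sg <= 0) return(-Inf)
    -n * log(sg) - ss / (2 * sg^2) - sg^2 / (2 * scale^2)
  }
  y <- logpost(current) - stats::rexp(1)
  lo <- max(current - 1, 1e-9)
  hi <- current + 1
  while (logpost(lo) > y && lo > 1e-9) lo <- max(lo / 2, 1e-9)
  while (logpost(hi) > y) hi <- hi * 2
  repeat {
    prop <- runif(1, lo, hi)
    if (logpost(prop) > y) return(prop)
    if (prop < current) lo <- prop else hi <- prop
  }
}
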