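# Container for posterior summaries shared by every Bayesian model in the
# package. `fixed` and `sd_draws` are named lists of draw vectors.
new_hierarchical_fit <- function(fixed, sd_draws = list(), model = "model",
                                 n_obs = NA_integer_, extra = list()) {
  summarise_draws <- function(x) {
    qs <- quantile(x, c(0.025, 0.975), names = FALSE)
    tibble::tibble(mean = mean(x), median = median(x),
                   conf.low = qs[1], conf.high = qs[2],
                   ess = ess_draws(x))
  }
  fe <- dplyr::bind_cols(
    tibble::tibble(term = names(fixed)),
    dplyr::bind_rows(lapply(fixed, summarise_draws))
  )
  re <- if (length(sd_draws)) {
    dplyr::bind_cols(
      tibble::tibble(group = names(sd_draws)),
      dplyr::bind_rows(lapply(sd_draws, summarise_draws))
    )
  } else {
    tibble::tibble()
  }
  structure(
    c(list(fixed_effects = fe, random_effect_sds = re,
           draws = c(fixed, sd_draws), model = model, n_obs = n_obs),
      extra),
    class = "hierarchical_fit"
  )
}

# crude effective sample size from lag-autocorrelations (Geyer initial
# positive sequence, capped)
ess_draws <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(as.numeric(n))
  acf_ <- stats::acf(x, lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
  pos <- which(acf_ < 0.05)
  cutoff <- if (length(pos)) pos[1] - 1 else length(acf_)
  denom <- 1 + 2 * sum(acf_[seq_len(cutoff)])
  max(1, n / max(denom, 1e-3))
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat(sprintf("<hierarchical_fit> %s (n = %s)\n", x$model, x$n_obs))
  print(x$fixed_effects)
  if (nrow(x$random_effect_sds)) {
    cat("random-effect sds:\n")
    print(x$random_effect_sds)
  }
  invisible(x)
}

#' @export
tidy.hierarchical_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    x$fixed_effects
  } else {
    dplyr::rename(x$random_effect_sds, term = "group")
  }
}

#' @export
glance.hierarchical_fit <- function(x, ...) {
  tibble::tibble(model = x$model, nobs = x$n_obs,
                 n_fixed = nrow(x$fixed_effects),
                 n_groups = nrow(x$random_effect_sds),
                 min_ess = min(c(x$fixed_effects$ess,
                                 x$random_effect_sds$ess), na.rm = TRUE))
}

# Gibbs sampler for y = X beta + u[g1] + v[g2] + eps with normal priors on
# beta (sd 2.5 on standardized predictors), half-normal(0, prior sd scale)
# on the three sds. Returns draw vectors. Fully conjugate except the sds,
# which use slice updates.
gibbs_gaussian_crossed <- function(y, X, g1, g2, n_draws = 1000,
                                   warmup = 500, beta_prior_sd = 2.5,
                                   sd_scale = 1, seed = 1) {
  withr::local_seed(derive_seed(seed, 6L))
  n <- length(y)
  p <- ncol(X)
  g1 <- as.integer(factor(g1)); n1 <- max(g1)
  g2 <- as.integer(factor(g2)); n2 <- max(g2)
  if (n1 < 2 || n2 < 2) abort("each grouping factor needs at least 2 levels")

  beta <- rep(0, p)
  u <- rep(0, n1); v <- rep(0, n2)
  sig_e <- max(sd(y), 0.1); sig_u <- 0.5 * sd_scale; sig_v <- 0.5 * sd_scale
  xtx <- crossprod(X)
  draws_beta <- matrix(NA_real_, n_draws, p, dimnames = list(NULL, colnames(X)))
  draws_sd <- matrix(NA_real_, n_draws, 3,
                     dimnames = list(NULL, c("participant", "stimulus", "residual")))
  cnt1 <- tabulate(g1, n1); cnt2 <- tabulate(g2, n2)

  for (t in seq_len(warmup + n_draws)) {
    # beta | rest
    resid <- y - u[g1] - v[g2]
    prec <- xtx / sig_e^2 + diag(1 / beta_prior_sd^2, p)
    ch <- chol(prec)
    mu_b <- backsolve(ch, forwardsolve(t(ch), crossprod(X, resid) / sig_e^2))
    beta <- drop(mu_b + backsolve(ch, rnorm(p)))
    # u | rest (vectorized per-level conjugate normal)
    r1 <- y - drop(X %*% beta) - v[g2]
    s1 <- rowsum(r1, g1)[, 1]
    prec1 <- cnt1 / sig_e^2 + 1 / sig_u^2
    u <- rnorm(n1, (s1 / sig_e^2) / prec1, sqrt(1 / prec1))
    # v | rest
    r2 <- y - drop(X %*% beta) - u[g1]
    s2 <- rowsum(r2, g2)[, 1]
    prec2 <- cnt2 / sig_e^2 + 1 / sig_v^2
    v <- rnorm(n2, (s2 / sig_e^2) / prec2, sqrt(1 / prec2))
    # sds via slice under half-normal priors
    eps <- y - drop(X %*% beta) - u[g1] - v[g2]
    sig_e <- slice_sample_sd(sum(eps^2), n, sig_e, sd_scale * 2)
    sig_u <- slice_sample_sd(sum(u^2), n1, sig_u, sd_scale)
    sig_v <- slice_sample_sd(sum(v^2), n2, sig_v, sd_scale)
    if (t > warmup) {
      draws_beta[t - warmup, ] <- beta
      draws_sd[t - warmup, ] <- c(sig_u, sig_v, sig_e)
    }
  }
  list(beta = draws_beta, sds = draws_sd, n1 = n1, n2 = n2)
}
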