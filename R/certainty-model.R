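jags_sample <- function(model_string, data, params, n_draws, warmup, seed,
                        inits = NULL) {
  init <- c(inits %||% list(),
            list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = derive_seed(seed, 7L)))
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = data, inits = init, n.chains = 1,
                          n.adapt = max(200, warmup %/% 2), quiet = TRUE)
  update(jm, warmup, progress.bar = "none")
  out <- rjags::coda.samples(jm, params, n.iter = n_draws,
                             progress.bar = "none")
  as.matrix(out[[1]])
}

#' Ordinal model of subjective naming certainty
#'
#' Cumulative-logit (proportional-odds) regression of the 1-3 certainty
#' rating (Don't know / Unsure / Sure) with a fixed effect of naming kind
#' (sound vs. emotion) and crossed random intercepts for participant and
#' stimulus, fitted by MCMC through JAGS. Reports the latent-scale
#' sound-vs-emotion contrast and the implied per-category probabilities
#' for each kind at the average participant and stimulus.
#'
#' @param trials naming-trial tibble with `certainty_sound`,
#'   `certainty_emotion`, `participant`, `stimulus`.
#' @param n_draws,warmup sampler settings.
#' @param seed integer seed.
#' @return a `hierarchical_fit`; fixed effect `kind_sound` is the latent
#'   shift for sound naming (positive = more certain), and
#'   `category_probs` holds the posterior-mean P(category | kind).
#' @export
fit_certainty_model <- function(trials, n_draws = 1000, warmup = 500,
                                seed = 1) {
  long <- tidyr::pivot_longer(
    dplyr::select(trials, "participant", "stimulus",
                  "certainty_sound", "certainty_emotion"),
    cols = dplyr::starts_with("certainty_"),
    names_to = "kind", values_to = "certainty", names_prefix = "certainty_"
  )
  long <- dplyr::filter(long, !is.na(.data$certainty))
  if (!all(long$certainty %in% 1:3)) {
    abort("certainty values must be in {1, 2, 3}")
  }
  present <- sort(unique(long$certainty))
  if (length(present) < 2) abort("certainty has a single category; model not estimable")
  if (length(present) < 3) {
    warn(paste("certainty category(ies) entirely absent:",
               paste(setdiff(1:3, present), collapse = ", ")))
  }

  model <- "
model {
  for (i in 1:N) {
    eta[i] <- b_sound * x[i] + u[part[i]] + v[stim[i]]
    q1[i] <- ilogit(c1 - eta[i])
    q2[i] <- ilogit(c2 - eta[i])
    p[i, 1] <- max(q1[i], 1e-10)
    p[i, 2] <- max(q2[i] - q1[i], 1e-10)
    p[i, 3] <- max(1 - q2[i], 1e-10)
    y[i] ~ dcat(p[i, 1:3])
  }
  b_sound ~ dnorm(0, 0.16)
  c1 ~ dnorm(0, 0.04)
  c2 <- c1 + exp(log_gap)
  log_gap ~ dnorm(0, 1)
  for (j in 1:NP) { u[j] ~ dnorm(0, tau_u) }
  for (k in 1:NS) { v[k] ~ dnorm(0, tau_v) }
  sigma_u ~ dnorm(0, 1) T(0,)
  sigma_v ~ dnorm(0, 1) T(0,)
  tau_u <- pow(sigma_u, -2)
  tau_v <- pow(sigma_v, -2)
}"
  part <- as.integer(factor(long$participant))
  stim <- as.integer(factor(long$stimulus))
  if (max(part) < 2 || max(stim) < 2) {
    abort("each grouping factor needs at least 2 levels")
  }
  draws <- jags_sample(
    model,
    data = list(N = nrow(long), NP = max(part), NS = max(stim),
                y = long$certainty,
                x = as.numeric(long$kind == "sound"),
                part = part, stim = stim),
    params = c("b_sound", "c1", "c2", "sigma_u", "sigma_v"),
    n_draws = n_draws, warmup = warmup, seed = seed
  )

  cat_probs <- function(eta) {
    q1 <- plogis(draws[, "c1"] - eta)
    q2 <- plogis(draws[, "c2"] - eta)
    c(dont_know = mean(q1), unsure = mean(q2 - q1), sure = mean(1 - q2))
  }
  probs <- dplyr::bind_rows(
    tibble::tibble(kind = "sound", category = names(cat_probs(0)),
                   probability = cat_probs(draws[, "b_sound"])),
    tibble::tibble(kind = "emotion", category = names(cat_probs(0)),
                   probability = cat_probs(0))
  )
  new_hierarchical_fit(
    fixed = list(kind_sound = draws[, "b_sound"],
                 threshold_1 = draws[, "c1"],
                 threshold_2 = draws[, "c2"]),
    sd_draws = list(participant = draws[, "sigma_u"],
                    stimulus = draws[, "sigma_v"]),
    model = "certainty_ordinal", n_obs = nrow(long),
    extra = list(category_probs = probs)
  )
}

#' Preference for naming the sound before the emotion
#'
#' Bayesian logistic regression of the "named the sound first" indicator
#' with the screen layout as covariate (+1 when sound names are on the
#' left, -1 when on the right) and a participant random intercept. The
#' layout term absorbs the left-to-right reading bias; the intercept is
#' the residual sound-first preference, reported as an odds ratio
#' `exp(2 * intercept)` (the odds of naming the sound first when sound
#' names are on the right, relative to the mirror-image behaviour).
#'
#' @param trials naming-trial tibble with `layout`, `participant` and
#'   either a logical `sound_first` column or both first-name timestamps
#'   (`t_first_sound < t_first_emotion` then defines the outcome).
#' @param n_draws,warmup sampler settings.
#' @param seed integer seed.
#' @return a `hierarchical_fit`; fixed effects `preference_log_odds`,
#'   `layout_log_odds` and the derived `odds_ratio`.
#' @export
order_preference <- function(trials, n_draws = 1000, warmup = 500, seed = 1) {
  if (!"layout" %in% names(trials) || any(is.na(trials$layout))) {
    abort("trials must record `layout` for every row")
  }
  if (length(unique(trials$layout)) < 2) {
    abort("all trials share one layout; the preference is not identifiable")
  }
  y <- if ("sound_first" %in% names(trials)) {
    trials$sound_first
  } else {
    if (!all(c("t_first_sound", "t_first_emotion") %in% names(trials))) {
      abort("need `sound_first` or both first-name timestamps")
    }
    trials$t_first_sound < trials$t_first_emotion
  }
  keep <- !is.na(y)
  y <- as.integer(y[keep])
  x <- ifelse(trials$layout[keep] == "sound_left", 1, -1)
  part <- as.integer(factor(trials$participant[keep]))

  model <- "
model {
  for (i in 1:N) {
    logit(p[i]) <- pref + lambda * x[i] + u[part[i]]
    y[i] ~ dbern(p[i])
  }
  pref ~ dnorm(0, 0.16)
  lambda ~ dnorm(0, 0.16)
  for (j in 1:NP) { u[j] ~ dnorm(0, tau_u) }
  sigma_u ~ dnorm(0, 1) T(0,)
  tau_u <- pow(sigma_u, -2)
}"
  draws <- jags_sample(
    model,
    data = list(N = length(y), NP = max(part), y = y, x = x, part = part),
    params = c("pref", "lambda", "sigma_u"),
    n_draws = n_draws, warmup = warmup, seed = seed
  )
  new_hierarchical_fit(
    fixed = list(preference_log_odds = draws[, "pref"],
                 layout_log_odds = draws[, "lambda"],
                 odds_ratio = exp(2 * draws[, "pref"])),
    sd_draws = list(participant = draws[, "sigma_u"]),
    model = "order_preference", n_obs = length(y)
  )
}
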