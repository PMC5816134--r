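# Default loadings mapping the 3 latent perceptual dimensions onto the 12
# acoustic variables. Dimension 1 loads on pitch and spectral balance,
# dimension 2 on burst/temporal structure, dimension 3 on voicing and
# amplitude — echoing the roles the acoustic variables play in practice.
default_acoustic_loadings <- function(dim = 3) {
  m <- rbind(
    amplitude_median    = c(0.2,  -0.2,  0.6),
    prop_voiced         = c(0.3,  -0.4,  0.8),
    pitch_median        = c(1.1,   0.2,  0.1),
    pitch_sd            = c(0.5,   0.1,  0.3),
    quartile1_median    = c(0.9,   0.0,  0.2),
    quartile1_sd        = c(0.3,   0.2,  0.4),
    spectral_entropy_sd = c(0.1,   0.2, -0.6),
    interburst_median   = c(0.0,  -0.7,  0.2),
    interburst_sd       = c(0.1,  -0.8, -0.1),
    n_bursts            = c(-0.2,  1.1,  0.0),
    syllable_median     = c(0.0,  -0.5, -0.4),
    syllable_sd         = c(0.1,  -0.3, -0.5)
  )
  if (dim <= 3) return(m[, seq_len(dim), drop = FALSE])
  cbind(m, matrix(0, nrow(m), dim - 3))
}

#' Default generative parameters for the simulators
#'
#' Bundles every knob of the synthetic-data generator. Defaults are chosen
#' to emulate the scale of real naming studies of non-linguistic
#' vocalizations: first-name latencies around 5 s with the emotion name
#' ~0.16 log-units slower, mostly "Sure" certainty ratings, softmax naming
#' confusion concentrated within synonym groups, and a strong but not
#' absolute left-to-right response bias.
#'
#' @param dim latent dimensionality the acoustic loadings should match.
#' @param ... named overrides of any default element.
#' @return a list of class `vocal_gen_params`.
#' @export
default_gen_params <- function(dim = 3, ...) {
  p <- list(
    naming_temperature = 1,
    multi_label_threshold = 0.25,
    certainty_slope = 8,
    certainty_cuts = c(-2, 0),
    rt_location_sound = log(5),
    rt_location_emotion = log(5) + 0.16,
    rt_sd_participant = 0.3,
    rt_sd_stimulus = 0.2,
    rt_sd_resid = 0.5,
    order_pref_logit = 1.2,
    layout_logit = 2.5,
    triad_temperature = 1,
    acoustic_loadings = default_acoustic_loadings(dim),
    acoustic_noise_sd = 1,
    n_distractor_features = 0
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) abort(paste("unknown parameter(s):", paste(bad, collapse = ", ")))
  p <- modifyList(p, over)
  if (p$naming_temperature <= 0 || p$triad_temperature <= 0) {
    abort("temperatures must be positive")
  }
  sds <- c(p$rt_sd_participant, p$rt_sd_stimulus, p$rt_sd_resid,
           p$acoustic_noise_sd)
  if (any(sds < 0)) abort("standard deviations must be nonnegative")
  if (p$multi_label_threshold <= 0 || p$multi_label_threshold >= 1) {
    abort("multi_label_threshold must be in (0, 1)")
  }
  structure(p, class = "vocal_gen_params")
}

# softmax label-choice probabilities for every stimulus: stimulus x label
label_choice_probs <- function(coords, prototypes, temperature) {
  d2 <- outer(rowSums(coords^2), rowSums(prototypes^2), "+") -
    2 * coords %*% t(prototypes)
  d <- sqrt(pmax(d2, 0))
  p <- exp(-(d - apply(d, 1, min)) / temperature)
  p / rowSums(p)
}

# draw labels for one name kind over all participants x stimuli; returns a
# list with label strings (";"-joined, primary first) and certainty 1..3
draw_names <- function(probs, labels, n_participants, params) {
  n_stim <- nrow(probs)
  sorted <- t(apply(probs, 1, sort, decreasing = TRUE))
  margin <- sorted[, 1] - sorted[, 2]      # per-stimulus top-2 margin
  names_out <- matrix("", n_stim, n_participants)
  cert_out <- matrix(0L, n_stim, n_participants)
  for (s in seq_len(n_stim)) {
    prim <- sample(labels, n_participants, replace = TRUE, prob = probs[s, ])
    extra <- labels[probs[s, ] >= params$multi_label_threshold]
    lab <- vapply(prim, function(pl) {
      paste(c(pl, setdiff(extra, pl)), collapse = ";")
    }, character(1))
    latent <- params$certainty_slope * margin[s] +
      rlogis(n_participants)
    cert <- 1L + findInterval(latent, params$certainty_cuts)
    names_out[s, ] <- lab
    cert_out[s, ] <- cert
  }
  list(names = names_out, certainty = cert_out)
}

#' Simulate a cross-linguistic naming experiment
#'
#' Generates one naming trial per participant x stimulus. Label-choice
#' probabilities are a softmax over negative distances between the stimulus
#' and each label prototype, divided by `naming_temperature`; the primary
#' label is sampled and any other label whose choice probability reaches
#' `multi_label_threshold` is added (multi-label answers). Certainty (1 =
#' Don't know, 2 = Unsure, 3 = Sure) increases with the margin between the
#' two best labels. First-name latencies are lognormal with crossed random
#' intercepts for participant and stimulus and a location offset between
#' emotion and sound naming. The screen layout (sound names left or right)
#' is counterbalanced across participants, and the "named the sound first"
#' indicator follows a logistic model combining a left-to-right bias with a
#' sound-first preference.
#'
#' @param world a [make_world()] object.
#' @param lexicon a [make_lexicon()] object sharing the world's dimension.
#' @param n_participants number of participants (0 gives an empty tibble).
#' @param params a [default_gen_params()] list.
#' @param seed integer seed.
#' @return tibble with one row per participant x stimulus: `participant`,
#'   `language`, `stimulus`, `sound_names` and `emotion_names`
#'   (";"-separated, primary label first), `certainty_sound`,
#'   `certainty_emotion`, `t_first_sound`, `t_first_emotion`, `t_next`
#'   (seconds), `layout` ("sound_left"/"sound_right") and `sound_first`.
#' @export
simulate_naming <- function(world, lexicon, n_participants = 20,
                            params = default_gen_params(world$dim),
                            seed = 1) {
  stopifnot(inherits(world, "vocal_world"), inherits(lexicon, "vocal_lexicon"))
  n_participants <- check_count(n_participants, "n_participants", min = 0L)
  if (ncol(lexicon$sound_prototypes) != world$dim) {
    abort("lexicon prototypes do not share the world's dimension")
  }
  empty <- tibble::tibble(
    participant = character(), language = character(), stimulus = character(),
    sound_names = character(), emotion_names = character(),
    certainty_sound = integer(), certainty_emotion = integer(),
    t_first_sound = double(), t_first_emotion = double(), t_next = double(),
    layout = character(), sound_first = logical()
  )
  if (n_participants == 0L) return(empty)

  withr::local_seed(derive_seed(seed, 2L))
  coords <- world$latent_coords
  n_stim <- nrow(coords)
  ids <- rownames(coords)

  p_sound <- label_choice_probs(coords, lexicon$sound_prototypes,
                                params$naming_temperature)
  p_emo <- label_choice_probs(coords, lexicon$emotion_prototypes,
                              params$naming_temperature)
  snd <- draw_names(p_sound, lexicon$sound_labels, n_participants, params)
  emo <- draw_names(p_emo, lexicon$emotion_labels, n_participants, params)

  part_ids <- sprintf("%s_p%03d", substr(lexicon$language, 1, 2),
                      seq_len(n_participants))
  layout <- ifelse(seq_len(n_participants) %% 2L == 1L,
                   "sound_left", "sound_right")
  u_part <- rnorm(n_participants, 0, params$rt_sd_participant)
  v_stim <- rnorm(n_stim, 0, params$rt_sd_stimulus)

  grid <- tidyr::expand_grid(pi_ = seq_len(n_participants),
                             si_ = seq_len(n_stim))
  eta <- u_part[grid$pi_] + v_stim[grid$si_]
  t_sound <- exp(params$rt_location_sound + eta +
                   rnorm(nrow(grid), 0, params$rt_sd_resid))
  t_emo <- exp(params$rt_location_emotion + eta +
                 rnorm(nrow(grid), 0, params$rt_sd_resid))
  x_layout <- ifelse(layout[grid$pi_] == "sound_left", 1, -1)
  p_first <- plogis(params$order_pref_logit + params$layout_logit * x_layout)
  sound_first <- runif(nrow(grid)) < p_first

  tibble::tibble(
    participant = part_ids[grid$pi_],
    language = lexicon$language,
    stimulus = ids[grid$si_],
    sound_names = snd$names[cbind(grid$si_, grid$pi_)],
    emotion_names = emo$names[cbind(grid$si_, grid$pi_)],
    certainty_sound = snd$certainty[cbind(grid$si_, grid$pi_)],
    certainty_emotion = emo$certainty[cbind(grid$si_, grid$pi_)],
    t_first_sound = t_sound,
    t_first_emotion = t_emo,
    t_next = pmax(t_sound, t_emo) + exp(rnorm(nrow(grid), log(8), 0.4)),
    layout = layout[grid$pi_],
    sound_first = sound_first
  )
}

#' Split a ";"-separated label column into a list of label vectors
#'
#' @param x character vector as stored in `sound_names` / `emotion_names`.
#' @return list of character vectors (empty strings give zero-length
#'   vectors).
#' @export
split_labels <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
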