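#' Hierarchical model of first-name response latency
#'
#' Models log first-name latency with a Gaussian likelihood, fixed effects
#' for the naming kind (emotion vs. sound) and screen layout, and crossed
#' random intercepts for stimulus and participant. Latencies above
#' `rt_cutoff_s` (default 60 s, the conventional filter for unsupervised
#' online sessions) are removed before fitting. The key estimate is the
#' emotion-minus-sound latency contrast on the log scale, also
#' back-transformed to a milliseconds difference at the sound-name
#' baseline.
#'
#' @param trials naming-trial tibble with `t_first_sound`,
#'   `t_first_emotion`, `layout`, `participant`, `stimulus`.
#' @param response which latencies to model: `"both"` stacks the sound and
#'   emotion first-name latencies (needed for the kind contrast);
#'   `"first_sound"` / `"first_emotion"` model a single kind (no kind
#'   effect).
#' @param rt_cutoff_s latencies strictly greater than this are dropped.
#' @param n_draws,warmup sampler settings.
#' @param seed integer seed.
#' @return a `hierarchical_fit`; with `response = "both"` the fixed effect
#'   `kind_emotion` is the log-scale emotion-minus-sound contrast and
#'   `ms_difference` its back-transformed millisecond counterpart.
#' @export
fit_rt_model <- function(trials, response = c("both", "first_sound",
                                              "first_emotion"),
                         rt_cutoff_s = 60, n_draws = 1000, warmup = 500,
                         seed = 1) {
  response <- match.arg(response)
  need <- c("participant", "stimulus", "layout")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(trials, dplyr::all_of(need), "t_first_sound", "t_first_emotion"),
    cols = c("t_first_sound", "t_first_emotion"),
    names_to = "kind", values_to = "t", names_prefix = "t_first_"
  )
  long <- dplyr::filter(long, !is.na(.data$t), .data$t > 0,
                        .data$t <= rt_cutoff_s)
  if (response == "first_sound") long <- dplyr::filter(long, .data$kind == "sound")
  if (response == "first_emotion") long <- dplyr::filter(long, .data$kind == "emotion")
  if (nrow(long) == 0) abort("no latencies left after the cutoff filter")

  y <- log(long$t)
  X <- cbind(intercept = 1,
             layout_right = as.numeric(long$layout == "sound_right"))
  if (response == "both") {
    X <- cbind(X, kind_emotion = as.numeric(long$kind == "emotion"))
  }
  fit <- gibbs_gaussian_crossed(y, X, long$participant, long$stimulus,
                                n_draws = n_draws, warmup = warmup,
                                seed = seed)
  fixed <- lapply(seq_len(ncol(fit$beta)), function(j) fit$beta[, j])
  names(fixed) <- colnames(fit$beta)
  if (response == "both") {
    # ms difference at the sound-name baseline (mean over layouts)
    base <- exp(fit$beta[, "intercept"] +
                  0.5 * fit$beta[, "layout_right"])
    fixed$ms_difference <- 1000 * base * (exp(fit$beta[, "kind_emotion"]) - 1)
  }
  new_hierarchical_fit(
    fixed = fixed,
    sd_draws = list(participant = fit$sds[, "participant"],
                    stimulus = fit$sds[, "stimulus"],
                    residual = fit$sds[, "residual"]),
    model = paste0("log_rt_", response), n_obs = nrow(long)
  )
}
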