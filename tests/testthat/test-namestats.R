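test_that("normalized entropy matches the formula and its invariants", {
  expect_equal(normalized_entropy(c(5, 5, 5, 5)), 100)
  expect_equal(normalized_entropy(c(10, 0, 0, 0)), 0)
  expect_equal(normalized_entropy(c(3, 1)), entropy_oracle(c(3, 1), 2),
               tolerance = 1e-12)
  expect_equal(round(normalized_entropy(c(3, 1)), 2), 81.13)

  set.seed(1)
  for (i in 1:25) {
    n_alt <- sample(2:16, 1)
    a <- rpois(n_alt, 3)
    if (sum(a) == 0) a[1] <- 1
    e <- normalized_entropy(a)
    expect_gte(e, 0); expect_lte(e, 100)
    expect_equal(e, normalized_entropy(sample(a)))            # permutation
    expect_equal(e, normalized_entropy(a * 7))                # scale
    expect_equal(e == 100, all(a == a[1]) && all(a > 0))
    expect_equal(e == 0, sum(a > 0) == 1)
  }
  expect_error(normalized_entropy(c(0, 0, 0)), "all-zero")
  expect_error(normalized_entropy(c(-1, 2)), "nonnegative")
})

test_that("entropy contrast recovers a known paired difference", {
  x <- rnorm(132, 50, 10)
  fit0 <- entropy_contrast(x, x, seed = 1)
  ci0 <- tidy(fit0)[tidy(fit0)$term == "difference", ]
  expect_lte(ci0$conf.low, 0); expect_gte(ci0$conf.high, 0)
  d0 <- tidy(fit0)[tidy(fit0)$term == "cohens_d", ]
  expect_lt(abs(d0$mean), 0.05)

  for (seed in 1:3) {
    set.seed(seed)
    s <- rnorm(132, 45, 10)
    e <- s + rnorm(132, 10, 5)
    fit <- entropy_contrast(s, e, seed = seed)
    est <- tidy(fit)$mean[tidy(fit)$term == "difference"]
    expect_gt(est, 8); expect_lt(est, 12)
  }
  expect_error(entropy_contrast(1:2, 1:2), "at least 3")
  expect_error(entropy_contrast(1:5, 1:4), "paired")
})

test_that("log-latency model recovers the simulated naming-kind offset", {
  w <- fixture_world()
  lex <- make_lexicon(w, "english")
  p <- default_gen_params(rt_location_emotion = log(5) + 0.2)
  tr <- simulate_naming(w, lex, 50, p, seed = 7)
  fit <- fit_rt_model(tr, n_draws = 800, warmup = 400, seed = 1)
  kt <- tidy(fit)[tidy(fit)$term == "kind_emotion", ]
  expect_lt(abs(kt$mean - 0.2), 0.05)
  expect_gt(tidy(fit)$mean[tidy(fit)$term == "ms_difference"], 0)
  sds <- tidy(fit, "ran_pars")
  expect_lt(abs(sds$mean[sds$term == "participant"] - 0.3), 0.1)
  expect_lt(abs(sds$mean[sds$term == "residual"] - 0.5), 0.05)
})

test_that("latency filtering and grouping contracts are enforced", {
  tr <- make_trials(c("s1", "s2"), c("laugh", "cry"))
  tr$t_first_sound <- c(100, 120)
  tr$t_first_emotion <- c(90, 130)
  expect_error(fit_rt_model(tr), "no latencies")
  base <- fixture_naming()
  tr2 <- base[base$participant %in% unique(base$participant)[1:2] &
                base$stimulus %in% unique(base$stimulus)[1:20], ]
  tr2$t_first_sound[1] <- 200          # above cutoff: dropped, not modeled
  fit <- fit_rt_model(tr2, n_draws = 50, warmup = 50, seed = 1)
  expect_equal(fit$n_obs, 79)
})

test_that("certainty model flags invalid codes and recovers effect sign", {
  tr <- fixture_naming()
  bad <- tr[1:10, ]
  bad$certainty_sound[2] <- 4L
  expect_error(fit_certainty_model(bad), "\\{1, 2, 3\\}")

  # simulate a latent sound-kind advantage and check the recovered sign
  w <- make_world(40, 3, 2, character(0), seed = 2)
  lex <- make_lexicon(w, "english")
  signs <- vapply(1:3, function(seed) {
    p <- default_gen_params(dim = 2, certainty_cuts = c(-4, -1))
    trs <- simulate_naming(w, lex, 12, p, seed = seed)
    # emotion certainty forced lower by a latent shift
    shift_down <- rbinom(nrow(trs), 1, 0.35) == 1
    trs$certainty_emotion <- pmax(1L, trs$certainty_emotion -
                                    as.integer(shift_down))
    fit <- fit_certainty_model(trs, n_draws = 300, warmup = 300, seed = seed)
    tidy(fit)$mean[tidy(fit)$term == "kind_sound"]
  }, double(1))
  expect_true(all(signs > 0))
})

test_that("certainty model reports per-category probabilities", {
  tr <- fixture_naming()[1:600, ]
  fit <- fit_certainty_model(tr, n_draws = 200, warmup = 200, seed = 1)
  probs <- fit$category_probs
  expect_setequal(unique(probs$kind), c("sound", "emotion"))
  sums <- tapply(probs$probability, probs$kind, sum)
  expect_equal(as.vector(sums), c(1, 1), tolerance = 1e-6)
})

test_that("order preference covers the null under pure layout behaviour", {
  set.seed(5)
  n_part <- 40; n_trial <- 60
  layout <- rep(c("sound_left", "sound_right"), each = n_part / 2)
  df <- tidyr::expand_grid(p = seq_len(n_part), t = seq_len(n_trial))
  df$layout <- layout[df$p]
  x <- ifelse(df$layout == "sound_left", 1, -1)
  df_tr <- tibble::tibble(
    participant = sprintf("p%02d", df$p),
    layout = df$layout,
    sound_first = runif(nrow(df)) < plogis(2.5 * x)   # no intrinsic preference
  )
  fit <- order_preference(df_tr, n_draws = 400, warmup = 400, seed = 1)
  or <- tidy(fit)[tidy(fit)$term == "odds_ratio", ]
  expect_lte(or$conf.low, 1); expect_gte(or$conf.high, 1)
})

test_that("order preference recovers a true odds ratio of 5", {
  set.seed(6)
  n_part <- 50; n_trial <- 100
  layout <- rep(c("sound_left", "sound_right"), length.out = n_part)
  df <- tidyr::expand_grid(p = seq_len(n_part), t = seq_len(n_trial))
  df$layout <- layout[df$p]
  x <- ifelse(df$layout == "sound_left", 1, -1)
  pref <- log(5) / 2
  df_tr <- tibble::tibble(
    participant = sprintf("p%02d", df$p),
    layout = df$layout,
    sound_first = runif(nrow(df)) < plogis(pref + 2 * x)
  )
  fit <- order_preference(df_tr, n_draws = 500, warmup = 500, seed = 2)
  or_med <- tidy(fit)$median[tidy(fit)$term == "odds_ratio"]
  expect_gt(or_med, 3.5); expect_lt(or_med, 7)
})

test_that("order preference requires both layouts and layout data", {
  tr <- make_trials(c("s1", "s2"), c("laugh", "cry"))
  expect_error(order_preference(tr), "one layout")
  tr$layout <- c("sound_left", NA)
  expect_error(order_preference(tr), "layout")
})

test_that("contingency table counts label pairs and matches chi-square", {
  labs_s <- c("laugh", "cry")
  labs_e <- c("joy", "sadness")
  tr <- make_trials(
    stimulus = sprintf("s%02d", 1:20),
    sound = rep(c("laugh", "cry"), each = 10),
    emotion = rep(c("joy", "sadness"), each = 10)
  )
  res <- sound_emotion_contingency(tr, labs_s, labs_e)
  expect_equal(unname(res$table), rbind(c(10, 0), c(0, 10)))
  expect_equal(res$chi_square, 20)   # hand: sum (O-E)^2/E with E = 5
  expect_equal(res$df, 1)

  tr_unif <- make_trials(
    stimulus = sprintf("s%02d", 1:20),
    sound = rep(c("laugh", "cry"), 10),
    emotion = rep(c("joy", "joy", "sadness", "sadness"), 5)
  )
  res_u <- sound_emotion_contingency(tr_unif, labs_s, labs_e)
  expect_equal(res_u$chi_square, 0)

  # multi-label trials contribute one count per label pair
  tr_ml <- make_trials("s1", "laugh;cry", "joy")
  res_ml <- sound_emotion_contingency(tr_ml, labs_s, labs_e)
  expect_equal(unname(res_ml$table[, "joy"]), c(1, 1))
})

test_that("contingency chi-square equals the closed form on 2x2 tables", {
  set.seed(9)
  for (i in 1:5) {
    counts <- matrix(rpois(4, 15) + 1, 2,
                     dimnames = list(c("laugh", "cry"), c("joy", "sadness")))
    sounds <- rep(rep(rownames(counts), 2), as.vector(counts))
    emotions <- rep(rep(colnames(counts), each = 2), as.vector(counts))
    tr <- make_trials(sprintf("s%03d", seq_along(sounds)), sounds, emotions)
    res <- sound_emotion_contingency(tr, rownames(counts), colnames(counts))
    o <- res$table
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(res$table, counts + 0)
    expect_equal(res$chi_square, sum((o - e)^2 / e), tolerance = 1e-10)
  }
})

test_that("full contingency table has the lexicon dimensions", {
  tr <- fixture_naming()
  lex <- fixture_lexicon()
  res <- sound_emotion_contingency(tr, lex$sound_labels, lex$emotion_labels)
  expect_equal(dim(res$table), c(16, 16))
  expect_equal(res$df, (16 - 1) * (16 - 1))
  expect_lt(res$p_value, 1e-15)
})

test_that("emotion-from-name classifier is perfect for a 1-to-1 mapping", {
  labs_s <- c("laugh", "cry", "scream")
  tr <- make_trials(
    stimulus = sprintf("s%02d", 1:60),
    sound = rep(labs_s, 20),
    emotion = rep(c("joy", "sadness", "fear"), 20)
  )
  res <- emotion_from_name_accuracy(tr, labs_s, seed = 1)
  expect_equal(res$accuracy, 1)
})

test_that("emotion-from-name accuracy collapses to baseline under shuffling", {
  tr <- fixture_naming()
  lex <- fixture_lexicon()
  set.seed(21)
  tr$emotion_names <- sample(tr$emotion_names)
  res <- emotion_from_name_accuracy(tr, lex$sound_labels, seed = 2)
  expect_lt(abs(res$accuracy - res$majority_baseline), 0.05)
})

test_that("emotion-from-name classifier contracts", {
  tr1 <- make_trials(sprintf("s%d", 1:6), rep("laugh", 6), rep("joy", 6))
  expect_error(emotion_from_name_accuracy(tr1, "laugh"), "2 emotion classes")
  tr2 <- make_trials(sprintf("s%d", 1:8),
                     rep(c("laugh", "cry"), 4),
                     c(rep("joy", 6), "sadness", "sadness"))
  expect_warning(emotion_from_name_accuracy(tr2, c("laugh", "cry"), cv_folds = 5,
                                            seed = 1),
                 "reducing folds")
})
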