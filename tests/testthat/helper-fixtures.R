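# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# small cached default-scale world + english naming data (built once)
fixture_env <- new.env()

fixture_world <- function() {
  if (is.null(fixture_env$world)) fixture_env$world <- make_world(seed = 1)
  fixture_env$world
}

fixture_naming <- function() {
  if (is.null(fixture_env$naming)) {
    w <- fixture_world()
    lex <- make_lexicon(w, "english")
    fixture_env$lexicon <- lex
    fixture_env$naming <- simulate_naming(w, lex, 20, seed = 1)
  }
  fixture_env$naming
}

fixture_lexicon <- function() {
  fixture_naming()
  fixture_env$lexicon
}

# build a naming-trial tibble from per-trial label strings
make_trials <- function(stimulus, sound, emotion = NULL,
                        participant = NULL, layout = NULL) {
  n <- length(stimulus)
  tibble::tibble(
    participant = participant %||% sprintf("p%02d", seq_len(n)),
    language = "english",
    stimulus = stimulus,
    sound_names = sound,
    emotion_names = emotion %||% rep("joy", n),
    certainty_sound = 3L, certainty_emotion = 3L,
    t_first_sound = 2, t_first_emotion = 3, t_next = 8,
    layout = layout %||% rep("sound_left", n),
    sound_first = TRUE
  )
}

# brute-force affinity-propagation oracle: maximise net similarity
# sum_i s(i, exemplar(i)) over all nonempty exemplar subsets, with
# s(k, k) = preference for exemplars
bf_best_net_similarity <- function(d, q) {
  s <- -d^2
  off <- s[row(s) != col(s)]
  pref <- as.numeric(quantile(off, q, names = FALSE, type = 7))
  diag(s) <- pref
  n <- nrow(s)
  best <- -Inf
  best_k <- NA_integer_
  for (mask in seq_len(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    net <- sum(apply(s[, ex, drop = FALSE], 1, max)[-ex]) + sum(s[cbind(ex, ex)])
    if (net > best) { best <- net; best_k <- length(ex) }
  }
  list(net = best, n_exemplars = best_k)
}

# independent direct evaluation of the normalized-entropy formula
entropy_oracle <- function(a, n_alt) {
  p <- a / sum(a)
  terms <- ifelse(p > 0, log2(p) * p, 0)
  -sum(terms) / log2(n_alt) * 100
}

# pair-counting ARI oracle (O(n^2) over item pairs)
ari_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  tot <- n11 + n10 + n01 + n00
  exp_idx <- (n11 + n10) * (n11 + n01) / tot
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == exp_idx) return(1)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# direct silhouette oracle with explicit loops
silhouette_oracle <- function(d, cl) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g])
    }, double(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# direct WAIC oracle from the defining formula
waic_oracle <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(colMeans(sweep(ll, 2, colMeans(ll))^2))
  list(waic = -2 * (lppd - p), lppd = lppd, p_waic = p)
}

expect_distance_matrix <- function(d) {
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
}
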