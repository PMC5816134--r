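test_that("make_world honours its shape contract and is deterministic", {
  w <- make_world(132, 6, 3, c("laugh", "cry"), spread = 1, separation = 4,
                  seed = 1)
  expect_equal(nrow(w$latent_coords), 132)
  expect_equal(nrow(w$type_centers), 6)
  expect_equal(ncol(w$latent_coords), 3)
  expect_setequal(unique(w$stimuli$true_type), rownames(w$type_centers))
  expect_true(all(is.finite(w$latent_coords)))
  expect_true(all(w$stimuli$context_category %in% c(
    "amusement", "anger", "disgust", "effort", "fear", "joy", "pain",
    "pleasure", "sadness")))

  w2 <- make_world(132, 6, 3, c("laugh", "cry"), spread = 1, separation = 4,
                   seed = 7)
  w3 <- make_world(132, 6, 3, c("laugh", "cry"), spread = 1, separation = 4,
                   seed = 7)
  expect_identical(w2$latent_coords, w3$latent_coords)
  expect_identical(w2$stimuli, w3$stimuli)

  expect_error(make_world(spread = 0), "positive")
  expect_error(make_world(separation = -1), "positive")
  expect_error(make_world(n_stimuli = 3, n_types = 6), "at least")
})

test_that("compact types are tighter than the global point cloud", {
  w <- fixture_world()
  d <- as.matrix(dist(w$latent_coords))
  global_mean <- mean(d[upper.tri(d)])
  for (tt in w$compact_types) {
    idx <- which(w$stimuli$true_type == tt)
    sub <- d[idx, idx]
    expect_lt(mean(sub[upper.tri(sub)]), global_mean)
  }
})

test_that("well-separated worlds have silhouette > 0.5 on latent distances", {
  w <- make_world(60, 6, 3, c("laugh", "cry"), spread = 0.5, separation = 10,
                  seed = 3)
  d <- as.matrix(dist(w$latent_coords))
  sil <- silhouette_index(d, setNames(w$stimuli$true_type,
                                      w$stimuli$stimulus))
  expect_gt(sil, 0.5)
})

test_that("naming simulator hits the argmax limit at low temperature", {
  w <- make_world(30, 3, 2, character(0), seed = 5)
  lex <- make_lexicon(w, "english")
  p <- default_gen_params(dim = 2, naming_temperature = 1e-4)
  tr <- simulate_naming(w, lex, 10, p, seed = 2)
  # nearest-prototype label per stimulus
  d <- as.matrix(dist(rbind(w$latent_coords, lex$sound_prototypes)))
  d <- d[seq_len(30), -seq_len(30)]
  nearest <- lex$sound_labels[apply(d, 1, which.min)]
  primary <- vapply(split_labels(tr$sound_names), `[`, character(1), 1)
  expect_identical(primary, nearest[match(tr$stimulus,
                                          rownames(w$latent_coords))])
})

test_that("naming entropy approaches 100% at high temperature and is monotone", {
  w <- make_world(20, 3, 2, character(0), seed = 6)
  lex <- make_lexicon(w, "english")
  ents <- vapply(c(0.3, 1, 5, 1e3), function(tau) {
    p <- default_gen_params(dim = 2, naming_temperature = tau)
    tr <- simulate_naming(w, lex, 40, p, seed = 11)
    mean(naming_entropies(tr, lex$sound_labels,
                          lex$emotion_labels)$entropy_sound)
  }, double(1))
  expect_true(all(diff(ents) > -2))    # non-decreasing up to sampling noise
  expect_gt(ents[4], 95)
})

test_that("latency offset between emotion and sound naming is recovered", {
  w <- fixture_world()
  lex <- make_lexicon(w, "english")
  p <- default_gen_params(rt_location_sound = log(5),
                          rt_location_emotion = log(5) + 0.2)
  tr <- simulate_naming(w, lex, 50, p, seed = 4)
  diff_log <- mean(log(tr$t_first_emotion)) - mean(log(tr$t_first_sound))
  expect_lt(abs(diff_log - 0.2), 0.03)
})

test_that("naming simulator contracts: empty, mismatched dims, layout balance", {
  w <- make_world(10, 2, 2, character(0), seed = 8)
  lex <- make_lexicon(w, "english")
  expect_equal(nrow(simulate_naming(w, lex, 0, default_gen_params(2))), 0)
  w3 <- make_world(10, 2, 3, character(0), seed = 8)
  expect_error(simulate_naming(w3, lex, 5, default_gen_params(3)), "dimension")
  tr <- simulate_naming(w, lex, 4, default_gen_params(2), seed = 1)
  expect_setequal(unique(tr$layout), c("sound_left", "sound_right"))
})

test_that("acoustic simulator is an exact linear image without noise", {
  w <- make_world(40, 4, 3, character(0), seed = 9)
  # orthogonal loading columns: feature distances proportional to latent ones
  L <- matrix(0, 12, 3)
  L[1:3, ] <- diag(3) * 2
  rownames(L) <- paste0("f", 1:12)
  p <- default_gen_params(acoustic_loadings = L, acoustic_noise_sd = 0,
                          n_distractor_features = 0)
  ac <- simulate_acoustics(w, p, seed = 1)
  d_feat <- as.matrix(dist(as.matrix(ac[, -1])))
  d_lat <- as.matrix(dist(w$latent_coords))
  expect_equal(cor(d_feat[upper.tri(d_feat)], d_lat[upper.tri(d_lat)]), 1,
               tolerance = 1e-12)
})

test_that("acoustic distractors are uncorrelated with the latent space", {
  w <- fixture_world()
  p <- default_gen_params(n_distractor_features = 8)
  ac <- simulate_acoustics(w, p, seed = 2)
  for (j in paste0("distractor", 1:8)) {
    rs <- abs(cor(ac[[j]], w$latent_coords))
    expect_true(all(rs < 0.25))
  }
  ac2 <- simulate_acoustics(w, p, seed = 2)
  expect_identical(ac, ac2)
  expect_error(simulate_acoustics(
    w, default_gen_params(acoustic_noise_sd = -1)), "nonnegative")
})

test_that("triad simulator follows the softmax choice law", {
  # equilateral triple: all pairs equally likely
  X <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  rownames(X) <- c("a", "b", "c")
  tr <- simulate_triads(X, 200, 50, 1, seed = 1)   # 10,000 draws
  pair_key <- paste(pmin(tr$chosen1, tr$chosen2),
                    pmax(tr$chosen1, tr$chosen2))
  freq <- table(pair_key) / nrow(tr)
  expect_equal(length(freq), 3)
  expect_true(all(abs(freq - 1 / 3) < 0.02))

  # distances (1, 2, 3): probabilities from the softmax over -d
  Y <- cbind(c(0, 1, 3), 0)
  rownames(Y) <- c("a", "b", "c")   # d_ab = 1, d_ac = 3, d_bc = 2
  tr2 <- simulate_triads(Y, 200, 50, 1, seed = 2)
  key2 <- paste(pmin(tr2$chosen1, tr2$chosen2), pmax(tr2$chosen1, tr2$chosen2))
  p_hat <- c(mean(key2 == "a b"), mean(key2 == "b c"), mean(key2 == "a c"))
  p_exp <- exp(-c(1, 2, 3)) / sum(exp(-c(1, 2, 3)))
  expect_true(all(abs(p_hat - p_exp) < 0.02))

  # temperature -> 0: always the closest pair
  tr3 <- simulate_triads(Y, 50, 20, 1e-6, seed = 3)
  expect_true(all(paste(pmin(tr3$chosen1, tr3$chosen2),
                        pmax(tr3$chosen1, tr3$chosen2)) == "a b"))

  expect_error(simulate_triads(X[1:2, , drop = FALSE], 5, 5, 1), "at least 3")
})

test_that("every stimulus is covered when triads are plentiful", {
  w <- make_world(30, 3, 2, character(0), seed = 4)
  tr <- simulate_triads(w, n_participants = 2, triads_per_participant = 10,
                        seed = 5)
  expect_setequal(unique(c(tr$item1, tr$item2, tr$item3)),
                  rownames(w$latent_coords))
})

test_that("worlds round-trip through JSON", {
  w <- make_world(12, 3, 2, "laugh", seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_world_json(w, path)
  w2 <- read_world_json(path)
  expect_equal(w2$latent_coords, w$latent_coords)
  expect_equal(w2$type_centers, w$type_centers)
  expect_equal(w2$stimuli, w$stimuli)
  expect_equal(w2$compact_types, w$compact_types)
})
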