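#' Simulate an acoustic feature table with known latent alignment
#'
#' Informative features are linear images of the latent perceptual
#' coordinates (`latent_coords %*% t(acoustic_loadings)`) plus Gaussian
#' measurement noise; `n_distractor_features` additional columns are pure
#' standard-normal noise with no relation to the latent space. With the
#' default loadings the table has the twelve conventional acoustic
#' variables (amplitude and pitch medians/SDs, spectral quartile and
#' entropy measures, burst and syllable statistics).
#'
#' @param world a [make_world()] object.
#' @param params a [default_gen_params()] list; uses `acoustic_loadings`,
#'   `acoustic_noise_sd`, `n_distractor_features`.
#' @param seed integer seed.
#' @return tibble with a `stimulus` id column followed by one numeric
#'   column per feature (distractors named `distractor1`, ...).
#' @export
simulate_acoustics <- function(world, params = default_gen_params(world$dim),
                               seed = 1) {
  stopifnot(inherits(world, "vocal_world"))
  loadings <- params$acoustic_loadings
  if (ncol(loadings) != world$dim) {
    abort("acoustic_loadings columns must match the world dimension")
  }
  if (params$acoustic_noise_sd < 0) abort("acoustic_noise_sd must be >= 0")
  n_distract <- check_count(params$n_distractor_features,
                            "n_distractor_features", min = 0L)

  withr::local_seed(derive_seed(seed, 3L))
  coords <- world$latent_coords
  n <- nrow(coords)
  signal <- coords %*% t(loadings)
  noise <- matrix(rnorm(n * nrow(loadings), 0, params$acoustic_noise_sd),
                  n, nrow(loadings))
  values <- signal + noise
  colnames(values) <- rownames(loadings)
  if (n_distract > 0) {
    extra <- matrix(rnorm(n * n_distract), n, n_distract)
    colnames(extra) <- paste0("distractor", seq_len(n_distract))
    values <- cbind(values, extra)
  }
  dplyr::bind_cols(
    tibble::tibble(stimulus = rownames(coords)),
    tibble::as_tibble(values)
  )
}

#' Simulate triad similarity judgments from latent coordinates
#'
#' For each participant, random triples of distinct stimuli are drawn and a
#' pair is chosen from the same softmax choice law the embedding model
#' assumes (see [triad_choice_prob()]): the pair with the smallest distance
#' is the most likely choice, with `triad_temperature` controlling
#' decisiveness.
#'
#' @param coords stimulus x dim coordinate matrix with row names, or a
#'   `vocal_world` (its latent coordinates are used).
#' @param n_participants number of simulated participants.
#' @param triads_per_participant triads presented to each participant.
#' @param triad_temperature positive softmax temperature.
#' @param seed integer seed.
#' @return tibble of triad trials: `participant`, `item1`, `item2`, `item3`,
#'   `chosen1`, `chosen2` (the chosen pair, a subset of the items).
#' @export
simulate_triads <- function(coords, n_participants = 150,
                            triads_per_participant = 42,
                            triad_temperature = 1, seed = 1) {
  if (inherits(coords, "vocal_world")) coords <- coords$latent_coords
  stopifnot(is.matrix(coords))
  if (nrow(coords) < 3) abort("need at least 3 stimuli to form triads")
  triad_temperature <- check_positive(triad_temperature, "triad_temperature")
  n_participants <- check_count(n_participants, "n_participants", min = 0L)
  triads_per_participant <- check_count(triads_per_participant,
                                        "triads_per_participant")
  ids <- rownames(coords)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(coords)))

  withr::local_seed(derive_seed(seed, 4L))
  n <- nrow(coords)
  dmat <- coords_to_distances(coords)
  n_total <- n_participants * triads_per_participant
  if (n_total == 0L) {
    return(tibble::tibble(participant = character(), item1 = character(),
                          item2 = character(), item3 = character(),
                          chosen1 = character(), chosen2 = character()))
  }

  # each participant cycles through a fresh random order of stimuli so all
  # stimuli are covered whenever 3 * triads_per_participant >= n
  items <- matrix(0L, n_total, 3)
  row <- 1L
  for (p in seq_len(n_participants)) {
    need <- triads_per_participant * 3L
    pool <- integer(0)
    while (length(pool) < need) pool <- c(pool, sample.int(n))
    for (tr in seq_len(triads_per_participant)) {
      cand <- pool[(3 * tr - 2):(3 * tr)]
      while (anyDuplicated(cand)) {          # guard at cycle boundaries
        cand <- sample.int(n, 3)
      }
      items[row, ] <- cand
      row <- row + 1L
    }
  }

  d12 <- dmat[cbind(items[, 1], items[, 2])]
  d13 <- dmat[cbind(items[, 1], items[, 3])]
  d23 <- dmat[cbind(items[, 2], items[, 3])]
  p <- triad_choice_prob(d12, d13, d23, triad_temperature)
  u <- runif(n_total)
  choice <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])

  pair_a <- c(1L, 1L, 2L)
  pair_b <- c(2L, 3L, 3L)
  tibble::tibble(
    participant = rep(sprintf("t_p%03d", seq_len(n_participants)),
                      each = triads_per_participant),
    item1 = ids[items[, 1]], item2 = ids[items[, 2]], item3 = ids[items[, 3]],
    chosen1 = ids[items[cbind(seq_len(n_total), pair_a[choice])]],
    chosen2 = ids[items[cbind(seq_len(n_total), pair_b[choice])]]
  )
}
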