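# Canonical call types and context categories used by the default generator.
# Six graded call types, two of which (laugh, cry) form compact clusters in
# perceptual space; nine contextual-emotional categories for the stimuli.
CALL_TYPES <- c("laugh", "cry", "scream", "moan", "sigh", "roar")
CONTEXT_CATEGORIES <- c("amusement", "anger", "disgust", "effort", "fear",
                        "joy", "pain", "pleasure", "sadness")

# P(context | call type): rows = call types, cols = the nine contexts.
# Laughter and crying map onto narrow emotional ranges; screams, moans and
# roars are emotionally ambiguous, mirroring the graded middle of the
# repertoire.
type_context_probs <- function(types) {
  base <- rbind(
    laugh  = c(amusement = .60, anger = 0,   disgust = .02, effort = 0,
               fear = 0,   joy = .35, pain = 0,   pleasure = .03, sadness = 0),
    cry    = c(amusement = 0,   anger = .02, disgust = 0,   effort = 0,
               fear = .05, joy = 0,   pain = .13, pleasure = 0,   sadness = .80),
    scream = c(amusement = .05, anger = .15, disgust = .05, effort = 0,
               fear = .45, joy = .10, pain = .20, pleasure = 0,   sadness = 0),
    moan   = c(amusement = 0,   anger = .05, disgust = .15, effort = .10,
               fear = .05, joy = 0,   pain = .30, pleasure = .30, sadness = .05),
    sigh   = c(amusement = .02, anger = .05, disgust = .08, effort = .25,
               fear = .10, joy = .05, pain = .10, pleasure = .20, sadness = .15),
    roar   = c(amusement = .05, anger = .50, disgust = .05, effort = .30,
               fear = .05, joy = .05, pain = 0,   pleasure = 0,   sadness = 0)
  )
  extra <- setdiff(types, rownames(base))
  if (length(extra)) {
    # unseen types get a flat context distribution
    flat <- matrix(1 / 9, length(extra), 9,
                   dimnames = list(extra, CONTEXT_CATEGORIES))
    base <- rbind(base, flat)
  }
  base[types, , drop = FALSE]
}

#' Generate a ground-truth perceptual world
#'
#' Draws a Gaussian-mixture configuration of stimuli in a latent perceptual
#' space: each call type gets a centre, and stimuli scatter around their
#' type's centre. Types listed in `compact_types` use one fifth of the
#' within-type spread, producing the compact, well-separated clusters that
#' laughs and cries form in perceptual data, while the remaining types stay
#' graded. Every stimulus also receives one of nine contextual-emotional
#' categories, drawn from a type-specific distribution.
#'
#' @param n_stimuli number of stimuli (default 132).
#' @param n_types number of call types (>= 2; up to 6 canonical names).
#' @param dim latent dimensionality (>= 2; default 3).
#' @param compact_types character vector of type names generated with small
#'   within-type spread (default `c("laugh", "cry")`).
#' @param spread within-type standard deviation for graded types (> 0).
#' @param separation minimum distance between type centres (> 0).
#' @param seed integer seed; identical seeds give identical worlds.
#' @return A `vocal_world` object: a list with `stimuli` (tibble of
#'   `stimulus`, `true_type`, `context_category`), `latent_coords`
#'   (n_stimuli x dim matrix), `type_centers`, `compact_types`, `dim`,
#'   `spread`, `separation` and `seed`.
#' @examples
#' w <- make_world(n_stimuli = 30, n_types = 3, dim = 2, seed = 1)
#' table(w$stimuli$true_type)
#' @export
make_world <- function(n_stimuli = 132, n_types = 6, dim = 3,
                       compact_types = c("laugh", "cry"),
                       spread = 1, separation = 3, seed = 1) {
  n_stimuli <- check_count(n_stimuli, "n_stimuli")
  n_types <- check_count(n_types, "n_types", min = 2L)
  dim <- check_count(dim, "dim", min = 2L)
  spread <- check_positive(spread, "spread")
  separation <- check_positive(separation, "separation")
  if (n_stimuli < n_types) abort("`n_stimuli` must be at least `n_types`")

  types <- if (n_types <= length(CALL_TYPES)) {
    CALL_TYPES[seq_len(n_types)]
  } else {
    c(CALL_TYPES, paste0("type", seq_len(n_types - length(CALL_TYPES))))
  }
  compact_types <- intersect(compact_types, types)

  withr::local_seed(derive_seed(seed, 1L))

  # type centres: isotropic Gaussian directions rescaled so the smallest
  # pairwise centre distance equals `separation` — guarantees that no two
  # call types coincide, whatever the seed
  centers <- matrix(rnorm(n_types * dim), n_types, dim)
  centers <- scale(centers, center = TRUE, scale = FALSE)
  min_d <- min(dist(centers))
  centers <- centers * (separation / min_d)
  attributes(centers) <- attributes(centers)[c("dim")]
  rownames(centers) <- types

  true_type <- rep(types, length.out = n_stimuli)
  type_sd <- ifelse(true_type %in% compact_types, spread / 5, spread)
  coords <- centers[true_type, , drop = FALSE] +
    matrix(rnorm(n_stimuli * dim), n_stimuli, dim) * type_sd
  ids <- sprintf("s%03d", seq_len(n_stimuli))
  rownames(coords) <- ids

  ctx_probs <- type_context_probs(types)
  context <- vapply(true_type, function(tt) {
    sample(CONTEXT_CATEGORIES, 1L, prob = ctx_probs[tt, ])
  }, character(1), USE.NAMES = FALSE)

  structure(
    list(
      stimuli = tibble::tibble(stimulus = ids, true_type = true_type,
                               context_category = context),
      latent_coords = coords,
      type_centers = centers,
      compact_types = compact_types,
      dim = dim, spread = spread, separation = separation, seed = seed
    ),
    class = "vocal_world"
  )
}

#' @export
print.vocal_world <- function(x, ...) {
  cat(sprintf(
    "<vocal_world> %d stimuli, %d call types (%s compact), dim %d, seed %d\n",
    nrow(x$latent_coords), nrow(x$type_centers),
    if (length(x$compact_types)) paste(x$compact_types, collapse = "/") else "none",
    x$dim, x$seed
  ))
  invisible(x)
}

#' Write / read a world as JSON
#'
#' Round-trips a [make_world()] object through JSON (coordinates as nested
#' arrays) so ground truths can be stored alongside simulated datasets.
#'
#' @param world a `vocal_world` object.
#' @param path file path.
#' @return `read_world_json()` returns a `vocal_world`; `write_world_json()`
#'   returns `path` invisibly.
#' @export
write_world_json <- function(world, path) {
  stopifnot(inherits(world, "vocal_world"))
  out <- list(
    stimuli = world$stimuli,
    latent_coords = unname(apply(world$latent_coords, 1, identity,
                                 simplify = FALSE)),
    type_centers = unname(apply(world$type_centers, 1, identity,
                                simplify = FALSE)),
    type_names = rownames(world$type_centers),
    compact_types = world$compact_types,
    dim = world$dim, spread = world$spread,
    separation = world$separation, seed = world$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_world_json
#' @export
read_world_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  }
  coords <- as_mat(raw$latent_coords)
  centers <- as_mat(raw$type_centers)
  rownames(coords) <- raw$stimuli$stimulus
  rownames(centers) <- raw$type_names
  structure(
    list(
      stimuli = tibble::as_tibble(raw$stimuli),
      latent_coords = coords,
      type_centers = centers,
      compact_types = as.character(raw$compact_types),
      dim = raw$dim, spread = raw$spread,
      separation = raw$separation, seed = raw$seed
    ),
    class = "vocal_world"
  )
}
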