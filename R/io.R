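# All tables are UTF-8 comma-separated CSV with a header row and "."
# decimals; stimulus ids are opaque strings and every matrix carries
# explicit id headers (no positional coupling).

#' Read / write trial and feature tables
#'
#' CSV round-trips for the three table kinds the pipeline consumes:
#' naming trials, triad trials and acoustic features. Writers emit the
#' documented column layout; readers enforce it.
#'
#' @param trials,table tibble to write.
#' @param path file path.
#' @return readers return tibbles; writers return `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_naming_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_naming_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant = readr::col_character(),
                    language = readr::col_character(),
                    stimulus = readr::col_character(),
                    sound_names = readr::col_character(),
                    emotion_names = readr::col_character(),
                    certainty_sound = readr::col_integer(),
                    certainty_emotion = readr::col_integer(),
                    t_first_sound = readr::col_double(),
                    t_first_emotion = readr::col_double(),
                    t_next = readr::col_double(),
                    layout = readr::col_character(),
                    .default = readr::col_guess()
                  ))
}

#' @rdname table_io
#' @export
write_triads_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_triads_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname table_io
#' @export
write_acoustics_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_acoustics_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           stimulus = readr::col_character(),
                           .default = readr::col_double()
                         ))
  out
}

#' Read / write a distance matrix as square CSV
#'
#' The first column (`stimulus`) holds row ids; the remaining column
#' names repeat the ids in the same order.
#'
#' @param d distance matrix with dimnames.
#' @param path file path.
#' @return `read_distance_csv()` returns a validated distance matrix.
#' @export
write_distance_csv <- function(d, path) {
  validate_distance_matrix(d)
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  df <- dplyr::bind_cols(tibble::tibble(stimulus = ids),
                         tibble::as_tibble(d, .name_repair = "minimal"))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          stimulus = readr::col_character(),
                          .default = readr::col_double()
                        ))
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(df$stimulus, colnames(df)[-1])
  if (!identical(rownames(m), colnames(m))) {
    abort("distance CSV row ids and column headers disagree")
  }
  validate_distance_matrix(m)
  m
}

#' Write an embedding's coordinates as CSV
#'
#' @param embedding a [embed_space()] or [acoustic_pca()] object.
#' @param path file path.
#' @export
write_embedding_csv <- function(embedding, path) {
  coords <- if (inherits(embedding, "acoustic_embedding")) {
    embedding$pc_scores
  } else {
    embedding$coords
  }
  df <- dplyr::bind_cols(tibble::tibble(stimulus = rownames(coords)),
                         tibble::as_tibble(coords))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read per-language label lists from a JSON config
#'
#' The config maps language names to objects with `sound_labels` and
#' `emotion_labels` arrays.
#'
#' @param path JSON file path.
#' @return named list per language, each with `sound_labels` and
#'   `emotion_labels` character vectors.
#' @export
read_labels_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) {
    if (is.null(x$sound_labels) || is.null(x$emotion_labels)) {
      abort("each language needs `sound_labels` and `emotion_labels`")
    }
    list(sound_labels = as.character(x$sound_labels),
         emotion_labels = as.character(x$emotion_labels))
  })
}

#' Write posterior summaries of a fitted model as JSON
#'
#' Serialises the fixed-effect and random-effect-sd summary tables of a
#' `hierarchical_fit` (posterior means, medians, 95% intervals, ESS).
#'
#' @param fit a `hierarchical_fit` object.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hierarchical_fit"))
  jsonlite::write_json(
    list(model = fit$model, n_obs = fit$n_obs,
         fixed_effects = fit$fixed_effects,
         random_effect_sds = fit$random_effect_sds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write learned metric weights as JSON
#'
#' @param weights a [optimize_weights()] result.
#' @param path file path.
#' @export
write_weights_json <- function(weights, path) {
  stopifnot(inherits(weights, "metric_weights"))
  jsonlite::write_json(
    list(weights = weights$weights,
         achieved_correlation = weights$achieved_correlation,
         uniform_correlation = weights$uniform_correlation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
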