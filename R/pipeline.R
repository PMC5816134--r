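#' Pipeline configuration
#'
#' Builds the configuration consumed by [validate_and_load()] and
#' [run_pipeline()]. Either `synthetic` (a list of generator settings) or
#' explicit input `paths` must be provided, never neither. Every
#' stochastic stage derives its stream from the single `seed`.
#'
#' @param synthetic list of generator settings: `n_stimuli`, `n_types`,
#'   `dim`, `languages`, `n_participants` (naming participants per
#'   language), `triad_participants`, `triads_per_participant`, plus
#'   overrides passed to [default_gen_params()].
#' @param paths list with `naming` (named character vector of CSV paths
#'   per language), `acoustics`, `triads`.
#' @param stages character subset of
#'   `c("semspace", "namestats", "acoustic", "triad")`.
#' @param seed integer master seed.
#' @param out_dir output directory (created on demand); `NULL` disables
#'   file output.
#' @param sampler list of reduced-or-full sampler sizes: `n_draws`,
#'   `warmup`, `triad_config` (an [embedding_config()]), `d_values`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            stages = c("semspace", "namestats", "acoustic",
                                       "triad"),
                            seed = 1, out_dir = NULL, sampler = list()) {
  if (is.null(synthetic) && is.null(paths)) {
    abort("either `synthetic` or `paths` must be given")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  syn_defaults <- list(n_stimuli = 132, n_types = 6, dim = 3,
                       languages = c("english", "swedish", "russian"),
                       n_participants = 20, triad_participants = 150,
                       triads_per_participant = 42)
  if (!is.null(synthetic)) {
    synthetic <- modifyList(syn_defaults, synthetic)
  }
  sampler <- modifyList(
    list(n_draws = 500, warmup = 300,
         triad_config = embedding_config(d = 3, warmup = 300, samples = 250,
                                         seed = seed),
         d_values = NULL),
    sampler
  )
  structure(list(synthetic = synthetic, paths = paths, stages = stages,
                 seed = seed, out_dir = out_dir, sampler = sampler),
            class = "pipeline_config")
}

validate_naming_table <- function(df, name) {
  problems <- character(0)
  need <- c("participant", "language", "stimulus", "sound_names",
            "emotion_names", "certainty_sound", "certainty_emotion",
            "t_first_sound", "t_first_emotion", "t_next", "layout")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing_cols, collapse = ", ")))
  } else {
    bad_cert <- which(!(df$certainty_sound %in% c(1:3, NA)) |
                        !(df$certainty_emotion %in% c(1:3, NA)))
    if (length(bad_cert)) {
      problems <- c(problems, paste0("certainty outside {1,2,3} in row(s): ",
                                     paste(head(bad_cert, 10), collapse = ", ")))
    }
    for (col in c("t_first_sound", "t_first_emotion", "t_next")) {
      bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
      if (length(bad)) {
        problems <- c(problems, paste0("non-positive ", col, " in row(s): ",
                                       paste(head(bad, 10), collapse = ", ")))
      }
    }
    bad_layout <- which(!df$layout %in% c("sound_left", "sound_right"))
    if (length(bad_layout)) {
      problems <- c(problems, paste0("unknown layout in row(s): ",
                                     paste(head(bad_layout, 10), collapse = ", ")))
    }
  }
  if (length(problems)) {
    abort(paste0("invalid naming table [", name, "]:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  df
}

validate_triad_table <- function(df) {
  problems <- character(0)
  need <- c("participant", "item1", "item2", "item3", "chosen1", "chosen2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("invalid triad table: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  its <- cbind(df$item1, df$item2, df$item3)
  dup <- which(apply(its, 1, anyDuplicated) > 0)
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate items in row(s): ",
                                   paste(head(dup, 10), collapse = ", ")))
  }
  in_triad <- df$chosen1 == df$item1 | df$chosen1 == df$item2 |
    df$chosen1 == df$item3
  in_triad2 <- df$chosen2 == df$item1 | df$chosen2 == df$item2 |
    df$chosen2 == df$item3
  bad <- which(!(in_triad & in_triad2) | df$chosen1 == df$chosen2)
  if (length(bad)) {
    problems <- c(problems, paste0("invalid chosen pair in row(s): ",
                                   paste(head(bad, 10), collapse = ", ")))
  }
  if (length(problems)) {
    abort(paste0("invalid triad table:\n  ", paste(problems, collapse = "\n  ")))
  }
  df
}

#' Validate and load all pipeline inputs
#'
#' Generates (synthetic mode) or reads (paths mode) every input table,
#' then schema-checks them with row-level error reports: unknown layout
#' codes, certainty values outside 1-3, non-positive latencies, triads
#' with duplicate items or chosen pairs outside the triad.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_bundle`: `naming` (named list of
#'   per-language trial tibbles), `acoustics`, `triads`, `lexicons`,
#'   `world` (synthetic mode only), `counts` summary tibble.
#' @export
validate_and_load <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  world <- NULL; lexicons <- list()
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    world <- make_world(n_stimuli = syn$n_stimuli, n_types = syn$n_types,
                        dim = syn$dim, seed = config$seed)
    par_over <- syn[setdiff(names(syn), names(formals(make_world))) ]
    par_over <- par_over[names(par_over) %in% names(default_gen_params(syn$dim))]
    params <- do.call(default_gen_params, c(list(dim = syn$dim), par_over))
    naming <- list()
    for (i in seq_along(syn$languages)) {
      lang <- syn$languages[i]
      lex <- make_lexicon(world, lang)
      lexicons[[lang]] <- lex
      naming[[lang]] <- simulate_naming(world, lex, syn$n_participants,
                                        params,
                                        seed = derive_seed(config$seed, 30L + i))
    }
    acoustics <- simulate_acoustics(world, params,
                                    seed = derive_seed(config$seed, 40L))
    triads <- simulate_triads(world, syn$triad_participants,
                              syn$triads_per_participant,
                              params$triad_temperature,
                              seed = derive_seed(config$seed, 41L))
  } else {
    naming <- lapply(config$paths$naming, read_naming_csv)
    acoustics <- if (!is.null(config$paths$acoustics)) {
      read_acoustics_csv(config$paths$acoustics)
    }
    triads <- if (!is.null(config$paths$triads)) {
      tr <- read_triads_csv(config$paths$triads)
      tr
    }
  }
  naming <- purrr::imap(naming, validate_naming_table)
  if (!is.null(triads)) triads <- validate_triad_table(triads)
  counts <- dplyr::bind_rows(purrr::imap(naming, function(df, lang) {
    tibble::tibble(language = lang, n_trials = nrow(df),
                   n_participants = dplyr::n_distinct(df$participant),
                   n_stimuli = dplyr::n_distinct(df$stimulus))
  }))
  structure(list(naming = naming, acoustics = acoustics, triads = triads,
                 lexicons = lexicons, world = world, counts = counts),
            class = "pipeline_bundle")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: per-language semantic spaces (profiles,
#' co-occurrence distances, MDS embedding, modal clusters, preference-
#' quantile sweep, prototype-weighted centroids) plus the cross-language
#' averaged space; naming statistics (entropies and their contrast,
#' log-latency model, certainty model, order preference, sound-emotion
#' contingency, emotion-from-name classifier); acoustic alignment
#' (standardization, weight learning against the averaged semantic space,
#' PCA, decision map, call-type classifier); and the triad embedding
#' (fit or dimension sweep, correlations with the naming references).
#' Stage failures are caught: downstream dependents are skipped,
#' independent stages still run, and the failure is recorded in the
#' summary.
#'
#' @param config a [pipeline_config()].
#' @param bundle optionally a pre-validated [validate_and_load()] bundle.
#' @return list of class `pipeline_report` with one element per stage,
#'   `summary` (schema-versioned list also written to
#'   `summary.json` when `out_dir` is set), and `errors`.
#' @export
run_pipeline <- function(config, bundle = validate_and_load(config)) {
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(writer, obj, file) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }
  report <- list()
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  sound_label_sets <- purrr::map(bundle$naming, function(df) {
    lang <- df$language[1]
    if (length(bundle$lexicons)) bundle$lexicons[[lang]]$sound_labels
    else sort(unique(unlist(split_labels(df$sound_names))))
  })
  emotion_label_sets <- purrr::map(bundle$naming, function(df) {
    lang <- df$language[1]
    if (length(bundle$lexicons)) bundle$lexicons[[lang]]$emotion_labels
    else sort(unique(unlist(split_labels(df$emotion_names))))
  })

  # ---- semspace -----------------------------------------------------
  if ("semspace" %in% config$stages) {
    report$semspace <- run_stage("semspace", {
      per_lang <- purrr::imap(bundle$naming, function(df, lang) {
        prof <- name_profile_matrix(df, sound_label_sets[[lang]], "sound")
        dmat <- cooccurrence_distances(prof)
        emb <- embed_space(dmat, k = 3)
        modal <- modal_clusters(df, sound_label_sets[[lang]], "sound")
        cert <- df |>
          dplyr::group_by(.data$stimulus) |>
          dplyr::summarise(certainty = mean(.data$certainty_sound))
        assign_modal <- setNames(modal$modal_label, modal$stimulus)
        sweep_tab <- q_sweep(dmat, assign_modal,
                             q_grid = seq(0, 1, by = 0.1))
        centroids <- weighted_centroids(
          emb, assign_modal,
          setNames(cert$certainty, cert$stimulus),
          setNames(modal$modal_proportion, modal$stimulus)
        )
        emit(write_distance_csv, dmat, paste0("distances_sound_", lang, ".csv"))
        emit(write_embedding_csv, emb, paste0("embedding_", lang, ".csv"))
        emit(function(x, p) readr::write_csv(dplyr::select(x, -"solutions"), p),
             sweep_tab, paste0("q_sweep_", lang, ".csv"))
        list(profiles = prof, distances = dmat, embedding = emb,
             modal = modal, q_sweep = sweep_tab, centroids = centroids)
      })
      emo_dists <- purrr::imap(bundle$naming, function(df, lang) {
        cooccurrence_distances(
          name_profile_matrix(df, emotion_label_sets[[lang]], "emotion"))
      })
      averaged <- average_distance_matrices(purrr::map(per_lang, "distances"))
      averaged_emotion <- average_distance_matrices(unname(emo_dists))
      emit(write_distance_csv, averaged, "distances_sound_averaged.csv")
      emit(write_distance_csv, averaged_emotion, "distances_emotion_averaged.csv")
      list(per_language = per_lang, averaged = averaged,
           averaged_emotion = averaged_emotion)
    })
  }

  # ---- namestats ----------------------------------------------------
  if ("namestats" %in% config$stages) {
    report$namestats <- run_stage("namestats", {
      trials <- dplyr::bind_rows(bundle$naming)
      lang1 <- names(bundle$naming)[1]
      ent <- naming_entropies(bundle$naming[[lang1]],
                              sound_label_sets[[lang1]],
                              emotion_label_sets[[lang1]])
      contrast <- entropy_contrast(ent$entropy_sound, ent$entropy_emotion,
                                   seed = derive_seed(config$seed, 50L))
      rt <- fit_rt_model(trials, n_draws = config$sampler$n_draws,
                         warmup = config$sampler$warmup,
                         seed = derive_seed(config$seed, 51L))
      cert <- fit_certainty_model(bundle$naming[[lang1]],
                                  n_draws = config$sampler$n_draws,
                                  warmup = config$sampler$warmup,
                                  seed = derive_seed(config$seed, 52L))
      ord <- order_preference(trials, n_draws = config$sampler$n_draws,
                              warmup = config$sampler$warmup,
                              seed = derive_seed(config$seed, 53L))
      cont <- sound_emotion_contingency(bundle$naming[[lang1]],
                                        sound_label_sets[[lang1]],
                                        emotion_label_sets[[lang1]])
      efn <- emotion_from_name_accuracy(bundle$naming[[lang1]],
                                        sound_label_sets[[lang1]],
                                        seed = derive_seed(config$seed, 54L))
      emit(function(x, p) readr::write_csv(x, p), ent, "entropies.csv")
      emit(function(x, p) readr::write_csv(tidy(x), p), rt, "rt_model.csv")
      emit(function(x, p) {
        df <- dplyr::bind_cols(tibble::tibble(sound = rownames(x$table)),
                               tibble::as_tibble(x$table))
        readr::write_csv(df, p)
      }, cont, "contingency.csv")
      list(entropies = ent, entropy_contrast = contrast, rt_model = rt,
           certainty_model = cert, order_preference = ord,
           contingency = cont, emotion_from_name = efn)
    })
  }

  # ---- acoustic -----------------------------------------------------
  if ("acoustic" %in% config$stages && !is.null(bundle$acoustics)) {
    semspace_ok <- !is.null(report$semspace)
    report$acoustic <- run_stage("acoustic", {
      if (!semspace_ok) abort("acoustic stage needs the semspace reference")
      feats <- standardize_features(bundle$acoustics)
      ref <- report$semspace$averaged
      ids <- rownames(ref)
      feats <- feats[match(ids, feats$stimulus), ]
      mw <- optimize_weights(feats, ref,
                             seed = derive_seed(config$seed, 60L))
      w <- setNames(mw$weights$weight, mw$weights$feature)
      wd <- weighted_distance_matrix(feats, w)
      weighted_feats <- dplyr::bind_cols(
        tibble::tibble(stimulus = feats$stimulus),
        tibble::as_tibble(sweep(feature_matrix(feats), 2, w, "*"))
      )
      pca <- acoustic_pca(weighted_feats, k = 2)
      lang1 <- names(bundle$naming)[1]
      modal <- modal_clusters(bundle$naming[[lang1]],
                              sound_label_sets[[lang1]], "sound")
      labels <- setNames(modal$modal_label, modal$stimulus)
      dm <- multinomial_decision_map(pca$pc_scores[, 1:2],
                                     labels[rownames(pca$pc_scores)])
      acc <- calltype_classifier_accuracy(
        feats, labels, pooling = "major7",
        seed = derive_seed(config$seed, 61L))
      emit(function(x, p) readr::write_csv(tidy(x), p), mw, "acoustic_weights.csv")
      emit(write_distance_csv, wd, "distances_acoustic.csv")
      emit(write_embedding_csv, pca, "acoustic_pca.csv")
      list(weights = mw, weighted_distances = wd, pca = pca,
           decision_map = dm, calltype_accuracy = acc,
           semantic_correlation = mw$achieved_correlation)
    })
  }

  # ---- triad --------------------------------------------------------
  if ("triad" %in% config$stages && !is.null(bundle$triads)) {
    report$triad <- run_stage("triad", {
      refs <- if (!is.null(report$semspace)) {
        list(sound = report$semspace$averaged,
             emotion = report$semspace$averaged_emotion)
      }
      cfg <- config$sampler$triad_config
      cfg$seed <- derive_seed(config$seed, 70L)
      if (!is.null(config$sampler$d_values)) {
        sw <- dimension_sweep(bundle$triads, config$sampler$d_values, cfg,
                              reference_matrices = refs)
        best <- sw$fits[[which.min(sw$waic)]]
        emit(function(x, p) readr::write_csv(dplyr::select(x, -"fits"), p),
             sw, "dimension_sweep.csv")
        emit(write_distance_csv, best$mean_distance_matrix,
             "distances_triad.csv")
        list(sweep = sw, fit = best)
      } else {
        fit <- fit_embedding(bundle$triads, cfg)
        rs <- purrr::map_dbl(refs %||% list(), function(ref) {
          ids <- fit$ids
          matrix_correlation(fit$mean_distance_matrix, ref[ids, ids])
        })
        emit(write_distance_csv, fit$mean_distance_matrix,
             "distances_triad.csv")
        list(fit = fit, reference_correlations = rs)
      }
    })
  }

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    stages_run = intersect(config$stages, names(report)),
    errors = errors,
    counts = bundle$counts,
    semspace = if (!is.null(report$semspace)) list(
      n_stimuli = nrow(report$semspace$averaged),
      variance_explained_3d = purrr::map_dbl(
        report$semspace$per_language,
        ~ sum(.x$embedding$explained_variance))
    ),
    namestats = if (!is.null(report$namestats)) list(
      mean_entropy_sound = mean(report$namestats$entropies$entropy_sound),
      mean_entropy_emotion = mean(report$namestats$entropies$entropy_emotion),
      chi_square = report$namestats$contingency$chi_square,
      emotion_from_name_accuracy = report$namestats$emotion_from_name$accuracy
    ),
    acoustic = if (!is.null(report$acoustic)) list(
      semantic_correlation = report$acoustic$semantic_correlation,
      calltype_accuracy = report$acoustic$calltype_accuracy$accuracy
    ),
    triad = if (!is.null(report$triad) && !is.null(report$triad$fit)) list(
      d = report$triad$fit$config$d,
      waic = waic(report$triad$fit$pointwise_loglik)$waic
    )
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report$summary <- summary
  report$errors <- errors
  class(report) <- "pipeline_report"
  if (length(errors)) {
    warn(paste("pipeline stage(s) failed:", paste(names(errors), collapse = ", ")))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages:",
      paste(setdiff(names(x), c("summary", "errors")), collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("failed:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
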