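#' Per-stimulus label-choice profiles
#'
#' Converts naming trials into a stimulus x label matrix of choice
#' proportions: cell (s, l) is the number of times label l was chosen for
#' stimulus s divided by the total number of label choices for s.
#' Multi-label answers contribute one count per chosen label.
#'
#' @param trials tibble of naming trials (as from [simulate_naming()] or
#'   [read_naming_csv()]), with `stimulus` and a `sound_names` /
#'   `emotion_names` column of ";"-separated labels.
#' @param label_set character vector: the full ordered label inventory.
#' @param name_kind "sound" or "emotion".
#' @return matrix (rows = stimuli in first-appearance order, columns =
#'   `label_set`) whose rows sum to 1, with class `label_profile`.
#' @export
name_profile_matrix <- function(trials, label_set,
                                name_kind = c("sound", "emotion")) {
  name_kind <- match.arg(name_kind)
  col <- paste0(name_kind, "_names")
  if (!col %in% names(trials)) abort(sprintf("column `%s` not found", col))
  if (anyDuplicated(label_set)) abort("`label_set` has duplicate labels")

  stimuli <- unique(trials$stimulus)
  labs <- split_labels(trials[[col]])
  all_labs <- unlist(labs)
  unknown <- setdiff(all_labs, label_set)
  if (length(unknown)) {
    abort(paste("labels outside `label_set`:",
                paste(unique(unknown), collapse = ", ")))
  }
  counts <- table(
    factor(rep(trials$stimulus, lengths(labs)), levels = stimuli),
    factor(all_labs, levels = label_set)
  )
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    abort(paste("stimuli with zero label choices:",
                paste(stimuli[tot == 0], collapse = ", ")))
  }
  structure(counts / tot, class = c("label_profile", "matrix"))
}

#' Modal-name clusters
#'
#' Defines a cluster as the group of stimuli sharing the same most commonly
#' chosen name, and reports each stimulus's modal label and the proportion
#' of all its label choices that the modal label received. Exact ties are
#' broken toward the earliest label in `label_set` order and flagged.
#'
#' @inheritParams name_profile_matrix
#' @return tibble with `stimulus`, `modal_label`, `modal_proportion`,
#'   `tie` (logical).
#' @export
modal_clusters <- function(trials, label_set,
                           name_kind = c("sound", "emotion")) {
  profiles <- name_profile_matrix(trials, label_set, name_kind)
  idx <- apply(profiles, 1, which.max)        # first max = lowest label index
  mx <- profiles[cbind(seq_len(nrow(profiles)), idx)]
  tie <- apply(profiles, 1, function(r) sum(r == max(r)) > 1)
  tibble::tibble(
    stimulus = rownames(profiles),
    modal_label = colnames(profiles)[idx],
    modal_proportion = unname(mx),
    tie = unname(tie)
  )
}
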