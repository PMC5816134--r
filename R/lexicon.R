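# Default label inventories. English has 16 sound names; Swedish and
# Russian have 12 (their low-frequency candidates were dropped). All three
# languages use 16 emotion names. Non-ASCII characters are transliterated
# so CSV fixtures stay locale-proof.
SOUND_LABELS <- list(
  english = c(laugh = "laugh", laugh2 = "giggle", laugh3 = "chuckle",
              cry = "cry", cry2 = "sob", cry3 = "whimper",
              scream = "scream", scream2 = "shriek", scream3 = "yell",
              moan = "moan", moan2 = "groan",
              sigh = "sigh", sigh2 = "gasp",
              roar = "roar", roar2 = "grunt", roar3 = "growl"),
  swedish = c(laugh = "skratt", laugh2 = "fniss",
              cry = "grat", cry2 = "snyft",
              scream = "skrik", scream2 = "tjut",
              moan = "ston", moan2 = "jammer",
              sigh = "suck", sigh2 = "flamtning",
              roar = "vral", roar2 = "grymtning"),
  russian = c(laugh = "smekh", laugh2 = "khikhikanie",
              cry = "plach", cry2 = "vskhlip",
              scream = "krik", scream2 = "vizg",
              moan = "ston", moan2 = "okh",
              sigh = "vzdokh", sigh2 = "akh",
              roar = "ryov", roar2 = "rychanie")
)

EMOTION_LABELS <- list(
  english = c("amusement", "anger", "disgust", "effort", "fear", "joy",
              "pain", "pleasure", "sadness", "surprise", "relief",
              "contempt", "tenderness", "boredom", "shame", "excitement"),
  swedish = c("munterhet", "ilska", "ackel", "anstrangning", "radsla",
              "gladje", "smarta", "njutning", "sorg", "forvaning",
              "lattnad", "forakt", "omhet", "trakighet", "skam",
              "upphetsning"),
  russian = c("vesele", "gnev", "otvrashchenie", "usilie", "strakh",
              "radost", "bol", "udovolstvie", "grust", "udivlenie",
              "oblegchenie", "prezrenie", "nezhnost", "skuka", "styd",
              "vozbuzhdenie")
)

#' Build a per-language lexicon for the naming simulator
#'
#' Places a prototype in the world's latent space for every sound name and
#' emotion name. Sound names are grouped into synonym sets (e.g. laugh /
#' giggle / chuckle), all anchored near the centre of the call type they
#' denote, with a deterministic jitter so synonyms are distinguishable but
#' confusable. Emotion-name prototypes are placed at context-weighted
#' averages of the type centres, so that e.g. "sadness" sits near the cry
#' cluster while ambiguous emotions sit between clusters — which makes
#' emotion naming intrinsically less consistent than sound naming.
#'
#' @param world a [make_world()] object.
#' @param language one of "english", "swedish", "russian".
#' @param synonym_jitter sd of the prototype offset within a synonym group.
#' @return A `vocal_lexicon`: list with `language`, `sound_labels`,
#'   `emotion_labels`, `sound_prototypes` (label x dim), `emotion_prototypes`
#'   and `synonymy_groups` (named list mapping call type -> labels).
#' @export
make_lexicon <- function(world, language = c("english", "swedish", "russian"),
                         synonym_jitter = 0.7) {
  stopifnot(inherits(world, "vocal_world"))
  language <- match.arg(language)
  withr::local_seed(derive_seed(world$seed, 100L + match(language, names(SOUND_LABELS))))

  types <- rownames(world$type_centers)
  raw <- SOUND_LABELS[[language]]
  # label -> call type from the synonym-group key (strip trailing digits)
  label_type <- sub("[0-9]+$", "", names(raw))
  keep <- label_type %in% types
  labels <- unname(raw[keep])
  label_type <- label_type[keep]
  if (anyDuplicated(labels)) abort("duplicate sound labels in lexicon")

  proto <- world$type_centers[label_type, , drop = FALSE] +
    matrix(rnorm(length(labels) * world$dim), length(labels)) * synonym_jitter
  rownames(proto) <- labels

  # emotion prototypes: context-probability-weighted blends of type centres,
  # plus a small jitter for the non-context emotion terms
  emo <- EMOTION_LABELS[[language]]
  ctx <- type_context_probs(types)              # type x context
  ctx_pos <- t(ctx) %*% world$type_centers      # context x dim, unnormalized
  ctx_pos <- sweep(ctx_pos, 1, pmax(colSums(ctx), 1e-9), "/")
  eproto <- matrix(0, length(emo), world$dim)
  for (i in seq_along(emo)) {
    if (i <= nrow(ctx_pos)) {
      eproto[i, ] <- ctx_pos[i, ]
    } else {
      # extra emotion terms shadow one of the nine contexts
      eproto[i, ] <- ctx_pos[1 + (i - 1) %% nrow(ctx_pos), ]
    }
  }
  eproto <- eproto + matrix(rnorm(length(emo) * world$dim), length(emo)) * 0.5
  # compress toward the centre of gravity: emotional readings of a call are
  # intrinsically more ambiguous than its acoustic category, so emotion
  # prototypes discriminate less sharply than sound-name prototypes
  eproto <- eproto * 0.55
  rownames(eproto) <- emo

  structure(
    list(
      language = language,
      sound_labels = labels,
      emotion_labels = emo,
      sound_prototypes = proto,
      emotion_prototypes = eproto,
      synonymy_groups = split(labels, label_type)
    ),
    class = "vocal_lexicon"
  )
}

#' @export
print.vocal_lexicon <- function(x, ...) {
  cat(sprintf("<vocal_lexicon> %s: %d sound names, %d emotion names\n",
              x$language, length(x$sound_labels), length(x$emotion_labels)))
  invisible(x)
}
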