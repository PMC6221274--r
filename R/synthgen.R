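# Default vocabulary: 60 words typical of spoken descriptions of a busy
# kitchen scene (the picture-description task the transcripts come from).
picture_words <- c(
  "the", "a", "and", "is", "are", "on", "in", "of", "to", "there",
  "here", "she", "he", "it", "they", "boy", "girl", "mother", "woman",
  "kid", "kids", "cookie", "cookies", "jar", "stool", "chair", "kitchen",
  "sink", "water", "dish", "dishes", "plate", "counter", "window",
  "curtains", "floor", "cupboard", "standing", "falling", "reaching",
  "taking", "washing", "drying", "running", "over", "overflowing",
  "wobbling", "little", "young", "busy", "wet", "dry", "full", "empty",
  "up", "down", "off", "out", "while", "with")

# One Dirichlet(alpha) draw per row via normalized gammas.
rdirichlet_rows <- function(nrow, ncol, alpha) {
  g <- matrix(stats::rgamma(nrow * ncol, shape = alpha), nrow, ncol)
  # guard against all-zero rows at tiny concentrations
  g[rowSums(g) == 0, ] <- 1
  g / rowSums(g)
}

#' Specification for a two-group synthetic transcript corpus
#'
#' Describes two groups of short picture-description transcripts drawn from
#' a shared small vocabulary by first-order Markov walks. The control group
#' uses a base transition matrix; the positive group mixes in a
#' group-specific perturbation with weight \code{divergence}, so
#' \code{divergence = 0} makes both groups draws from exactly the same
#' process and \code{divergence = 1} gives the positive group fully
#' perturbed transitions. Defaults mirror the sparse clinical regime of a
#' small study arm: 19 transcripts per group of 8-15 sentences each
#' (roughly 200 sentences per group).
#'
#' @param vocabulary_size Number of word types (default 60; at most the
#'   built-in word list unless \code{words} is supplied).
#' @param divergence Mixing weight of the perturbation, in [0, 1].
#' @param transcripts_per_group Transcripts per group (default 19).
#' @param sentences_per_transcript Integer range (default 8:15).
#' @param sentence_length Integer range of words per sentence (default
#'   4:12).
#' @param concentration Dirichlet concentration of the transition rows
#'   (default 0.1: low-entropy, formulaic phrasing, which keeps the 4-gram
#'   vocabulary in the few-thousand range typical of picture-description
#'   corpora).
#' @param perturb_fraction Fraction of words whose outgoing transition row
#'   is re-drawn for the positive group (default 0.5).
#' @param base_transition Optional row-stochastic matrix overriding the
#'   seeded Dirichlet base.
#' @param perturbation Optional row-stochastic matrix overriding the
#'   seeded perturbation.
#' @param words Optional character vector of word types.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return An object of class \code{"generator_spec"}.
#' @export
generator_spec <- function(vocabulary_size = 60L, divergence = 0.5,
                           transcripts_per_group = 19L,
                           sentences_per_transcript = 8:15,
                           sentence_length = 4:12,
                           concentration = 0.1, perturb_fraction = 0.5,
                           base_transition = NULL, perturbation = NULL,
                           words = NULL, seed = 1L) {
  if (divergence < 0 || divergence > 1)
    stop("`divergence` must lie in [0, 1]", call. = FALSE)
  if (is.null(words))
    words <- rep_len(picture_words, vocabulary_size)
  words <- make.unique(words, sep = "")
  vocabulary_size <- length(words)
  check_stochastic <- function(m, what) {
    if (!is.null(m)) {
      if (nrow(m) != vocabulary_size || ncol(m) != vocabulary_size ||
          any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
        stop("`", what, "` must be a ", vocabulary_size, "x",
             vocabulary_size, " row-stochastic matrix", call. = FALSE)
    }
    m
  }
  structure(list(vocabulary_size = vocabulary_size, words = words,
                 divergence = divergence,
                 transcripts_per_group = as.integer(transcripts_per_group),
                 sentences_per_transcript = as.integer(sentences_per_transcript),
                 sentence_length = as.integer(sentence_length),
                 concentration = concentration,
                 perturb_fraction = perturb_fraction,
                 base_transition = check_stochastic(base_transition,
                                                   "base_transition"),
                 perturbation = check_stochastic(perturbation,
                                                 "perturbation"),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(paste0("<generator_spec: %d words, divergence %.2f, ",
                     "%d transcripts/group, seed %d>\n"),
              x$vocabulary_size, x$divergence, x$transcripts_per_group,
              x$seed))
  invisible(x)
}

#' Generate a two-group synthetic transcript corpus
#'
#' Sentences are first-order Markov walks over the word vocabulary. The
#' control group walks on the base transition matrix; the positive group
#' walks on \code{(1 - divergence) * base + divergence * perturbation},
#' where the perturbation re-draws the outgoing rows of a seeded subset of
#' words. The initial word distribution is shared by both groups. Fully
#' deterministic for a fixed spec seed.
#'
#' @param spec A \code{\link{generator_spec}}.
#' @return List of labeled \code{\link{transcript}} objects (positives
#'   first, ids \code{pos01...}/\code{ctl01...}).
#' @export
make_groups <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  V <- spec$vocabulary_size
  with_seed(spec$seed, {
    base <- spec$base_transition
    if (is.null(base)) base <- rdirichlet_rows(V, V, spec$concentration)
    init <- as.numeric(rdirichlet_rows(1L, V, spec$concentration))
    pert <- spec$perturbation
    if (is.null(pert)) {
      pert <- base
      redo <- sample.int(V, max(1L, round(spec$perturb_fraction * V)))
      pert[redo, ] <- rdirichlet_rows(length(redo), V, spec$concentration)
    }
    pos_trans <- (1 - spec$divergence) * base + spec$divergence * pert
    pick <- function(r) if (length(r) == 1L) r else sample(r, 1L)
    sample_sentence <- function(trans) {
      len <- pick(spec$sentence_length)
      w <- integer(len)
      w[1] <- sample.int(V, 1L, prob = init)
      for (t in seq_len(len - 1L))
        w[t + 1L] <- sample.int(V, 1L, prob = trans[w[t], ])
      spec$words[w]
    }
    sample_transcript <- function(id, label, trans) {
      ns <- pick(spec$sentences_per_transcript)
      transcript(id, label, lapply(seq_len(ns),
                                   function(i) sample_sentence(trans)))
    }
    out <- vector("list", 2L * spec$transcripts_per_group)
    for (i in seq_len(spec$transcripts_per_group))
      out[[i]] <- sample_transcript(sprintf("pos%02d", i), "positive",
                                    pos_trans)
    for (i in seq_len(spec$transcripts_per_group))
      out[[spec$transcripts_per_group + i]] <-
        sample_transcript(sprintf("ctl%02d", i), "control", base)
  })
  out
}

#' Write a generated corpus as a loadable fixture
#'
#' One file per transcript (plain or minimal CHAT, see
#' \code{\link{write_transcripts}}) plus a \code{labels.tsv} sidecar with
#' columns \code{id} and \code{label}. Round-trips through
#' \code{\link{load_transcripts}}.
#'
#' @param transcripts Labeled transcripts (e.g. \code{\link{make_groups}}).
#' @param path Output directory.
#' @param format \code{"plain"} or \code{"chat_minimal"}.
#' @return Invisibly, \code{path}.
#' @export
write_fixture <- function(transcripts, path,
                          format = c("plain", "chat_minimal")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (length(transcripts)) write_transcripts(transcripts, path, format)
  labels <- data.frame(id = transcript_ids(transcripts),
                       label = transcript_labels(transcripts))
  utils::write.table(labels, file.path(path, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
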