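#' Fit a class-conditional n-gram language model
#'
#' The conventional (non-neural) baseline: per-class n-gram occurrence
#' counts over the pooled unique n-gram vocabulary with add-one smoothing,
#' so \eqn{P(g \mid c) = (count_c(g) + 1) / (total_c + |V|)}. N-grams
#' unseen in any training class map to a single smoothed unseen bucket with
#' probability \eqn{1 / (total_c + |V|)}.
#'
#' @param transcripts Labeled list of \code{\link{transcript}} objects
#'   (both classes present).
#' @param n N-gram order (default 4).
#' @param smoothing Only \code{"add_one"} is implemented.
#' @return An object of class \code{"class_lm"}: list with \code{order},
#'   \code{vocab} (character), \code{counts} (matrix, vocab x classes),
#'   \code{totals}, \code{classes}.
#' @export
fit_ngram_lm <- function(transcripts, n = 4L, smoothing = "add_one") {
  smoothing <- match.arg(smoothing, "add_one")
  labels <- transcript_labels(transcripts)
  if (length(unique(labels)) < 2L)
    stop("need training transcripts from both classes", call. = FALSE)
  vocab <- build_vocabulary(transcripts, n)
  structure(list(order = as.integer(n), vocab = vocab$entries,
                 counts = vocab$entry_counts,
                 totals = colSums(vocab$entry_counts),
                 classes = colnames(vocab$entry_counts),
                 smoothing = smoothing),
            class = "class_lm")
}

#' @export
print.class_lm <- function(x, ...) {
  cat(sprintf("<class_lm: order %d, %d n-grams, classes %s>\n",
              x$order, length(x$vocab), paste(x$classes, collapse = "/")))
  invisible(x)
}

# Smoothed log2 probability of each n-gram of `grams` under class `cl`.
class_log2_prob <- function(model, grams, cl) {
  idx <- match(grams, model$vocab)
  cnt <- rep(0L, length(grams))      # unseen n-grams: the add-one bucket
  seen <- !is.na(idx)
  cnt[seen] <- model$counts[idx[seen], cl]
  log2((cnt + 1) / (model$totals[[cl]] + length(model$vocab)))
}

#' Classify a transcript by class-conditional likelihood
#'
#' The score for each class is the mean per-n-gram log2 probability of the
#' transcript under that class's smoothed table. The predicted label is the
#' argmax; exact ties predict control. The confidence reported for AUC is
#' score(positive) - score(control).
#'
#' @param model A \code{\link{fit_ngram_lm}} result.
#' @param transcript A \code{\link{transcript}}.
#' @return List with \code{scores} (named per class), \code{label} and
#'   \code{confidence}.
#' @export
classify_by_likelihood <- function(model, transcript) {
  grams <- transcript_ngrams(transcript, model$order)
  if (length(grams) == 0L)
    stop("transcript '", transcript$id, "' has no n-grams of order ",
         model$order, call. = FALSE)
  scores <- vapply(model$classes,
                   function(cl) mean(class_log2_prob(model, grams, cl)),
                   numeric(1))
  # classes are sorted, so "control" precedes "positive"
  confidence <- scores[["positive"]] - scores[["control"]]
  label <- if (confidence > 0) "positive" else "control"
  list(scores = scores, label = label, confidence = confidence)
}

#' Export per-class n-gram count tables as TSV
#'
#' @param model A \code{\link{fit_ngram_lm}} result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_class_lm <- function(model, path) {
  df <- data.frame(ngram = model$vocab, model$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
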