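#' Extract contiguous n-grams from a token sequence
#'
#' Returns the \code{max(0, L - n + 1)} contiguous n-grams of a length-L
#' sentence, in order. N-grams never cross sentence boundaries and no
#' start/end padding is added, so a sentence shorter than \code{n} yields
#' none.
#'
#' @param tokens Character vector of tokens (one sentence).
#' @param n N-gram order, an integer >= 1.
#' @return Character vector of n-grams, tokens joined by single spaces.
#' @examples
#' extract_ngrams(c("the", "boy", "is", "on", "the", "stool"), 4)
#' @export
extract_ngrams <- function(tokens, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be an integer >= 1", call. = FALSE)
  L <- length(tokens)
  if (L < n) return(character(0))
  if (n == 1L) return(tokens)
  idx <- embed(seq_len(L), n)[, n:1, drop = FALSE]
  apply(idx, 1L, function(i) paste(tokens[i], collapse = " "))
}

transcript_ngrams <- function(tr, n)
  unlist(lapply(tr$sentences, extract_ngrams, n = n), use.names = FALSE)

#' Build an order-n vocabulary space from labeled transcripts
#'
#' Enumerates the distinct n-grams of a transcript collection. Entries are
#' ordered by first occurrence (transcripts in the given order, sentences in
#' reading order), which makes the index map deterministic. Per-class counts
#' are type-level: the number of distinct n-grams observed in each class,
#' whose sum (\code{total_count}) exceeds the pooled distinct count
#' (\code{unique_count}) by the size of the between-class overlap.
#'
#' @param transcripts List of labeled \code{\link{transcript}} objects.
#' @param n N-gram order.
#' @return An object of class \code{"ngram_vocabulary"}: list with
#'   \code{order}, \code{entries} (character vector; the index map is the
#'   position in this vector), \code{entry_counts} (integer matrix of
#'   occurrence counts, one row per entry, one column per class),
#'   \code{per_group_counts} (named integer: distinct n-grams per class),
#'   \code{total_count} and \code{unique_count}.
#' @export
build_vocabulary <- function(transcripts, n) {
  if (length(transcripts) == 0L)
    stop("need at least one transcript", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be an integer >= 1", call. = FALSE)
  labels <- transcript_labels(transcripts)
  grams <- lapply(transcripts, transcript_ngrams, n = n)
  entries <- unique(unlist(grams, use.names = FALSE))
  classes <- sort(unique(labels))
  counts <- matrix(0L, length(entries), length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    g <- unlist(grams[labels == cl], use.names = FALSE)
    tab <- table(factor(g, levels = entries))
    counts[, cl] <- as.integer(tab)
  }
  per_group <- colSums(counts > 0L)
  structure(list(order = n, entries = entries,
                 entry_counts = counts,
                 per_group_counts = per_group,
                 total_count = sum(per_group),
                 unique_count = length(entries)),
            class = "ngram_vocabulary")
}

#' @export
print.ngram_vocabulary <- function(x, ...) {
  cat(sprintf("<%d-gram vocabulary: %d unique / %d total (%s)>\n",
              x$order, x$unique_count, x$total_count,
              paste(sprintf("%s %d", names(x$per_group_counts),
                            x$per_group_counts), collapse = ", ")))
  invisible(x)
}

#' Sparse document by n-gram matrix
#'
#' One row per transcript, one column per vocabulary entry. Binary mode
#' records presence/absence; count mode records raw occurrence counts.
#' N-grams absent from the vocabulary (out-of-vocabulary at test time) are
#' ignored and contribute nothing.
#'
#' @param transcripts List of \code{\link{transcript}} objects.
#' @param vocab An \code{\link{build_vocabulary}} result.
#' @param mode \code{"binary"} (default) or \code{"count"}.
#' @return A \code{\link[Matrix]{sparseMatrix}} with transcript ids as
#'   rownames and n-grams as colnames.
#' @export
vectorize_transcripts <- function(transcripts, vocab,
                                  mode = c("binary", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vocab, "ngram_vocabulary"))
  ids <- transcript_ids(transcripts)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_along(transcripts)) {
    g <- transcript_ngrams(transcripts[[i]], vocab$order)
    j <- match(g, vocab$entries)
    j <- j[!is.na(j)]
    if (!length(j)) next
    tab <- table(j)
    jj <- c(jj, as.integer(names(tab)))
    ii <- c(ii, rep.int(i, length(tab)))
    xx <- c(xx, if (mode == "binary") rep(1, length(tab))
            else as.numeric(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(ids), vocab$unique_count),
                       dimnames = list(ids, vocab$entries))
}

#' Export / import an n-gram vocabulary as TSV
#'
#' Columns: \code{ngram} (tokens space-joined), \code{index}, and one
#' occurrence-count column per class. The n-gram order is recorded in a
#' comment header line.
#'
#' @param vocab,path Vocabulary object and file path.
#' @return \code{write_vocabulary} invisibly returns \code{path};
#'   \code{read_vocabulary} returns an \code{"ngram_vocabulary"}.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- data.frame(ngram = vocab$entries,
                   index = seq_along(vocab$entries))
  df <- cbind(df, as.data.frame(vocab$entry_counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# order=%d", vocab$order), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  order <- as.integer(sub("^# order=", "", readLines(path, n = 1L)))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          quote = "", comment.char = "",
                          colClasses = "character")
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- NULL
  per_group <- colSums(counts > 0L)
  structure(list(order = order, entries = df$ngram,
                 entry_counts = counts,
                 per_group_counts = per_group,
                 total_count = sum(per_group),
                 unique_count = nrow(df)),
            class = "ngram_vocabulary")
}

#' Write a document-term matrix in Matrix Market format
#'
#' Writes the sparse matrix as \code{<path>.mtx} with row ids in
#' \code{<path>.rows.txt} and column n-grams in \code{<path>.cols.txt}.
#'
#' @param x Sparse matrix from \code{\link{vectorize_transcripts}}.
#' @param path Path stem (no extension).
#' @return Invisibly, the three paths written.
#' @export
write_dtm <- function(x, path) {
  mtx <- paste0(path, ".mtx")
  Matrix::writeMM(x, mtx)
  rows <- paste0(path, ".rows.txt")
  cols <- paste0(path, ".cols.txt")
  writeLines(rownames(x), rows)
  writeLines(colnames(x), cols)
  invisible(c(mtx, rows, cols))
}
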