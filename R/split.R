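#' Stratified train/test/validation split
#'
#' Partitions a transcript collection into training, test and validation id
#' sets, stratified by diagnostic label. Within each class the requested
#' proportions are realized by largest-remainder rounding, so each realized
#' set size is within one transcript of the requested fraction per class,
#' and the three sets always partition the input exactly. The assignment is
#' deterministic for a fixed seed.
#'
#' @param transcripts List of \code{\link{transcript}} objects.
#' @param proportions Numeric vector of three fractions
#'   (train, test, validation) summing to 1.
#' @param seed Integer seed controlling the shuffle.
#' @param stratify Stratify by label (default \code{TRUE}).
#' @return An object of class \code{"dataset_split"}: a list with
#'   \code{train_ids}, \code{test_ids}, \code{validation_ids},
#'   \code{proportions} and \code{seed}.
#' @examples
#' trs <- c(
#'   lapply(1:4, function(i) transcript(paste0("p", i), "positive",
#'                                      list(c("a", "b")))),
#'   lapply(1:4, function(i) transcript(paste0("c", i), "control",
#'                                      list(c("a", "b")))))
#' make_split(trs, c(0.5, 0.25, 0.25), seed = 1)
#' @export
make_split <- function(transcripts, proportions = c(0.5, 0.25, 0.25),
                       seed = 1L, stratify = TRUE) {
  if (length(proportions) != 3L || any(proportions < 0))
    stop("`proportions` must be three nonnegative fractions", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("`proportions` must sum to 1", call. = FALSE)
  ids <- transcript_ids(transcripts)
  labels <- transcript_labels(transcripts)
  strata <- if (stratify) split(ids, factor(labels, c("control", "positive")))
            else list(all = ids)
  if (stratify && any(lengths(strata) == 0L))
    stop("stratified split requires at least one transcript per class",
         call. = FALSE)
  sets <- list(character(0), character(0), character(0))
  for (class_ids in strata) {
    class_ids <- sort(class_ids)
    with_seed(seed, class_ids <- sample(class_ids))
    n <- length(class_ids)
    sizes <- largest_remainder(proportions * n)
    idx <- rep.int(1:3, sizes)
    for (s in 1:3) sets[[s]] <- c(sets[[s]], class_ids[idx == s])
  }
  structure(list(train_ids = sets[[1]], test_ids = sets[[2]],
                 validation_ids = sets[[3]],
                 proportions = proportions, seed = as.integer(seed)),
            class = "dataset_split")
}

# Integer apportionment: floors plus remainders assigned to the largest
# fractional parts (ties broken by position: train, then test, then val).
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- sum(x) - sum(fl)
  extra <- order(x - fl, decreasing = TRUE)[seq_len(round(rem))]
  fl[extra] <- fl[extra] + 1
  as.integer(fl)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train / %d test / %d validation (seed %d)>\n",
              length(x$train_ids), length(x$test_ids),
              length(x$validation_ids), x$seed))
  invisible(x)
}

#' Subset transcripts by id
#'
#' @param transcripts List of \code{\link{transcript}} objects.
#' @param ids Character vector of transcript ids to keep (order preserved).
#' @return The matching transcripts.
#' @export
subset_transcripts <- function(transcripts, ids) {
  all_ids <- transcript_ids(transcripts)
  missing <- setdiff(ids, all_ids)
  if (length(missing))
    stop("unknown transcript ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  transcripts[match(ids, all_ids)]
}
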