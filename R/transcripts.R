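#' Construct a transcript object
#'
#' A transcript holds one participant's picture-description speech as an
#' ordered list of tokenized sentences, together with a unique id and a
#' diagnostic label (\code{"positive"} for the impaired group, \code{"control"}
#' for healthy speakers).
#'
#' @param id Unique identifier string.
#' @param label Either \code{"positive"} or \code{"control"}.
#' @param sentences List of character vectors, one vector of lowercased
#'   word tokens per sentence. Empty sentences are dropped.
#' @return An object of class \code{"transcript"}.
#' @examples
#' transcript("p01", "control", list(c("the", "boy", "is", "falling")))
#' @export
transcript <- function(id, label, sentences) {
  label <- match.arg(label, c("positive", "control"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("`id` must be a single non-empty string", call. = FALSE)
  if (!is.list(sentences))
    stop("`sentences` must be a list of token vectors", call. = FALSE)
  sentences <- Filter(length, lapply(sentences, as.character))
  for (s in sentences) {
    if (any(grepl("[[:space:]]", s)))
      stop("tokens must not contain whitespace (transcript '", id, "')",
           call. = FALSE)
  }
  structure(list(id = id, label = label, sentences = sentences),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript '%s' [%s]: %d sentences, %d tokens>\n",
              x$id, x$label, length(x$sentences),
              sum(lengths(x$sentences))))
  invisible(x)
}

#' Tokenize a sentence string
#'
#' Lowercases, strips punctuation, and splits on whitespace. Internal
#' apostrophes are preserved (\code{"don't"} stays one token); leading and
#' trailing apostrophes and all other punctuation are removed. Tokens that
#' become empty are dropped.
#'
#' @param text Character vector of sentence strings.
#' @return For a single string, a character vector of tokens; for a vector,
#'   a list of token vectors.
#' @examples
#' tokenize("The boy, falling!")   # "the" "boy" "falling"
#' tokenize("don't stop")          # "don't" "stop"
#' @export
tokenize <- function(text) {
  one <- function(x) {
    x <- tolower(x)
    # every character that is not a letter, digit or apostrophe separates
    x <- gsub("[^a-z0-9']+", " ", x)
    toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
    toks <- gsub("^'+|'+$", "", toks)
    toks[nzchar(toks)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

# Strip a minimal-CHAT utterance line down to plain text.
# Removes the speaker prefix, [...] annotation groups (replacement,
# retracing, error codes), fillers starting with & or +, and the
# parenthesis marks of shortened words ("(be)cause" -> "because").
clean_chat_line <- function(line) {
  x <- sub("^\\*[A-Za-z0-9]+:\\s*", "", line)
  x <- gsub("\\[[^]]*\\]", " ", x)           # bracketed codes
  x <- gsub("<|>", " ", x)                   # retrace scope marks
  x <- gsub("(^|\\s)[&+][^\\s]*", " ", x, perl = TRUE)  # fillers/joiners
  x <- gsub("\\(|\\)", "", x)                # keep shortened-word letters
  x
}

read_one_transcript <- function(file, format, label, speaker) {
  lines <- tryCatch(readLines(file, encoding = "UTF-8", warn = FALSE),
                    error = function(e)
                      stop("cannot read transcript file '", file, "': ",
                           conditionMessage(e), call. = FALSE))
  if (format == "chat_minimal") {
    keep <- grepl("^\\*[A-Za-z0-9]+:", lines)
    if (!is.null(speaker))
      keep <- keep & grepl(paste0("^\\*", speaker, ":"), lines)
    lines <- vapply(lines[keep], clean_chat_line, character(1),
                    USE.NAMES = FALSE)
  }
  sentences <- Filter(length, lapply(lines, tokenize))
  id <- sub("\\.[A-Za-z]+$", "", basename(file))
  if (length(sentences) == 0L) return(NULL)
  transcript(id, label, sentences)
}

#' Load labeled transcripts from a file or directory
#'
#' Reads one transcript per file. Plain format is UTF-8 text, one sentence
#' per line. The minimal CHAT dialect keeps only speaker-prefixed utterance
#' lines (\code{*PAR:} ...), strips the speaker prefix, bracketed annotation
#' codes and non-word symbols, and drops dependent tiers (\code{\%} lines)
#' before tokenization.
#'
#' @param path A directory (all regular files inside are read, sorted by
#'   name) or a single file.
#' @param format \code{"plain"} or \code{"chat_minimal"}.
#' @param label Label applied to every transcript read:
#'   \code{"positive"} or \code{"control"}.
#' @param speaker For \code{chat_minimal}, the speaker code whose utterances
#'   are kept (default \code{"PAR"}, the participant). Use \code{NULL} to
#'   keep all speakers.
#' @return A list of \code{\link{transcript}} objects. Files that are empty
#'   after cleaning are excluded with a warning.
#' @export
load_transcripts <- function(path, format = c("plain", "chat_minimal"),
                             label = c("positive", "control"),
                             speaker = "PAR") {
  format <- match.arg(format)
  label <- match.arg(label)
  if (!file.exists(path))
    stop("path does not exist: '", path, "'", call. = FALSE)
  files <- if (dir.exists(path)) {
    # .tsv sidecars (e.g. a labels table next to fixture files) are not
    # transcripts
    sort(list.files(path, full.names = TRUE))
  } else path
  files <- files[!dir.exists(files) & !grepl("\\.tsv$", files)]
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    tr <- read_one_transcript(files[i], format, label, speaker)
    if (is.null(tr)) {
      warning("transcript '", files[i],
              "' is empty after cleaning; excluded", call. = FALSE)
    }
    out[[i]] <- tr
  }
  out <- Filter(Negate(is.null), out)
  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out
}

#' Write transcripts to disk
#'
#' Plain format writes one sentence per line (tokens space-joined).
#' Chat format writes minimal CHAT files with \code{*PAR:} utterance lines.
#' Both round-trip through \code{\link{load_transcripts}}.
#'
#' @param transcripts List of \code{\link{transcript}} objects.
#' @param dir Output directory (created if needed).
#' @param format \code{"plain"} or \code{"chat_minimal"}.
#' @return Invisibly, the paths written.
#' @export
write_transcripts <- function(transcripts, dir,
                              format = c("plain", "chat_minimal")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "plain") ".txt" else ".cha"
  paths <- character(length(transcripts))
  for (i in seq_along(transcripts)) {
    tr <- transcripts[[i]]
    path <- file.path(dir, paste0(tr$id, ext))
    lines <- vapply(tr$sentences, paste, character(1), collapse = " ")
    if (format == "chat_minimal") {
      lines <- paste0("*PAR:\t", lines, " .")
      lines <- c("@Begin", "@Participants:\tPAR Participant", lines, "@End")
    }
    writeLines(lines, path, useBytes = TRUE)
    paths[i] <- path
  }
  invisible(paths)
}

transcript_labels <- function(transcripts)
  vapply(transcripts, `[[`, character(1), "label")

transcript_ids <- function(transcripts)
  vapply(transcripts, `[[`, character(1), "id")
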