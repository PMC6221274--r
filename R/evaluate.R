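#' Percent classification error
#'
#' @param predicted,truth Equal-length label vectors.
#' @return 100 times the misclassification fraction.
#' @examples
#' percent_error(c("a", "a", "b"), c("a", "b", "b"))  # 33.3...
#' @export
percent_error <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0L)
    stop("`predicted` and `truth` must be equal-length and nonempty",
         call. = FALSE)
  100 * mean(as.character(predicted) != as.character(truth))
}

#' Base-2 perplexity of true-class probabilities
#'
#' \eqn{B(q) = -\frac{1}{N}\sum_i \log_2 q(x_i)} and perplexity
#' \eqn{2^{B(q)}}. For a proper binary classifier, 1 means perfect
#' prediction and 2 means uninformative.
#'
#' @param q Probabilities assigned to the true outcomes, all in (0, 1].
#' @return Single number >= 1.
#' @examples
#' perplexity(c(0.5, 0.5, 0.5))  # 2
#' perplexity(c(0.5, 1.0))       # sqrt(2)
#' @export
perplexity <- function(q) {
  if (length(q) == 0L) stop("`q` must be nonempty", call. = FALSE)
  if (any(q <= 0))
    stop("zero probability encountered; apply a numerical floor upstream",
         call. = FALSE)
  if (any(q > 1)) stop("probabilities must be <= 1", call. = FALSE)
  2^(-mean(log2(q)))
}

#' Enumerate leave-pair-out cross-validation rounds
#'
#' Every (positive, negative) id pair is held out exactly once, giving
#' \code{length(pos_ids) * length(neg_ids)} rounds; each round trains on
#' the remaining ids.
#'
#' @param pos_ids,neg_ids Character vectors of ids (each of length >= 2).
#' @return Data frame with columns \code{round}, \code{pos}, \code{neg}.
#' @export
lpocv_pairs <- function(pos_ids, neg_ids) {
  if (length(pos_ids) < 2L || length(neg_ids) < 2L)
    stop("leave-pair-out needs at least 2 ids per class", call. = FALSE)
  if (length(intersect(pos_ids, neg_ids)))
    stop("positive and negative id sets overlap", call. = FALSE)
  g <- expand.grid(pos = pos_ids, neg = neg_ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(round = seq_len(nrow(g)), g)
}

#' AUC by pairwise comparison of precomputed scores
#'
#' The Wilcoxon-Mann-Whitney estimate: the fraction of (positive,
#' negative) pairs where the positive example scores strictly higher. Under
#' the literal comparison rule (\code{tie = "strict"}, the default) a tied
#' pair contributes 0; \code{tie = "half"} awards the conventional 0.5.
#'
#' @param scores Numeric classifier confidences.
#' @param labels Matching labels; the alphabetically second level is the
#'   positive class (so \code{"positive"} beats \code{"control"}), or a
#'   factor whose second level is positive.
#' @param tie \code{"strict"} or \code{"half"}.
#' @return AUC in [0, 1].
#' @export
pairwise_auc <- function(scores, labels, tie = c("strict", "half")) {
  tie <- match.arg(tie)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("need exactly two classes", call. = FALSE)
  sp <- scores[as.integer(f) == 2L]
  sn <- scores[as.integer(f) == 1L]
  cmp <- outer(sp, sn, `>`)
  a <- sum(cmp)
  if (tie == "half") a <- a + 0.5 * sum(outer(sp, sn, `==`))
  a / (length(sp) * length(sn))
}

#' Leave-pair-out cross-validated AUC
#'
#' Runs every round of \code{\link{lpocv_pairs}}: a scoring function is
#' fitted on the training remainder and scores the held-out pair; the pair
#' contributes 1 when the positive member scores strictly higher (ties 0
#' under the literal rule, 0.5 with \code{tie = "half"}). Per-round seeds
#' are derived deterministically from the master seed.
#'
#' @param score_fun Function \code{(train_ids, test_ids, seed)} returning a
#'   numeric vector of confidences named by \code{test_ids} (higher = more
#'   positive).
#' @param pos_ids,neg_ids Ids of the positive and negative examples.
#' @param seed Master seed; round r trains with a seed drawn under it.
#' @param tie Tie rule, see \code{\link{pairwise_auc}}.
#' @param max_rounds Optional cap: a uniformly sampled (seeded) subset of
#'   rounds for expensive trainers. Default runs the full enumeration.
#' @return List with \code{auc}, \code{n_pos}, \code{n_neg} and
#'   \code{rounds}, a data frame (round, pos, neg, pos_score, neg_score, c).
#' @export
lpocv_auc <- function(score_fun, pos_ids, neg_ids, seed = 1L,
                      tie = c("strict", "half"), max_rounds = NULL) {
  tie <- match.arg(tie)
  pairs <- lpocv_pairs(pos_ids, neg_ids)
  with_seed(seed, {
    round_seeds <- sample.int(.Machine$integer.max - 1L, nrow(pairs))
    if (!is.null(max_rounds) && max_rounds < nrow(pairs)) {
      keep <- sort(sample.int(nrow(pairs), max_rounds))
      pairs <- pairs[keep, , drop = FALSE]
      round_seeds <- round_seeds[keep]
    }
  })
  all_ids <- c(pos_ids, neg_ids)
  pairs$pos_score <- NA_real_
  pairs$neg_score <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    test_ids <- c(pairs$pos[i], pairs$neg[i])
    train_ids <- setdiff(all_ids, test_ids)
    s <- tryCatch(score_fun(train_ids, test_ids, round_seeds[i]),
                  error = function(e)
                    stop("trainer failed in LPOCV round ", pairs$round[i],
                         " (", pairs$pos[i], " vs ", pairs$neg[i], "): ",
                         conditionMessage(e), call. = FALSE))
    pairs$pos_score[i] <- s[[pairs$pos[i]]]
    pairs$neg_score[i] <- s[[pairs$neg[i]]]
  }
  cval <- as.numeric(pairs$pos_score > pairs$neg_score)
  if (tie == "half")
    cval[pairs$pos_score == pairs$neg_score] <- 0.5
  pairs$c <- cval
  # mean over evaluated rounds: equals (1/|P||N|) sum c(p, n) under the
  # default full enumeration, and stays unbiased under round subsampling
  list(auc = mean(cval),
       n_pos = length(pos_ids), n_neg = length(neg_ids),
       rounds = pairs)
}

#' Hanley-McNeil variance of an AUC estimate
#'
#' \deqn{\sigma^2 = \frac{A(1-A) + (n_P-1)(Q_1-A^2) + (n_N-1)(Q_2-A^2)}
#'   {n_P n_N}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}.
#'
#' @param a AUC in [0, 1].
#' @param n_pos,n_neg Class sizes (>= 1).
#' @return Nonnegative variance; 0 at \code{a} = 0 or 1.
#' @export
auc_variance <- function(a, n_pos, n_neg) {
  if (any(a < 0 | a > 1)) stop("AUC must lie in [0, 1]", call. = FALSE)
  if (any(n_pos < 1) || any(n_neg < 1))
    stop("class sizes must be >= 1", call. = FALSE)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
    (n_pos * n_neg)
}

#' Standard error, confidence interval and p-value for an AUC
#'
#' Converts the AUC standard deviation \eqn{\sqrt{\sigma^2}} to a standard
#' error, forms a normal \eqn{(1-\alpha)} confidence interval about the
#' AUC (reported unclipped; lower bounds may be negative and upper bounds
#' may exceed 1 — set \code{truncate} to cap the displayed bounds at
#' [0, 1]), and tests the AUC against the uninformative value 0.5 with a
#' two-sided z-test.
#'
#' @param a AUC estimate.
#' @param variance Its variance (e.g. \code{\link{auc_variance}}).
#' @param n_pos,n_neg Class sizes.
#' @param alpha Significance level (default 0.05).
#' @param se_scale How the sd is converted to a standard error:
#'   \code{"total_n"} divides by \eqn{\sqrt{n_P + n_N}} (default),
#'   \code{"pair_product"} by \eqn{\sqrt{n_P n_N}}, and \code{"none"}
#'   uses the sd itself (the conventional reading of the Hanley-McNeil
#'   variance as the sampling variance of the estimate).
#' @param truncate Cap the reported interval at [0, 1] (default FALSE).
#' @return List with \code{sd}, \code{se}, \code{ci_low}, \code{ci_high}
#'   and \code{p_value}.
#' @export
auc_significance <- function(a, variance, n_pos, n_neg, alpha = 0.05,
                             se_scale = c("total_n", "pair_product", "none"),
                             truncate = FALSE) {
  se_scale <- match.arg(se_scale)
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  sd <- sqrt(variance)
  se <- switch(se_scale,
               total_n = sd / sqrt(n_pos + n_neg),
               pair_product = sd / sqrt(n_pos * n_neg),
               none = sd)
  z <- stats::qnorm(1 - alpha / 2)
  ci <- c(a - z * se, a + z * se)
  if (truncate) ci <- pmin(pmax(ci, 0), 1)
  p <- if (se == 0) {
    if (a == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(a - 0.5) / se)
  }
  list(sd = sd, se = se, ci_low = ci[1], ci_high = ci[2], p_value = p)
}

#' Assemble a full evaluation report
#'
#' @param percent_error Held-out percent error (or NA).
#' @param perplexity Held-out base-2 perplexity (or NA).
#' @param auc AUC estimate.
#' @param n_pos,n_neg Class sizes behind the AUC.
#' @param alpha,se_scale Passed to \code{\link{auc_significance}}.
#' @return An object of class \code{"eval_report"} with fields
#'   percent_error, perplexity, auc, sd, se, ci_low, ci_high, p_value,
#'   n_pos, n_neg.
#' @export
eval_report <- function(percent_error = NA_real_, perplexity = NA_real_,
                        auc, n_pos, n_neg, alpha = 0.05,
                        se_scale = "total_n") {
  v <- auc_variance(auc, n_pos, n_neg)
  sig <- auc_significance(auc, v, n_pos, n_neg, alpha, se_scale)
  structure(c(list(percent_error = percent_error, perplexity = perplexity,
                   auc = auc), sig,
              list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report: %%error %.1f | perplexity %.3f | ",
                     "AUC %.3f (sd %.3f, SE %.3f, CI %.3f..%.3f, p %.3g) ",
                     "| %d pos / %d neg>\n"),
              x$percent_error, x$perplexity, x$auc, x$sd, x$se,
              x$ci_low, x$ci_high, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param report An \code{\link{eval_report}}.
#' @param path Output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
write_eval_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(as.data.frame(unclass(report)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
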