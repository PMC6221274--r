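test_that("percent error is the misclassification percentage", {
  expect_equal(percent_error(c(rep("a", 8), "b"), rep("a", 9)), 100 / 9)
  expect_equal(percent_error(c("a", "b"), c("a", "b")), 0)
  expect_equal(percent_error(c("b", "a"), c("a", "b")), 100)
  expect_error(percent_error(character(0), character(0)), "nonempty")
})

test_that("perplexity follows the base-2 closed forms", {
  expect_equal(perplexity(c(0.5, 0.5, 0.5)), 2)
  expect_equal(perplexity(c(1, 1)), 1)
  expect_equal(perplexity(c(0.5, 1)), sqrt(2))
  expect_error(perplexity(c(0.5, 0)), "floor")
  expect_error(perplexity(c(0.5, 1.2)), "<= 1")
})

test_that("leave-pair-out enumerates |P| x |N| rounds with correct remainders", {
  p19 <- sprintf("p%02d", 1:19)
  n19 <- sprintf("n%02d", 1:19)
  expect_equal(nrow(lpocv_pairs(p19, n19)), 361)
  pr <- lpocv_pairs(c("p1", "p2"), c("n1", "n2", "n3"))
  expect_equal(nrow(pr), 6)
  expect_equal(nrow(unique(pr[c("pos", "neg")])), 6)
  expect_error(lpocv_pairs("p1", n19), "at least 2")
  # every training remainder excludes exactly the held-out pair
  score_fun <- function(train_ids, test_ids, seed) {
    expect_length(train_ids, 3)
    expect_length(intersect(train_ids, test_ids), 0)
    stats::setNames(c(1, 0), test_ids)
  }
  res <- lpocv_auc(score_fun, c("p1", "p2"), c("n1", "n2", "n3"))
  expect_equal(res$auc, 1)
  expect_equal(nrow(res$rounds), 6)
})

test_that("pairwise AUC equals the rank-statistic oracle on random scores", {
  set.seed(10)
  for (rep in 1:50) {
    np <- sample(2:20, 1)
    nn <- sample(2:20, 1)
    sp <- rnorm(np)
    sn <- rnorm(nn)
    scores <- c(sp, sn)
    labels <- rep(c("positive", "control"), c(np, nn))
    a <- pairwise_auc(scores, labels)
    w <- unname(stats::wilcox.test(sp, sn, exact = FALSE)$statistic) /
      (np * nn)
    expect_equal(a, w, tolerance = 1e-12)
  }
})

test_that("tie handling: literal rule scores 0, half rule adds half the tied mass", {
  scores <- c(1, 2, 2, 0, 2, 3)
  labels <- c("positive", "positive", "positive",
              "control", "control", "control")
  strict <- pairwise_auc(scores, labels, tie = "strict")
  half <- pairwise_auc(scores, labels, tie = "half")
  n_tied <- sum(outer(scores[1:3], scores[4:6], `==`))
  expect_equal(half - strict, 0.5 * n_tied / 9)
  # constant scores: all ties, AUC 0 under the literal rule
  expect_equal(pairwise_auc(rep(1, 6), labels, tie = "strict"), 0)
  expect_equal(pairwise_auc(rep(1, 6), labels, tie = "half"), 0.5)
  # label swap maps A to 1 - A when ties are absent
  set.seed(2)
  s <- rnorm(12)
  l <- rep(c("positive", "control"), 6)
  l_swapped <- ifelse(l == "positive", "control", "positive")
  expect_equal(pairwise_auc(s, l), 1 - pairwise_auc(s, l_swapped))
})

test_that("AUC variance follows the Hanley-McNeil closed form", {
  expect_equal(auc_variance(1, 7, 9), 0)
  expect_equal(auc_variance(0, 7, 9), 0)
  expect_equal(auc_variance(0.5, 1, 1), 0.25)
  # independent implementation of the published formula
  hm <- function(A, nP, nN) {
    Q1 <- A / (2 - A)
    Q2 <- 2 * A * A / (1 + A)
    num <- A - A * A + (nP - 1) * (Q1 - A * A) + (nN - 1) * (Q2 - A * A)
    num / (nP * nN)
  }
  for (A in seq(0.1, 0.9, by = 0.1))
    for (nP in c(5, 10, 50))
      for (nN in c(5, 10, 50)) {
        v <- auc_variance(A, nP, nN)
        expect_equal(v, hm(A, nP, nN), tolerance = 1e-12)
        expect_gte(v, 0)
      }
  expect_error(auc_variance(1.2, 5, 5), "\\[0, 1\\]")
})

test_that("significance conversion produces the stated SE, CI and p behavior", {
  # A = 0.74 with se 0.24: normal CI spans about (0.27, 1.21), unclipped
  sig <- auc_significance(0.74, 0.24^2, 19, 19, se_scale = "none")
  expect_equal(sig$se, 0.24)
  expect_equal(sig$ci_low, 0.74 - qnorm(0.975) * 0.24, tolerance = 1e-12)
  expect_equal(sig$ci_high, 0.74 + qnorm(0.975) * 0.24, tolerance = 1e-12)
  expect_gt(sig$ci_high, 1)  # reported unclipped
  trunc <- auc_significance(0.74, 0.24^2, 19, 19, se_scale = "none",
                            truncate = TRUE)
  expect_equal(trunc$ci_high, 1)
  # sd -> SE conversion by sqrt(total N)
  sig2 <- auc_significance(0.74, 1.5^2, 19, 19, se_scale = "total_n")
  expect_equal(sig2$se, 1.5 / sqrt(38), tolerance = 1e-12)
  sig3 <- auc_significance(0.74, 1.5^2, 19, 19, se_scale = "pair_product")
  expect_equal(sig3$se, 1.5 / sqrt(361), tolerance = 1e-12)
  # null and degenerate p-values
  expect_equal(auc_significance(0.5, 0.04, 5, 5)$p_value, 1)
  deg <- auc_significance(0.8, 0, 5, 5)
  expect_equal(deg$p_value, 0)
  expect_equal(deg$ci_low, deg$ci_high)
  # p monotone decreasing in |A - 0.5| at fixed se
  ps <- vapply(c(0.55, 0.65, 0.75, 0.85), function(a)
    auc_significance(a, 0.01, 10, 10, se_scale = "none")$p_value,
    numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("evaluation reports assemble and export coherently", {
  rep <- eval_report(percent_error = 11.1, perplexity = 1.5, auc = 0.74,
                     n_pos = 19, n_neg = 19)
  expect_s3_class(rep, "eval_report")
  expect_true(rep$ci_low <= rep$auc && rep$auc <= rep$ci_high)
  expect_equal(rep$sd, sqrt(auc_variance(0.74, 19, 19)))
  dir <- withr::local_tempdir()
  write_eval_report(rep, file.path(dir, "r.json"), "json")
  write_eval_report(rep, file.path(dir, "r.tsv"), "tsv")
  back <- jsonlite::read_json(file.path(dir, "r.json"),
                              simplifyVector = TRUE)
  expect_equal(back$auc, 0.74)
  tsv <- utils::read.delim(file.path(dir, "r.tsv"))
  expect_equal(tsv$percent_error, 11.1)
})

test_that("LPOCV on precomputed scores equals direct pairwise counting", {
  set.seed(3)
  ids <- c(sprintf("p%d", 1:4), sprintf("n%d", 1:4))
  fixed <- stats::setNames(rnorm(8), ids)
  score_fun <- function(train_ids, test_ids, seed) fixed[test_ids]
  res <- lpocv_auc(score_fun, ids[1:4], ids[5:8])
  labels <- rep(c("positive", "control"), each = 4)
  expect_equal(res$auc, pairwise_auc(fixed, labels))
  # subsampled rounds stay within [0, 1] and reproducible under the seed
  r1 <- lpocv_auc(score_fun, ids[1:4], ids[5:8], seed = 9, max_rounds = 6)
  r2 <- lpocv_auc(score_fun, ids[1:4], ids[5:8], seed = 9, max_rounds = 6)
  expect_identical(r1$rounds, r2$rounds)
  expect_equal(nrow(r1$rounds), 6)
})
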