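test_that("extract_ngrams returns the L - n + 1 contiguous windows in order", {
  toks <- c("the", "boy", "is", "on", "the", "stool")
  expect_equal(extract_ngrams(toks, 4),
               c("the boy is on", "boy is on the", "is on the stool"))
  expect_equal(extract_ngrams(c("a", "b"), 4), character(0))
  expect_equal(extract_ngrams(c("a", "b", "c"), 1), c("a", "b", "c"))
  expect_error(extract_ngrams(toks, 0), ">= 1")
  # property: output length is sum over sentences of max(0, L - n + 1)
  set.seed(1)
  for (rep in 1:20) {
    L <- sample(1:10, 1)
    n <- sample(1:5, 1)
    toks <- sample(letters, L, replace = TRUE)
    expect_length(extract_ngrams(toks, n), max(0, L - n + 1))
  }
})

test_that("vocabulary accounting matches independent enumeration, orders 1-5", {
  trs <- toy_corpus()
  # frozen hand enumeration for the two-transcript corpus
  hand <- data.frame(order = 1:5,
                     pos = c(8, 7, 5, 3, 1),
                     ctl = c(6, 6, 4, 2, 0),
                     unique = c(10, 10, 7, 4, 1))
  for (i in seq_len(nrow(hand))) {
    v <- build_vocabulary(trs, hand$order[i])
    expect_equal(unname(v$per_group_counts[["positive"]]), hand$pos[i])
    expect_equal(unname(v$per_group_counts[["control"]]), hand$ctl[i])
    expect_equal(v$unique_count, hand$unique[i])
    expect_equal(v$total_count, hand$pos[i] + hand$ctl[i])
    # cross-check against the independent enumerator
    by_class <- lapply(split(trs, vapply(trs, `[[`, "", "label")),
                       function(g) unlist(lapply(g, function(t)
                         enumerate_ngrams(t$sentences, hand$order[i]))))
    expect_equal(unname(v$per_group_counts[["control"]]),
                 length(unique(by_class$control)))
    expect_setequal(v$entries, unique(unlist(by_class)))
  }
})

test_that("vocabulary counts are invariant to transcript order", {
  trs <- small_corpus(0.5, seed = 6, n_per_group = 5L)
  v1 <- build_vocabulary(trs, 4)
  v2 <- build_vocabulary(rev(trs), 4)
  expect_equal(v1$per_group_counts, v2$per_group_counts)
  expect_equal(v1$unique_count, v2$unique_count)
  expect_setequal(v1$entries, v2$entries)
})

test_that("degenerate class overlap cases behave as counted", {
  same <- list(transcript("a", "positive", list(c("x", "y", "z"))),
               transcript("b", "control", list(c("x", "y", "z"))))
  v <- build_vocabulary(same, 2)
  expect_equal(unname(v$per_group_counts), c(2L, 2L))
  expect_equal(v$unique_count, 2L)
  expect_equal(v$total_count, 2L * v$unique_count)
  disjoint <- list(transcript("a", "positive", list(c("x", "y"))),
                   transcript("b", "control", list(c("p", "q"))))
  vd <- build_vocabulary(disjoint, 2)
  expect_equal(vd$unique_count, vd$total_count)
})

test_that("document vectors record presence or counts and ignore OOV", {
  trs <- toy_corpus()
  v <- build_vocabulary(trs[1], 2)  # vocabulary from the positive file only
  x <- vectorize_transcripts(trs, v, "binary")
  expect_equal(dim(x), c(2L, v$unique_count))
  expect_true(all(x@x %in% 1))
  expect_equal(sum(x["A", ]), v$unique_count)  # every vocab bigram present
  # control transcript only matches its shared bigrams; its OOV bigrams drop
  shared <- intersect(v$entries,
                      enumerate_ngrams(trs[[2]]$sentences, 2))
  expect_equal(sum(x["B", ]), length(shared))
  # count mode: repeated n-gram counted
  rep_tr <- list(transcript("r", "positive",
                            list(c("x", "y"), c("x", "y"))))
  vr <- build_vocabulary(rep_tr, 2)
  xc <- vectorize_transcripts(rep_tr, vr, "count")
  expect_equal(as.numeric(xc[1, "x y"]), 2)
  # all sentences shorter than n gives an all-zero row
  short <- vectorize_transcripts(list(transcript("s", "control",
                                                 list(c("q")))), v)
  expect_equal(sum(short), 0)
})

test_that("vocabulary and matrix exports round-trip", {
  trs <- toy_corpus()
  v <- build_vocabulary(trs, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(v, path)
  v2 <- read_vocabulary(path)
  expect_equal(v2$entries, v$entries)
  expect_equal(v2$entry_counts, v$entry_counts)
  expect_equal(v2$order, v$order)
  x <- vectorize_transcripts(trs, v)
  stem <- file.path(withr::local_tempdir(), "dtm")
  write_dtm(x, stem)
  m <- Matrix::readMM(paste0(stem, ".mtx"))
  # a binary matrix may come back as a pattern matrix; compare numerically
  expect_equal(1 * as.matrix(m), unname(as.matrix(x)))
  expect_equal(readLines(paste0(stem, ".rows.txt")), rownames(x))
})

test_that("full-rank SVD preserves geometry; truncation error is monotone", {
  set.seed(3)
  x <- matrix(rbinom(6 * 9, 1, 0.4), 6, 9)
  rownames(x) <- paste0("t", 1:6)
  full <- svd_reduce(x, k = "auto")
  expect_equal(full$k, 6)
  d1 <- as.matrix(dist(x))
  d2 <- as.matrix(dist(full$scores))
  expect_lt(max(abs(d1 - d2)), 1e-8)
  expect_true(all(diff(full$singular_values) <= 1e-12))
  expect_lt(max(abs(svd_reconstruct(full) - x)), 1e-8)
  errs <- vapply(1:6, function(k)
    sqrt(sum((svd_reconstruct(svd_reduce(x, k = k)) - x)^2)), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("SVD edge cases: identity, rank-1, and admissible-rank errors", {
  id <- diag(4)
  rownames(id) <- paste0("r", 1:4)
  red <- svd_reduce(id)
  expect_equal(red$singular_values, rep(1, 4))
  gram <- crossprod(t(red$scores))
  expect_lt(max(abs(gram - diag(4))), 1e-10)
  r1 <- outer(c(1, 2, 3), c(1, 0, 2))
  rownames(r1) <- paste0("r", 1:3)
  sv <- svd_reduce(r1)$singular_values
  expect_lt(max(sv[-1]), 1e-10)
  expect_gt(sv[1], 0)
  expect_error(svd_reduce(id, k = 5), "between 1 and")
})

test_that("held-out rows are projected through the fitted basis", {
  trs <- small_corpus(0.6, seed = 8, n_per_group = 6L)
  v <- build_vocabulary(trs, 2)
  x <- vectorize_transcripts(trs, v)
  fit_ids <- rownames(x)[1:8]
  red <- svd_reduce(x, fit_rows = fit_ids)
  expect_equal(red$fit_scope, "train_only")
  expect_equal(red$k, min(8, ncol(x)))
  # projection identity: scores of any row equal x %*% basis
  expect_equal(red$scores, as.matrix(x) %*% red$basis,
               ignore_attr = TRUE)
  expect_equal(predict(red, x[9:12, , drop = FALSE]),
               red$scores[9:12, , drop = FALSE])
})
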