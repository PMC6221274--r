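#' Configuration for a full classification run
#'
#' Validates the settings tying the pipeline together: which model
#' consumes which feature representation, the split, the grid, and the
#' evaluation mode. The deep model on reduced features (\code{"d2nnlm"})
#' requires SVD features; the sparse-input networks (\code{"nnlm"}, one
#' hidden layer, and \code{"dnnlm"}, three) consume the raw sparse n-gram
#' vectors; \code{"ngram_lm"} is the conventional class-conditional
#' baseline.
#'
#' @param model One of \code{"nnlm"}, \code{"dnnlm"}, \code{"d2nnlm"},
#'   \code{"ngram_lm"}.
#' @param ngram_order N-gram order (default 4).
#' @param use_svd Reduce the document matrix by SVD (default: TRUE exactly
#'   for \code{"d2nnlm"}).
#' @param svd_k \code{"auto"} (full admissible rank) or an integer.
#' @param fit_scope \code{"train_only"} (default: SVD basis and vocabulary
#'   from training rows only, held-out rows projected) or
#'   \code{"full_corpus"}.
#' @param feature_mode \code{"binary"} or \code{"count"} document vectors.
#' @param standardize Center and scale the SVD coordinates by the training
#'   rows' statistics before network training (default TRUE; ignored for
#'   sparse-input models). Keeps the tanh hidden layers away from
#'   saturation at initialization.
#' @param proportions Train/test/validation fractions (default
#'   0.5/0.25/0.25).
#' @param hidden_layers Hidden layers for the neural models (default: 1
#'   for nnlm, 3 otherwise).
#' @param hidden_units_grid,batch_size_grid Grid-search candidates.
#' @param epochs,learning_rate,l1,l2 Passed to
#'   \code{\link{network_config}}.
#' @param evaluation \code{"holdout"} or \code{"lpocv"}.
#' @param tie AUC tie rule (see \code{\link{pairwise_auc}}).
#' @param se_scale See \code{\link{auc_significance}}.
#' @param max_rounds Optional LPOCV round subsample cap.
#' @param seed Master seed.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(model = c("d2nnlm", "dnnlm", "nnlm", "ngram_lm"),
                       ngram_order = 4L, use_svd = NULL, svd_k = "auto",
                       fit_scope = c("train_only", "full_corpus"),
                       feature_mode = c("binary", "count"),
                       standardize = TRUE,
                       proportions = c(0.5, 0.25, 0.25),
                       hidden_layers = NULL,
                       hidden_units_grid = c(5L, 11L, 19L),
                       batch_size_grid = 1:10,
                       epochs = 500L, learning_rate = 0.01,
                       l1 = 1e-4, l2 = 1e-4,
                       evaluation = c("holdout", "lpocv"),
                       tie = c("strict", "half"),
                       se_scale = "total_n", max_rounds = NULL,
                       seed = 1L) {
  model <- match.arg(model)
  fit_scope <- match.arg(fit_scope)
  feature_mode <- match.arg(feature_mode)
  evaluation <- match.arg(evaluation)
  tie <- match.arg(tie)
  use_svd <- use_svd %||% (model == "d2nnlm")
  if (model == "d2nnlm" && !use_svd)
    stop_config("model 'd2nnlm' requires SVD-reduced features ",
                "(use_svd = TRUE)")
  if (model %in% c("nnlm", "dnnlm") && use_svd)
    stop_config("models 'nnlm'/'dnnlm' consume the raw sparse n-gram ",
                "representation (use_svd = FALSE)")
  hidden_layers <- as.integer(hidden_layers %||%
                                (if (model == "nnlm") 1L else 3L))
  if (model == "nnlm" && hidden_layers != 1L)
    stop_config("model 'nnlm' has exactly 1 hidden layer")
  structure(list(model = model, ngram_order = as.integer(ngram_order),
                 use_svd = use_svd, svd_k = svd_k, fit_scope = fit_scope,
                 feature_mode = feature_mode, standardize = standardize,
                 proportions = proportions,
                 hidden_layers = hidden_layers,
                 hidden_units_grid = as.integer(hidden_units_grid),
                 batch_size_grid = as.integer(batch_size_grid),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, l1 = l1, l2 = l2,
                 evaluation = evaluation, tie = tie, se_scale = se_scale,
                 max_rounds = max_rounds, seed = as.integer(seed)),
            class = "run_config")
}

# Feature matrix over all transcripts: vocabulary (and SVD basis, when
# used) fitted on `fit_ids` only under train_only scope; every row is
# then represented in that space. Continuous SVD coordinates are
# standardized by the fit rows' means and standard deviations so the tanh
# layers start in their active range.
build_features <- function(transcripts, config, fit_ids = NULL) {
  fit_set <- if (is.null(fit_ids) || config$fit_scope == "full_corpus")
    transcripts else subset_transcripts(transcripts, fit_ids)
  vocab <- build_vocabulary(fit_set, config$ngram_order)
  dtm <- vectorize_transcripts(transcripts, vocab, config$feature_mode)
  if (!config$use_svd)
    return(list(x = as.matrix(dtm), vocab = vocab, reducer = NULL))
  fit_rows <- if (config$fit_scope == "full_corpus") rownames(dtm)
              else intersect(rownames(dtm), fit_ids)
  red <- svd_reduce(dtm, k = config$svd_k,
                    fit_rows = if (config$fit_scope == "full_corpus") NULL
                               else fit_rows)
  x <- red$scores
  if (isTRUE(config$standardize)) {
    ctr <- colMeans(x[fit_rows, , drop = FALSE])
    scl <- pmax(apply(x[fit_rows, , drop = FALSE], 2, stats::sd), 1e-8)
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  }
  list(x = x, vocab = vocab, reducer = red)
}

# Scoring closure for lpocv_auc: refits vocabulary, features and model on
# each round's training remainder, then scores the held-out pair.
make_scorer <- function(transcripts, config, hidden_units, batch_size) {
  labels <- stats::setNames(transcript_labels(transcripts),
                            transcript_ids(transcripts))
  function(train_ids, test_ids, seed) {
    sub <- subset_transcripts(transcripts, c(train_ids, test_ids))
    if (config$model == "ngram_lm") {
      fit <- fit_ngram_lm(subset_transcripts(sub, train_ids),
                          config$ngram_order)
      return(vapply(test_ids, function(id) {
        classify_by_likelihood(fit,
                               subset_transcripts(sub, id)[[1]])$confidence
      }, numeric(1)))
    }
    feats <- build_features(sub, config, fit_ids = train_ids)
    bs <- min(batch_size, length(train_ids))
    cfg <- network_config(input_dim = ncol(feats$x),
                          hidden_layers = config$hidden_layers,
                          hidden_units = hidden_units,
                          epochs = config$epochs, batch_size = bs,
                          learning_rate = config$learning_rate,
                          l1 = config$l1, l2 = config$l2, seed = seed)
    m <- train_nlm(feats$x[train_ids, , drop = FALSE], labels[train_ids],
                   cfg)
    stats::setNames(predict(m, feats$x[test_ids, , drop = FALSE],
                            type = "score"), test_ids)
  }
}

#' Run the full classification pipeline
#'
#' Load (or accept) labeled transcripts, build the n-gram feature space,
#' reduce it when configured, split, grid-search the network, and
#' evaluate — by held-out percent error/perplexity/AUC, or by full
#' leave-pair-out cross-validation. All artifacts (report, grid table,
#' model, split, per-round scores, manifest) are written to
#' \code{out_dir} and are byte-identical across runs with the same
#' configuration and seed.
#'
#' @param transcripts Labeled list of \code{\link{transcript}} objects,
#'   or \code{NULL} to load from \code{pos_dir}/\code{neg_dir}.
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory (created; \code{NULL} writes nothing).
#' @param pos_dir,neg_dir,format Transcript directories per class and
#'   their on-disk format, used when \code{transcripts} is NULL.
#' @return An \code{\link{eval_report}} (invisibly also written to disk),
#'   with the grid table and split attached as attributes
#'   \code{"grid"} and \code{"split"}.
#' @export
run_pipeline <- function(transcripts = NULL, config = run_config(),
                         out_dir = NULL, pos_dir = NULL, neg_dir = NULL,
                         format = "plain") {
  if (is.null(transcripts)) {
    if (is.null(pos_dir) || is.null(neg_dir))
      stop_config("supply `transcripts` or both `pos_dir` and `neg_dir`")
    transcripts <- c(load_transcripts(pos_dir, format, "positive"),
                     load_transcripts(neg_dir, format, "control"))
  }
  labels <- stats::setNames(transcript_labels(transcripts),
                            transcript_ids(transcripts))
  if (length(unique(labels)) < 2L)
    stop_data("both classes must be present in the input transcripts")

  split <- make_split(transcripts, config$proportions, seed = config$seed)
  feats <- build_features(transcripts, config, fit_ids = split$train_ids)
  x <- feats$x

  if (config$model == "ngram_lm") {
    fit <- fit_ngram_lm(subset_transcripts(transcripts, split$train_ids),
                        config$ngram_order)
    cls <- lapply(split$test_ids, function(id)
      classify_by_likelihood(fit, subset_transcripts(transcripts, id)[[1]]))
    test_pred <- vapply(cls, `[[`, character(1), "label")
    scores <- vapply(cls, `[[`, numeric(1), "confidence")
    err <- percent_error(test_pred, labels[split$test_ids])
    # probability the model side of the likelihood ratio assigns the truth
    q <- stats::plogis(ifelse(labels[split$test_ids] == "positive", 1, -1) *
                         scores * log(2))
    perp <- perplexity(pmax(q, 1e-12))
    grid_tab <- NULL
    best <- NULL
    best_model <- NULL
  } else {
    cfg0 <- network_config(input_dim = ncol(x),
                           hidden_layers = config$hidden_layers,
                           hidden_units = config$hidden_units_grid[1],
                           epochs = config$epochs,
                           batch_size = config$batch_size_grid[1],
                           learning_rate = config$learning_rate,
                           l1 = config$l1, l2 = config$l2,
                           seed = config$seed)
    gs <- grid_search_nlm(x[split$train_ids, , drop = FALSE],
                          labels[split$train_ids],
                          x[split$validation_ids, , drop = FALSE],
                          labels[split$validation_ids],
                          config$hidden_units_grid,
                          config$batch_size_grid, cfg0)
    grid_tab <- gs$table
    best <- gs$best_config
    best_model <- gs$best_model
    test_pred <- predict(gs$best_model, x[split$test_ids, , drop = FALSE],
                         type = "class")
    scores <- predict(gs$best_model, x[split$test_ids, , drop = FALSE],
                      type = "score")
    err <- percent_error(test_pred, labels[split$test_ids])
    perp <- model_perplexity(gs$best_model,
                             x[split$test_ids, , drop = FALSE],
                             labels[split$test_ids])
  }

  if (config$evaluation == "lpocv") {
    scorer <- make_scorer(transcripts, config,
                          hidden_units = if (is.null(best))
                            config$hidden_units_grid[1] else
                              best$hidden_units,
                          batch_size = if (is.null(best))
                            config$batch_size_grid[1] else best$batch_size)
    lp <- lpocv_auc(scorer, names(labels)[labels == "positive"],
                    names(labels)[labels == "control"],
                    seed = config$seed, tie = config$tie,
                    max_rounds = config$max_rounds)
    auc <- lp$auc
    n_pos <- lp$n_pos; n_neg <- lp$n_neg
    rounds <- lp$rounds
  } else {
    auc <- pairwise_auc(scores, labels[split$test_ids], tie = config$tie)
    n_pos <- sum(labels[split$test_ids] == "positive")
    n_neg <- sum(labels[split$test_ids] == "control")
    rounds <- NULL
  }

  report <- eval_report(percent_error = err, perplexity = perp, auc = auc,
                        n_pos = n_pos, n_neg = n_neg,
                        se_scale = config$se_scale)
  attr(report, "grid") <- grid_tab
  attr(report, "split") <- split
  attr(report, "best_config") <- best

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_eval_report(report, file.path(out_dir, "report.json"), "json")
    write_eval_report(report, file.path(out_dir, "report.tsv"), "tsv")
    jsonlite::write_json(unclass(split), file.path(out_dir, "split.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(grid_tab))
      utils::write.table(grid_tab, file.path(out_dir, "grid.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rounds))
      utils::write.table(rounds, file.path(out_dir, "rounds.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(best_model))
      save_nlm(best_model, file.path(out_dir, "model.json"))
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    manifest <- list(package = "dementialm",
                     version = as.character(utils::packageVersion("dementialm")),
                     seed = config$seed,
                     config_md5 = unname(tools::md5sum(cfg_path)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' Generate and write a synthetic fixture corpus
#'
#' @param spec A \code{\link{generator_spec}}, or a path to a JSON file of
#'   its fields.
#' @param out_dir Output directory.
#' @param format On-disk transcript format.
#' @param seed Optional seed override.
#' @return Invisibly, \code{out_dir}.
#' @export
run_simulate <- function(spec, out_dir, format = c("plain", "chat_minimal"),
                         seed = NULL) {
  format <- match.arg(format)
  if (is.character(spec)) {
    if (!file.exists(spec)) stop_config("spec file not found: ", spec)
    fields <- jsonlite::read_json(spec, simplifyVector = TRUE)
    spec <- do.call(generator_spec, fields)
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  write_fixture(make_groups(spec), out_dir, format)
  invisible(out_dir)
}

#' Hidden-layer depth sweep
#'
#' Re-runs the grid-searched holdout evaluation at each hidden-layer depth
#' and records held-out percent error and perplexity, reproducing the
#' robustness protocol of varying network depth from 2 to 5.
#'
#' @param transcripts Labeled transcripts.
#' @param config A \code{\link{run_config}} template.
#' @param layers Integer vector of depths (default 2:5).
#' @param path Optional TSV output path.
#' @return Data frame: hidden_layers, hidden_units, batch_size,
#'   percent_error, perplexity.
#' @export
depth_sweep <- function(transcripts, config = run_config(), layers = 2:5,
                        path = NULL) {
  rows <- lapply(layers, function(L) {
    cfg <- config
    cfg$hidden_layers <- as.integer(L)
    cfg$evaluation <- "holdout"
    rep <- run_pipeline(transcripts, cfg)
    best <- attr(rep, "best_config")
    data.frame(hidden_layers = L,
               hidden_units = best$hidden_units,
               batch_size = best$batch_size,
               percent_error = rep$percent_error,
               perplexity = rep$perplexity)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
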