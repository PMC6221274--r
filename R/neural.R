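#' Network configuration for the feed-forward language-model classifier
#'
#' Bundles the architecture and training hyperparameters. One hidden layer
#' gives the classic feed-forward neural language model (NNLM); three or
#' more hidden layers give the deep variants, consuming either raw sparse
#' n-gram vectors or SVD-reduced continuous features.
#'
#' @param input_dim Number of input features.
#' @param hidden_layers Number of tanh hidden layers (>= 1; default 3).
#' @param hidden_units Units per hidden layer (H).
#' @param output_classes Number of softmax outputs (default 2).
#' @param epochs Training epochs (default 500).
#' @param batch_size Minibatch size for SGD.
#' @param learning_rate Constant SGD step size (default 0.01).
#' @param l1,l2 Regularization strengths applied to all weight matrices
#'   (L1: sum of absolute values; L2: sum of squares). Defaults 1e-4 —
#'   small values close to zero.
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling.
#' @return An object of class \code{"network_config"}.
#' @export
network_config <- function(input_dim, hidden_layers = 3L, hidden_units = 11L,
                           output_classes = 2L, epochs = 500L,
                           batch_size = 9L, learning_rate = 0.01,
                           l1 = 1e-4, l2 = 1e-4, seed = 1L) {
  cfg <- list(input_dim = as.integer(input_dim),
              hidden_layers = as.integer(hidden_layers),
              hidden_units = as.integer(hidden_units),
              output_classes = as.integer(output_classes),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              l1 = as.numeric(l1), l2 = as.numeric(l2),
              seed = as.integer(seed))
  dims <- c(cfg$input_dim, cfg$hidden_layers, cfg$hidden_units,
            cfg$output_classes, cfg$epochs, cfg$batch_size)
  if (any(is.na(dims)) || any(dims < 1L))
    stop("all dimensions and counts must be positive integers",
         call. = FALSE)
  if (cfg$learning_rate <= 0) stop("`learning_rate` must be > 0",
                                   call. = FALSE)
  if (cfg$l1 < 0 || cfg$l2 < 0) stop("`l1` and `l2` must be >= 0",
                                     call. = FALSE)
  structure(cfg, class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(paste0("<network_config: %d -> %s -> %d softmax; ",
                     "%d epochs, batch %d, lr %g, l1 %g, l2 %g, seed %d>\n"),
              x$input_dim,
              paste(rep(x$hidden_units, x$hidden_layers), collapse = " -> "),
              x$output_classes, x$epochs, x$batch_size, x$learning_rate,
              x$l1, x$l2, x$seed))
  invisible(x)
}

#' Initialize network parameters
#'
#' Weights are drawn uniformly in \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}}
#' under the configuration seed; biases start at zero.
#'
#' @param config A \code{\link{network_config}}.
#' @return A list with \code{Ws} (hidden weight matrices), \code{bs}
#'   (hidden biases), \code{V} (output weights) and \code{k} (output
#'   biases); class \code{"nlm_params"}.
#' @export
init_nlm_params <- function(config) {
  dims <- c(config$input_dim,
            rep(config$hidden_units, config$hidden_layers),
            config$output_classes)
  L <- config$hidden_layers
  with_seed(config$seed, {
    Ws <- vector("list", L)
    for (l in seq_len(L)) {
      r <- sqrt(6 / (dims[l] + dims[l + 1]))
      Ws[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -r, r),
                        dims[l], dims[l + 1])
    }
    r <- sqrt(6 / (dims[L + 1] + dims[L + 2]))
    V <- matrix(stats::runif(dims[L + 1] * dims[L + 2], -r, r),
                dims[L + 1], dims[L + 2])
  })
  bs <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
  structure(list(Ws = Ws, bs = bs, V = V, k = numeric(config$output_classes)),
            class = "nlm_params")
}

#' Forward pass: class probabilities
#'
#' Hidden activations are \eqn{d_j = \tanh(\sum_l M_{jl} c_l + b_j)};
#' outputs \eqn{o_i = \sum_j V_{ij} d_j + k_i} pass through a softmax, so
#' each returned row sums to 1.
#'
#' @param params An \code{\link{init_nlm_params}}-shaped parameter list.
#' @param x Feature matrix (rows = instances) or a single feature vector.
#' @return Matrix of class probabilities, one row per instance.
#' @export
nlm_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != nrow(params$Ws[[1]]))
    stop("feature dimension ", ncol(x), " does not match input_dim ",
         nrow(params$Ws[[1]]), call. = FALSE)
  cpp_nlm_forward(params$Ws, params$bs, params$V, params$k, x)
}

#' Regularized cross-entropy error
#'
#' Mean negative log-likelihood (natural log) of the targets under the
#' given class probabilities, plus \code{l1} times the sum of absolute
#' weights and \code{l2} times the sum of squared weights (hidden and
#' output weight matrices; biases are not penalized).
#'
#' @param probabilities Matrix of class probabilities (rows sum to 1).
#' @param targets One-hot target matrix of the same shape, or an integer
#'   vector of 1-based target column indices.
#' @param params Parameter list (used only for the penalty); may be
#'   \code{NULL} when \code{l1 = l2 = 0}.
#' @param l1,l2 Penalty strengths.
#' @return Single nonnegative number.
#' @export
nlm_loss <- function(probabilities, targets, params = NULL, l1 = 0, l2 = 0) {
  p <- as.matrix(probabilities)
  ti <- if (!is.null(dim(targets)))
    max.col(as.matrix(targets), ties.method = "first")
  else as.integer(targets)
  if (length(ti) != nrow(p))
    stop("`targets` does not match the number of probability rows",
         call. = FALSE)
  q <- p[cbind(seq_len(nrow(p)), ti)]
  if (any(q <= 0))
    stop("zero probability at a target; apply a numerical floor upstream",
         call. = FALSE)
  pen <- 0
  if (!is.null(params)) {
    w <- c(unlist(params$Ws), as.numeric(params$V))
    pen <- l1 * sum(abs(w)) + l2 * sum(w^2)
  }
  mean(-log(q)) + pen
}

encode_labels <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2L)
    stop("need exactly two classes; got ",
         paste(levels(f), collapse = ", "), call. = FALSE)
  # alphabetical order puts "control" before "positive"; the second level
  # is treated as the positive class throughout
  list(y0 = as.integer(f) - 1L, classes = levels(f))
}

#' Train the neural language-model classifier
#'
#' Minibatch stochastic gradient descent on the regularized cross-entropy
#' error for a fixed number of epochs, with seeded initialization and
#' epoch-level shuffling (the last short minibatch is kept). Deterministic:
#' the same data, configuration and seed give bitwise-identical parameters.
#'
#' @param x Feature matrix, rows = instances.
#' @param y Labels (two classes; with \code{"positive"}/\code{"control"}
#'   labels the positive class is scored by \code{predict}).
#' @param config A \code{\link{network_config}}.
#' @param x_val,y_val Optional validation set; when given, per-epoch
#'   validation percent error is recorded in the history.
#' @return An object of class \code{"nlm_model"}: list with \code{params},
#'   \code{config}, \code{classes} and \code{history} (data frame of
#'   per-epoch training loss and, if available, validation percent error).
#' @export
train_nlm <- function(x, y, config, x_val = NULL, y_val = NULL) {
  x <- as.matrix(x)
  enc <- encode_labels(y)
  if (nrow(x) != length(enc$y0))
    stop("`x` and `y` disagree on the number of instances", call. = FALSE)
  if (min(table(enc$y0)) < 1L)
    stop("need at least one example per class", call. = FALSE)
  if (config$batch_size > nrow(x))
    stop("`batch_size` exceeds the number of training examples",
         call. = FALSE)
  if (ncol(x) != config$input_dim)
    stop("feature dimension ", ncol(x), " does not match input_dim ",
         config$input_dim, call. = FALSE)
  params <- init_nlm_params(config)
  n <- nrow(x)
  with_seed(config$seed + 1L,
            order <- vapply(seq_len(config$epochs),
                            function(e) sample.int(n), integer(n)))
  if (!is.matrix(order)) order <- matrix(order, nrow = n)
  yv0 <- NULL
  if (!is.null(x_val)) {
    x_val <- as.matrix(x_val)
    yv0 <- as.integer(factor(y_val, levels = enc$classes)) - 1L
    if (anyNA(yv0))
      stop("validation labels outside training classes", call. = FALSE)
  }
  fit <- cpp_nlm_sgd(params$Ws, params$bs, params$V, params$k,
                     x, enc$y0, config$epochs, config$batch_size,
                     config$learning_rate, config$l1, config$l2,
                     order, x_val, yv0)
  if (!fit$ok)
    stop(errorCondition(
      paste0("training diverged: non-finite loss at epoch ", fit$stopped_at,
             " (learning rate ", config$learning_rate, ")"),
      class = c("dementialm_numeric_error", "error", "condition")))
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = as.numeric(fit$train_loss))
  if (!is.null(yv0)) history$val_percent_error <- as.numeric(fit$val_error)
  params <- structure(list(Ws = fit$Ws, bs = lapply(fit$bs, as.numeric),
                           V = fit$V, k = as.numeric(fit$k)),
                      class = "nlm_params")
  structure(list(params = params, config = config,
                 classes = enc$classes, history = history),
            class = "nlm_model")
}

#' @export
print.nlm_model <- function(x, ...) {
  cat(sprintf("<nlm_model: %d hidden layer(s) x %d units, classes %s; final loss %.4g>\n",
              x$config$hidden_layers, x$config$hidden_units,
              paste(x$classes, collapse = "/"),
              utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

#' Predict from a trained neural language model
#'
#' @param object An \code{\link{train_nlm}} result.
#' @param x Feature matrix or vector.
#' @param type \code{"prob"} for the class-probability matrix,
#'   \code{"class"} for argmax labels (ties go to the first class), or
#'   \code{"score"} for the positive-class probability used as the
#'   classifier confidence in AUC computations.
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.nlm_model <- function(object, x, type = c("prob", "class", "score"),
                              ...) {
  type <- match.arg(type)
  p <- nlm_forward(object$params, x)
  colnames(p) <- object$classes
  switch(type,
         prob = p,
         class = object$classes[max.col(p, ties.method = "first")],
         score = p[, 2L])
}

#' Perplexity of a trained model on labeled data
#'
#' Base-2 perplexity of the probabilities the model assigns to the true
#' classes; see \code{\link{perplexity}}.
#'
#' @param model An \code{\link{train_nlm}} result.
#' @param x,y Feature matrix and true labels.
#' @return Single number >= 1.
#' @export
model_perplexity <- function(model, x, y) {
  p <- predict(model, x, type = "prob")
  yi <- as.integer(factor(y, levels = model$classes))
  if (anyNA(yi)) stop("labels outside model classes", call. = FALSE)
  q <- p[cbind(seq_len(nrow(p)), yi)]
  perplexity(pmax(q, 1e-12))
}

#' Verify analytic gradients against central finite differences
#'
#' Perturbs every parameter by \code{h} in both directions, compares the
#' finite-difference slope of the regularized loss with the backpropagated
#' gradient, and reports the maximum relative deviation
#' \eqn{|a - f| / \max(1, |a|, |f|)}.
#'
#' @param params Parameter list (e.g. \code{\link{init_nlm_params}}).
#' @param x,y Small batch of features and labels (integer 1-based class
#'   indices or labels).
#' @param l1,l2 Penalty strengths (L1 is non-differentiable at 0; keep
#'   \code{l1 = 0} or away-from-zero weights for a meaningful check).
#' @param tol Relative tolerance (default 1e-4).
#' @param h Finite-difference step (default 1e-5).
#' @return List with \code{pass}, \code{max_rel_dev} and \code{tol}.
#' @export
gradient_check <- function(params, x, y, l1 = 0, l2 = 0,
                           tol = 1e-4, h = 1e-5) {
  x <- as.matrix(x)
  y0 <- if (is.numeric(y)) as.integer(y) - 1L else encode_labels(y)$y0
  ana <- cpp_nlm_loss_grad(params$Ws, params$bs, params$V, params$k,
                           x, y0, l1, l2)
  flat_grad <- c(unlist(ana$gW), unlist(ana$gb),
                 as.numeric(ana$gV), as.numeric(ana$gk))
  theta <- c(unlist(params$Ws), unlist(params$bs),
             as.numeric(params$V), as.numeric(params$k))
  loss_at <- function(th) {
    p <- relist_params(th, params)
    cpp_nlm_loss_grad(p$Ws, p$bs, p$V, p$k, x, y0, l1, l2)$loss
  }
  fd <- vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    (loss_at(up) - loss_at(dn)) / (2 * h)
  }, numeric(1))
  rel <- abs(flat_grad - fd) / pmax(1, abs(flat_grad), abs(fd))
  list(pass = all(rel < tol), max_rel_dev = max(rel), tol = tol)
}

relist_params <- function(theta, template) {
  out <- template
  pos <- 0L
  take <- function(n) {
    v <- theta[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  for (l in seq_along(template$Ws))
    out$Ws[[l]] <- matrix(take(length(template$Ws[[l]])),
                          nrow(template$Ws[[l]]), ncol(template$Ws[[l]]))
  for (l in seq_along(template$bs))
    out$bs[[l]] <- take(length(template$bs[[l]]))
  out$V <- matrix(take(length(template$V)), nrow(template$V),
                  ncol(template$V))
  out$k <- take(length(template$k))
  out
}

#' Grid search over hidden units and batch sizes
#'
#' Trains one model per (hidden units, batch size) grid cell and selects
#' the cell with the lowest held-out percent error; ties are broken by
#' lower perplexity, then fewer hidden units, then smaller batch size.
#'
#' @param x_train,y_train Training set.
#' @param x_val,y_val Held-out set used for selection (validation by
#'   default; pass the test set to mimic test-set selection).
#' @param hidden_units_grid,batch_size_grid Integer vectors of candidate
#'   values (nonempty).
#' @param config Template \code{\link{network_config}} supplying every
#'   other setting; its \code{hidden_units}/\code{batch_size} are
#'   overridden cell by cell.
#' @return List with \code{best_config}, \code{best_model} (retrained at
#'   the winning cell) and \code{table}, a data frame with one row per
#'   cell (hidden_units, batch_size, percent_error, perplexity).
#' @export
grid_search_nlm <- function(x_train, y_train, x_val, y_val,
                            hidden_units_grid, batch_size_grid, config) {
  if (!length(hidden_units_grid) || !length(batch_size_grid))
    stop("grids must be nonempty", call. = FALSE)
  grid <- expand.grid(hidden_units = as.integer(hidden_units_grid),
                      batch_size = as.integer(batch_size_grid))
  grid$percent_error <- NA_real_
  grid$perplexity <- NA_real_
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$hidden_units <- grid$hidden_units[i]
    cfg$batch_size <- grid$batch_size[i]
    m <- train_nlm(x_train, y_train, cfg)
    grid$percent_error[i] <- percent_error(predict(m, x_val, type = "class"),
                                           y_val)
    grid$perplexity[i] <- model_perplexity(m, x_val, y_val)
    models[[i]] <- m
  }
  best <- select_grid_best(grid)
  list(best_config = models[[best]]$config,
       best_model = models[[best]],
       table = grid)
}

# Winning grid row: lowest percent error, ties broken by lower
# perplexity, then fewer hidden units, then smaller batch.
select_grid_best <- function(grid)
  order(grid$percent_error, grid$perplexity,
        grid$hidden_units, grid$batch_size)[1L]

#' Save / load a trained model as a self-describing JSON archive
#'
#' @param model An \code{\link{train_nlm}} result.
#' @param path File path.
#' @return \code{save_nlm} invisibly returns \code{path}; \code{load_nlm}
#'   returns the restored \code{"nlm_model"}.
#' @export
save_nlm <- function(model, path) {
  # matrices stored as explicit dim + column-major data so that scalar
  # unboxing can never change a shape on the way back in
  enc <- function(m) list(dim = dim(m), data = as.numeric(m))
  payload <- list(
    format = "dementialm-nlm", version = 1L,
    config = unclass(model$config), classes = model$classes,
    Ws = lapply(model$params$Ws, enc),
    bs = model$params$bs,
    V = enc(model$params$V), k = model$params$k,
    history = as.list(model$history))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname save_nlm
#' @export
load_nlm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "dementialm-nlm"))
    stop("not a saved model archive: ", path, call. = FALSE)
  cfg <- do.call(network_config, lapply(p$config, unlist))
  dec <- function(m) {
    d <- unlist(m$dim)
    matrix(as.numeric(unlist(m$data)), d[1], d[2])
  }
  params <- structure(list(Ws = lapply(p$Ws, dec),
                           bs = lapply(p$bs, function(b)
                             as.numeric(unlist(b))),
                           V = dec(p$V), k = as.numeric(unlist(p$k))),
                      class = "nlm_params")
  history <- as.data.frame(lapply(p$history, function(col)
    unlist(lapply(col, function(v) if (is.null(v)) NA else v))))
  structure(list(params = params, config = cfg,
                 classes = as.character(unlist(p$classes)),
                 history = history),
            class = "nlm_model")
}
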