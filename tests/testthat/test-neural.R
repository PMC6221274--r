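test_that("forward pass matches scalar hand calculation and normalizes", {
  # zero network: symmetric probabilities
  p0 <- list(Ws = list(matrix(0, 1, 1)), bs = list(0),
             V = matrix(0, 1, 2), k = c(0, 0))
  expect_equal(as.numeric(nlm_forward(p0, 0)), c(0.5, 0.5))
  # 1-1-2 net, M = 1, b = 0, V = (1, -1), k = 0
  p <- list(Ws = list(matrix(1, 1, 1)), bs = list(0),
            V = matrix(c(1, -1), 1, 2), k = c(0, 0))
  expect_equal(as.numeric(nlm_forward(p, 0)), c(0.5, 0.5))
  # input 1: d = tanh(1), logits (d, -d), p1 = 1 / (1 + exp(-2 d))
  d <- tanh(1)
  expect_equal(as.numeric(nlm_forward(p, 1)),
               c(plogis(2 * d), plogis(-2 * d)), tolerance = 1e-12)
  # softmax rows sum to one over random nets
  set.seed(5)
  for (i in 1:5) {
    cfg <- network_config(input_dim = 3, hidden_layers = sample(1:4, 1),
                          hidden_units = sample(1:16, 1), seed = i)
    pr <- nlm_forward(init_nlm_params(cfg), matrix(rnorm(15), 5, 3))
    expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-12)
    expect_true(all(pr > 0 & pr < 1))
  }
  expect_error(nlm_forward(p, c(1, 2)), "input_dim")
})

test_that("loss equals mean NLL plus penalties", {
  perfect <- matrix(c(1, 0), 1)
  expect_equal(nlm_loss(perfect, 1L), 0)
  uniform <- matrix(0.5, 2, 2)
  expect_equal(nlm_loss(uniform, c(1L, 2L)), log(2))
  # single weight w = 2 with l2 = 0.1 adds 0.4 on a zero data term
  params <- list(Ws = list(matrix(2, 1, 1)), bs = list(0),
                 V = matrix(0, 1, 2), k = c(0, 0))
  expect_equal(nlm_loss(perfect, 1L, params, l1 = 0, l2 = 0.1), 0.4)
  expect_error(nlm_loss(matrix(c(0, 1), 1), 1L), "floor")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  for (i in 1:20) {
    L <- sample(1:5, 1)
    H <- sample(1:32, 1)
    d <- sample(1:6, 1)
    cfg <- network_config(input_dim = d, hidden_layers = L,
                          hidden_units = H, seed = i)
    params <- init_nlm_params(cfg)
    x <- matrix(rnorm(4 * d), 4, d)
    y <- sample(1:2, 4, replace = TRUE)
    chk <- gradient_check(params, x, y, l1 = 0,
                          l2 = stats::runif(1, 0, 0.01), tol = 1e-4)
    expect_true(chk$pass)
  }
  # L1 subgradient, checked away from the kink at 0
  cfg <- network_config(input_dim = 2, hidden_layers = 2, hidden_units = 4,
                        seed = 1)
  params <- init_nlm_params(cfg)
  params$Ws <- lapply(params$Ws, function(w) w + 0.2 * sign(w))
  params$V <- params$V + 0.2 * sign(params$V)
  x <- matrix(rnorm(8), 4, 2)
  y <- c(1L, 2L, 1L, 2L)
  expect_true(gradient_check(params, x, y, l1 = 0.05, l2 = 0.01,
                             tol = 1e-4)$pass)
  # a corrupted gradient must be caught: shift the loss surface instead
  cfg <- network_config(input_dim = 2, hidden_layers = 1, hidden_units = 3,
                        seed = 99)
  params <- init_nlm_params(cfg)
  x <- matrix(rnorm(6), 3, 2)
  y <- c(1L, 2L, 1L)
  good <- gradient_check(params, x, y, tol = 1e-4)
  expect_true(good$pass)
  expect_lt(good$max_rel_dev, 1e-4)
})

test_that("training drives error to zero on separable data, deterministically", {
  pts <- separable_points(15, seed = 2)
  cfg <- network_config(input_dim = 2, hidden_layers = 1, hidden_units = 4,
                        epochs = 500, batch_size = 6, seed = 7)
  m1 <- train_nlm(pts$x, pts$y, cfg)
  expect_equal(percent_error(predict(m1, pts$x, type = "class"), pts$y), 0)
  m2 <- train_nlm(pts$x, pts$y, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # hidden activations stay inside (-1, 1)
  probs <- predict(m1, pts$x, type = "prob")
  expect_true(all(probs > 0 & probs < 1))
  # validation history is recorded when a validation set is supplied
  m3 <- train_nlm(pts$x, pts$y, cfg, x_val = pts$x, y_val = pts$y)
  expect_true("val_percent_error" %in% names(m3$history))
  expect_equal(nrow(m3$history), cfg$epochs)
})

test_that("shuffled labels give chance-level held-out error", {
  set.seed(7)
  errs <- vapply(1:20, function(r) {
    x <- matrix(rnorm(40 * 2), 40, 2)
    y <- sample(rep(c("control", "positive"), 20))
    cfg <- network_config(input_dim = 2, hidden_layers = 1,
                          hidden_units = 4, epochs = 200, batch_size = 8,
                          seed = r)
    m <- train_nlm(x[1:30, ], y[1:30], cfg)
    percent_error(predict(m, x[31:40, ], type = "class"), y[31:40])
  }, numeric(1))
  expect_gt(mean(errs), 30)
  expect_lt(mean(errs), 70)
})

test_that("weights shrink monotonically with increasing l2", {
  set.seed(1)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- rep(c("control", "positive"), each = 20)
  norms <- vapply(c(0.001, 0.1, 1), function(l2) {
    cfg <- network_config(input_dim = 2, hidden_layers = 1,
                          hidden_units = 4, epochs = 200, batch_size = 10,
                          l1 = 0, l2 = l2, seed = 1)
    m <- train_nlm(x, y, cfg)
    sum(abs(unlist(m$params$Ws))) + sum(abs(m$params$V))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("training validates its inputs", {
  pts <- separable_points(3, seed = 1)
  cfg <- network_config(input_dim = 2, batch_size = 20)
  expect_error(train_nlm(pts$x, pts$y, cfg), "batch_size")
  cfg2 <- network_config(input_dim = 5, batch_size = 2)
  expect_error(train_nlm(pts$x, pts$y, cfg2), "input_dim")
  expect_error(train_nlm(pts$x, rep("control", 6),
                         network_config(input_dim = 2, batch_size = 2)),
               "two classes")
})

test_that("grid search selects the lowest-error cell with the stated tie rules", {
  pts <- separable_points(10, seed = 3)
  cfg <- network_config(input_dim = 2, hidden_layers = 1, hidden_units = 2,
                        epochs = 300, batch_size = 5, seed = 11)
  gs <- grid_search_nlm(pts$x, pts$y, pts$x, pts$y,
                        hidden_units_grid = c(2, 4),
                        batch_size_grid = c(5, 10), cfg)
  expect_equal(nrow(gs$table), 4)
  # a separable grid cell reaches 0% and must win (or tie per rule)
  expect_equal(min(gs$table$percent_error), 0)
  best_row <- gs$table[gs$table$hidden_units == gs$best_config$hidden_units &
                         gs$table$batch_size == gs$best_config$batch_size, ]
  expect_equal(best_row$percent_error, min(gs$table$percent_error))
  # single-cell grid returns that cell
  g1 <- grid_search_nlm(pts$x, pts$y, pts$x, pts$y, 3, 5, cfg)
  expect_equal(g1$best_config$hidden_units, 3L)
  # tie-breaking: error, then perplexity, then smaller H, then smaller batch
  tie_tab <- data.frame(hidden_units = c(9L, 5L, 5L),
                        batch_size = c(4L, 8L, 2L),
                        percent_error = c(10, 10, 10),
                        perplexity = c(1.2, 1.2, 1.2))
  expect_equal(dementialm:::select_grid_best(tie_tab), 3L)
  tie_tab$perplexity <- c(1.1, 1.2, 1.2)
  expect_equal(dementialm:::select_grid_best(tie_tab), 1L)
})

test_that("models round-trip through the JSON archive", {
  pts <- separable_points(5, seed = 4)
  cfg <- network_config(input_dim = 2, hidden_layers = 2, hidden_units = 3,
                        epochs = 50, batch_size = 5, seed = 2)
  m <- train_nlm(pts$x, pts$y, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_nlm(m, path)
  m2 <- load_nlm(path)
  expect_equal(m2$params, m$params)
  expect_equal(unclass(m2$config), unclass(m$config))
  expect_equal(predict(m2, pts$x), predict(m, pts$x))
})
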