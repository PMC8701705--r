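test_that("neuron scores are mean absolute incoming weights", {
  dense <- list(type = "dense", name = "d", input_dim = 2, units = 3,
                activation = "relu",
                W = cbind(c(1, 1), c(-3, 3), c(0.1, 0.1)), b = numeric(3))
  expect_equal(score_neurons(dense), c(1, 3, 0.1))
  expect_equal(score_neurons(dense, use_abs = FALSE), c(1, 0, 0.1))

  out <- list(type = "dense", name = "o", input_dim = 3, units = 1,
              activation = "sigmoid", W = matrix(1, 3, 1), b = 0)
  expect_error(score_neurons(out), "never prunable")

  # an LSTM unit spans its column in all four gate blocks
  m <- build_baseline_rnn(input_dim = 4, units = 3, seed = 31)
  l <- m$layers[[2]]
  sc <- score_neurons(l)
  j <- 2
  cols <- (0:3) * 3 + j
  expect_equal(sc[j], mean(abs(c(l$Wx[, cols], l$Wh[, cols]))))

  # a zeroed unit scores 0 and is selected first
  l0 <- l; l0$Wx[, cols] <- 0; l0$Wh[, cols] <- 0
  m$layers[[2]] <- l0
  expect_equal(score_neurons(l0)[j], 0)
  expect_true(j %in% plan_prune(m, 0.34)$layers[["lstm_1"]]$drop)

  # all-equal weights tie-break toward the lowest indices
  leq <- l; leq$Wx[] <- 0.5; leq$Wh[] <- 0.5
  m$layers[[2]] <- leq
  expect_identical(plan_prune(m, 0.67)$layers[["lstm_1"]]$drop, 1:2)
})

test_that("plans select floor(q * width) lowest-scoring neurons per layer", {
  m <- build_baseline_rnn(seed = 32)
  p <- plan_prune(m, 0.5)
  expect_length(p$layers[["lstm_1"]]$drop, 8)
  expect_length(p$layers[["lstm_2"]]$drop, 8)
  d <- plan_prune(build_dnn(seed = 32), 0.5)
  expect_equal(vapply(d$layers, function(l) length(l$drop), 0L),
               c(dense_1 = 128L, dense_2 = 64L, dense_3 = 32L))
  tiny <- plan_prune(m, 0.001)
  expect_true(all(vapply(tiny$layers, function(l) length(l$drop), 0L) == 0))
  expect_error(plan_prune(m, 0), "quantile")
  expect_error(plan_prune(m, 1.2), "quantile")
})

test_that("surgery yields the published pruned parameter count", {
  m <- build_baseline_rnn(seed = 33)
  pr <- apply_prune(m, plan_prune(m, 0.5))
  expect_identical(count_params(pr), 3273L)
  expect_equal(pr$layers[[2]]$units, 8)
  expect_equal(pr$layers[[3]]$units, 8)
  # closed-form recount with reduced widths
  expect_identical(count_params(pr),
                   as.integer(4 * (76 + 8 + 1) * 8 + 4 * (8 + 8 + 1) * 8 + 9))

  # parameter count strictly decreases in q
  counts <- vapply(c(0.25, 0.5, 0.75), function(q)
    count_params(apply_prune(m, plan_prune(m, q))), 0L)
  expect_true(all(diff(counts) < 0))

  # an (effectively) empty plan leaves the model and its outputs unchanged
  p0 <- plan_prune(m, 0.001)
  m0 <- apply_prune(m, p0)
  expect_identical(count_params(m0), count_params(m))
  set.seed(33)
  x <- random_episode_array(4)
  expect_identical(predict(m0, x), predict(m, x))

  bad <- plan_prune(m, 0.5)
  bad$layers[["lstm_1"]]$drop <- c(0L, 99L)
  expect_error(apply_prune(m, bad), "out of range")
})

test_that("surviving weights are carried over bit-identically", {
  m <- build_baseline_rnn(seed = 34)
  p <- plan_prune(m, 0.5)
  pr <- apply_prune(m, p)
  U <- 16
  keep1 <- setdiff(1:U, p$layers[["lstm_1"]]$drop)
  gcols <- as.vector(vapply(0:3, function(g) g * U + keep1, numeric(8)))
  expect_identical(pr$layers[[2]]$Wx, m$layers[[2]]$Wx[, gcols])
  expect_identical(pr$layers[[2]]$Wh, m$layers[[2]]$Wh[keep1, gcols])
  expect_identical(pr$layers[[2]]$b, m$layers[[2]]$b[gcols])
  keep2 <- setdiff(1:U, p$layers[["lstm_2"]]$drop)
  expect_identical(pr$layers[[5]]$W, m$layers[[5]]$W[keep2, , drop = FALSE])
})

test_that("pruned forward pass equals the zero-out oracle", {
  set.seed(35)
  for (builder in list(build_baseline_rnn, build_dnn)) {
    m <- builder(seed = 35)
    p <- plan_prune(m, 0.5)
    pr <- apply_prune(m, p)
    x <- if (m$kind == "rnn") random_episode_array(8) else
      matrix(rnorm(8 * 76), 8)
    got <- predict(pr, x)
    ref <- zero_out_oracle(m, p, x)
    expect_lt(max(abs(got - ref)), 1e-8)
  }
})

test_that("the train-prune-retrain schedule logs every epoch", {
  set.seed(36)
  cc <- cohort_config(60, seed = 36)
  co <- generate_cohort(cc)
  sp <- split_cohort(co, 0.2, seed = 36)
  prep <- preprocess_cohort(sp$train, sp$test)
  m <- build_baseline_rnn(seed = 36)
  fit <- prune_retrain(m, prep$train$x, prep$train$y, 0.5,
                       train_config(epochs = 3, seed = 36),
                       pre_epochs = 1, post_epochs = 2,
                       test = list(x = prep$test$x, y = prep$test$y))
  expect_equal(nrow(fit$history), 3)
  expect_identical(fit$history$phase, c("pre", "post", "post"))
  expect_identical(count_params(fit$model), 3273L)

  # post_epochs = 0 returns the freshly pruned model
  fit0 <- prune_retrain(build_baseline_rnn(seed = 36), prep$train$x,
                        prep$train$y, 0.5, train_config(seed = 36),
                        pre_epochs = 1, post_epochs = 0)
  manual <- train(build_baseline_rnn(seed = 36), prep$train$x, prep$train$y,
                  train_config(epochs = 1, seed = 36))
  manual_pruned <- apply_prune(manual$model, plan_prune(manual$model, 0.5))
  expect_identical(predict(fit0$model, prep$test$x),
                   predict(manual_pruned, prep$test$x))
})

test_that("prune plans round-trip through JSON", {
  m <- build_baseline_rnn(seed = 37)
  p <- plan_prune(m, 0.25)
  f <- tempfile(fileext = ".json")
  write_prune_plan(p, f)
  back <- read_prune_plan(f)
  expect_equal(back$quantile, p$quantile)
  expect_identical(lapply(back$layers, `[[`, "drop"),
                   lapply(p$layers, `[[`, "drop"))
  unlink(f)
})
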