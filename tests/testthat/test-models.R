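test_that("parameter counts match the closed forms", {
  expect_identical(count_params(build_baseline_rnn(seed = 1)), 8081L)
  expect_identical(count_params(build_hlstm_rnn(seed = 1)), 6993L)
  expect_identical(count_params(build_dnn(seed = 1)), 60929L)
  one <- new_dense_only <- structure(
    list(layers = list(nncondense:::new_dense_layer(1, 1, "sigmoid", "d")),
         kind = "dnn", input_dim = 1L), class = "nnc_model")
  expect_identical(count_params(one), 2L)
})

test_that("cell steps reproduce the analytic degenerate cases", {
  U <- 3; D <- 2
  w0 <- list(Wx = matrix(0, D, 4 * U), Wh = matrix(0, U, 4 * U),
             b = numeric(4 * U))
  st <- lstm_cell_step(numeric(D), numeric(U), numeric(U), w0)
  expect_equal(st$c, numeric(U))
  expect_equal(st$h, numeric(U))
  wh0 <- c(w0, list(Hk = matrix(0, U, 4 * U)))
  sth <- hlstm_cell_step(numeric(D), numeric(U), numeric(U), wh0)
  expect_equal(sth$h, numeric(U))

  # one unit, all gate pre-activations 0, c_prev = 1
  w1 <- list(Wx = matrix(0, 1, 4), Wh = matrix(0, 1, 4), b = numeric(4))
  st1 <- lstm_cell_step(0, 0, 1, w1)
  expect_equal(st1$c, 0.5)
  expect_equal(st1$h, 0.5 * tanh(0.5))

  expect_error(lstm_cell_step(numeric(3), numeric(U), numeric(U), w0),
               "shape")
})

test_that("cell steps agree with an independent scalar evaluation", {
  set.seed(21)
  for (rep in 1:5) {
    D <- sample(2:5, 1); U <- sample(2:4, 1)
    w <- list(Wx = matrix(rnorm(D * 4 * U), D), Wh = matrix(rnorm(U * 4 * U), U),
              b = rnorm(4 * U), Hk = matrix(rnorm(U * 4 * U), U))
    x <- rnorm(D); h <- rnorm(U); c <- rnorm(U)
    got <- lstm_cell_step(x, h, c, w[c("Wx", "Wh", "b")])
    ref <- oracle_lstm_step(x, h, c, w$Wx, w$Wh, w$b)
    expect_lt(max(abs(got$h - ref$h), abs(got$c - ref$c)), 1e-10)
    goth <- hlstm_cell_step(x, h, c, w)
    refh <- oracle_lstm_step(x, h, c, w$Wx, w$Wh, w$b, Hk = w$Hk)
    expect_lt(max(abs(goth$h - refh$h), abs(goth$c - refh$c)), 1e-10)
  }
})

test_that("batched compiled forward equals the scalar per-step oracle", {
  set.seed(22)
  for (builder in list(build_baseline_rnn, build_hlstm_rnn)) {
    m <- builder(input_dim = 5, units = 3)
    x <- random_episode_array(4, d = 5, t = 6)
    x[2, , 3] <- 0  # one masked step in one patient
    got <- predict(m, x)
    ref <- vapply(1:4, function(i) oracle_rnn_forward(m, x[, , i]), 0)
    expect_lt(max(abs(got - ref)), 1e-8)
    # batch-of-one equals batched evaluation
    one <- vapply(1:4, function(i) predict(m, x[, , i, drop = FALSE]), 0)
    expect_lt(max(abs(got - one)), 1e-7)
  }
})

test_that("hidden-kernel cell reduces to the standard LSTM under identity kernels", {
  set.seed(23)
  D <- 4; U <- 3
  Wx <- matrix(abs(rnorm(D * 4 * U)), D)  # non-negative input kernel
  w <- list(Wx = Wx, Wh = matrix(rnorm(U * 4 * U), U), b = rnorm(4 * U),
            Hk = do.call(cbind, replicate(4, diag(U), simplify = FALSE)))
  x <- abs(rnorm(D))  # non-negative inputs keep the ReLU inactive
  h <- rnorm(U); c <- rnorm(U)
  got <- hlstm_cell_step(x, h, c, w)
  ref <- lstm_cell_step(x, h, c, w[c("Wx", "Wh", "b")])
  expect_lt(max(abs(got$h - ref$h), abs(got$c - ref$c)), 1e-12)
})

test_that("all-zero time steps are skipped by the masking layer", {
  set.seed(24)
  m <- build_baseline_rnn(input_dim = 6, units = 4)
  x <- random_episode_array(3, d = 6, t = 10)
  x_tail <- array(0, c(14, 6, 3))
  x_tail[1:10, , ] <- x
  expect_equal(predict(m, x_tail), predict(m, x), tolerance = 1e-12)

  # a zero step mid-sequence leaves the state unchanged
  x2 <- x; x2[5, , ] <- 0
  x3 <- x[-5, , , drop = FALSE]
  expect_equal(predict(m, x2), predict(m, x3), tolerance = 1e-12)
})

test_that("hidden states stay inside the unit box", {
  set.seed(25)
  m <- build_hlstm_rnn(input_dim = 5, units = 4)
  x <- random_episode_array(2, d = 5, t = 30) * 5
  Xc <- aperm(x, c(3, 2, 1))
  out <- nncondense:::cpp_hlstm_forward(Xc, m$layers[[2]]$Wx, m$layers[[2]]$Wh,
                                        m$layers[[2]]$Hk, m$layers[[2]]$b,
                                        matrix(1, 2, 30))
  expect_true(all(abs(out$H) <= 1))
})

test_that("a zero-weight model scores everyone at one half", {
  m <- build_baseline_rnn(input_dim = 4, units = 2)
  for (li in seq_along(m$layers))
    for (w in intersect(names(m$layers[[li]]), c("Wx", "Wh", "b", "W")))
      m$layers[[li]][[w]][] <- 0
  x <- random_episode_array(3, d = 4, t = 5)
  expect_equal(predict(m, x), rep(0.5, 3))
  expect_error(predict(m, random_episode_array(2, d = 7, t = 5)), "expects")
})

test_that("analytic gradients match finite differences", {
  set.seed(26)
  fd_check <- function(model, grads_fn, n_probe = 4) {
    res <- grads_fn(model)
    maxerr <- 0
    for (li in seq_along(model$layers)) {
      l <- model$layers[[li]]
      g <- res$grads[[li]]
      if (is.null(g)) next
      gmap <- c(dWx = "Wx", dWh = "Wh", dHk = "Hk", db = "b", W = "W", b = "b")
      for (gn in intersect(names(g), names(gmap))) {
        wn <- gmap[[gn]]
        for (i in sample(length(l[[wn]]), min(n_probe, length(l[[wn]])))) {
          eps <- 1e-5
          mp <- model; mp$layers[[li]][[wn]][i] <- mp$layers[[li]][[wn]][i] + eps
          mm <- model; mm$layers[[li]][[wn]][i] <- mm$layers[[li]][[wn]][i] - eps
          fd <- (grads_fn(mp)$loss - grads_fn(mm)$loss) / (2 * eps)
          maxerr <- max(maxerr, abs(g[[gn]][i] - fd))
        }
      }
    }
    maxerr
  }

  B <- 3; T_ <- 5; D <- 4
  Xc <- array(rnorm(B * D * T_), c(B, D, T_))
  Xc[1, , 2] <- 0  # masked step exercises the skip path
  y <- c(1, 0, 1)
  for (builder in list(build_baseline_rnn, build_hlstm_rnn)) {
    m <- builder(input_dim = D, units = 3)
    dm <- matrix(1, B, 3)
    err <- fd_check(m, function(mod)
      nncondense:::rnn_batch_grads(mod, Xc, y, dm))
    expect_lt(err, 1e-6)
  }

  m <- build_dnn(input_dim = D, widths = c(5, 4))
  # jitter biases so no ReLU pre-activation sits exactly on the kink
  for (li in c(1, 2))
    m$layers[[li]]$b <- rnorm(length(m$layers[[li]]$b), 0, 0.1)
  x <- matrix(rnorm(8 * D), 8)
  yb <- rbinom(8, 1, 0.5)
  dms <- list(matrix(1, 8, 4))
  err <- fd_check(m, function(mod)
    nncondense:::dnn_batch_grads(mod, x, yb, dms))
  expect_lt(err, 1e-6)
})

test_that("weights survive a save/load round trip bit-exactly", {
  set.seed(27)
  for (builder in list(build_baseline_rnn, build_hlstm_rnn, build_dnn)) {
    m <- builder(input_dim = 7)
    f <- tempfile(fileext = ".json")
    save_weights(m, f)
    m2 <- load_weights(f)
    for (li in seq_along(m$layers))
      for (w in intersect(names(m$layers[[li]]), c("Wx", "Wh", "Hk", "b", "W")))
        expect_identical(m2$layers[[li]][[w]], m$layers[[li]][[w]])
    if (m$kind == "rnn") {
      x <- random_episode_array(2, d = 7, t = 4)
      expect_identical(predict(m2, x), predict(m, x))
    }
    unlink(f)
  }
})
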