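#' @useDynLib nncondense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gate order used everywhere (kernels, serialization): f, i, o, c.
GATES <- c("f", "i", "o", "c")

glorot_uniform <- function(fan_in, fan_out, n_row = fan_in, n_col = fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_row * n_col, -limit, limit), n_row, n_col)
}

orthogonal_init <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  q * sign(diag(qr.R(qr_)))  # fix the sign ambiguity for a Haar draw
}

lstm_bias_init <- function(units) {
  b <- numeric(4 * units)
  b[seq_len(units)] <- 1  # forget-gate offset, the usual recurrent default
  b
}

new_lstm_layer <- function(input_dim, units, name, hidden_kernel = FALSE) {
  Wx <- glorot_uniform(input_dim, units, input_dim, 4 * units)
  Wh <- do.call(cbind, lapply(GATES, function(g) orthogonal_init(units)))
  layer <- list(type = if (hidden_kernel) "hlstm" else "lstm", name = name,
                input_dim = input_dim, units = units,
                Wx = Wx, Wh = Wh, b = lstm_bias_init(units))
  if (hidden_kernel)
    layer$Hk <- do.call(cbind, lapply(GATES, function(g)
      glorot_uniform(units, units)))
  layer
}

new_dense_layer <- function(input_dim, units, activation, name) {
  list(type = "dense", name = name, input_dim = input_dim, units = units,
       activation = activation,
       W = glorot_uniform(input_dim, units), b = numeric(units))
}

new_model <- function(layers, kind, input_dim) {
  structure(list(layers = layers, kind = kind, input_dim = input_dim),
            class = "nnc_model")
}

#' Model builders
#'
#' `build_baseline_rnn()` assembles the two-layer LSTM mortality model:
#' masking layer, LSTM(D -> U), LSTM(U -> U), dropout, dense sigmoid head.
#' `build_hlstm_rnn()` replaces the two LSTM layers with a single
#' hidden-kernel LSTM layer. `build_dnn()` assembles the feedforward model:
#' three ReLU layers (256/128/64 by default), dropout, sigmoid head, applied
#' to time-collapsed inputs.
#'
#' Kernels are Glorot-uniform, recurrent kernels orthogonal (per gate),
#' biases zero except a forget-gate offset of 1. With the default widths the
#' trainable parameter counts are 8081 (baseline RNN), 6993 (hLSTM RNN) and
#' 60,929 (DNN).
#'
#' @param input_dim Model input width (default 76).
#' @param units Hidden state size of each recurrent layer (default 16).
#' @param widths Hidden-layer widths of the feedforward model.
#' @param dropout Dropout rate applied before the output head
#'   (0.3 recurrent, 0.5 feedforward).
#' @param seed Optional integer; when given, initialization is seeded.
#' @return An `nnc_model`.
#' @name builders
#' @export
build_baseline_rnn <- function(input_dim = 76, units = 16, dropout = 0.3,
                               seed = NULL) {
  stopifnot(input_dim > 0, units > 0)
  if (!is.null(seed)) set.seed(seed)
  new_model(list(
    list(type = "masking"),
    new_lstm_layer(input_dim, units, "lstm_1"),
    new_lstm_layer(units, units, "lstm_2"),
    list(type = "dropout", rate = dropout),
    new_dense_layer(units, 1, "sigmoid", "dense_out")
  ), kind = "rnn", input_dim = input_dim)
}

#' @rdname builders
#' @export
build_hlstm_rnn <- function(input_dim = 76, units = 16, dropout = 0.3,
                            seed = NULL) {
  stopifnot(input_dim > 0, units > 0)
  if (!is.null(seed)) set.seed(seed)
  new_model(list(
    list(type = "masking"),
    new_lstm_layer(input_dim, units, "hlstm_1", hidden_kernel = TRUE),
    list(type = "dropout", rate = dropout),
    new_dense_layer(units, 1, "sigmoid", "dense_out")
  ), kind = "rnn", input_dim = input_dim)
}

#' @rdname builders
#' @export
build_dnn <- function(input_dim = 76, widths = c(256, 128, 64),
                      dropout = 0.5, seed = NULL) {
  stopifnot(input_dim > 0, all(widths > 0))
  if (!is.null(seed)) set.seed(seed)
  layers <- list()
  d <- input_dim
  for (i in seq_along(widths)) {
    layers[[length(layers) + 1]] <-
      new_dense_layer(d, widths[i], "relu", paste0("dense_", i))
    d <- widths[i]
  }
  layers[[length(layers) + 1]] <- list(type = "dropout", rate = dropout)
  layers[[length(layers) + 1]] <- new_dense_layer(d, 1, "sigmoid", "dense_out")
  new_model(layers, kind = "dnn", input_dim = input_dim)
}

#' Trainable parameter count
#'
#' Sums weights and biases over all layers. Closed forms per layer:
#' LSTM `4 (D + U + 1) U`; hidden-kernel LSTM `4 ((D + U + 1) U + U^2)`;
#' dense `(D + 1) U`.
#'
#' @param model An `nnc_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  n <- 0L
  for (l in model$layers)
    for (w in intersect(names(l), c("Wx", "Wh", "Hk", "b", "W"))) {
      t_ <- l[[w]]
      n <- n + length(if (inherits(t_, "quantized_tensor")) t_$codes else t_)
    }
  n
}

#' Single LSTM / hLSTM cell step
#'
#' Reference (unbatched) evaluation of one recurrence step. Gate
#' pre-activations are affine in `(x_t, h_prev)`; forget/input/output gates
#' pass through the logistic function, the candidate through tanh;
#' `c_t = f * c_prev + i * candidate` and `h_t = o * tanh(c_t)`. The
#' hidden-kernel variant inserts, per gate, a bias-free U x U kernel after a
#' ReLU on the input-kernel product:
#' `z_g = W_h,g h_prev + H_g relu(W_x,g x_t) + b_g`.
#'
#' @param x_t Input vector (length D).
#' @param h_prev,c_prev Previous hidden and cell state (length U).
#' @param w Layer weights: `Wx` (D x 4U), `Wh` (U x 4U), `b` (4U), gate blocks
#'   ordered f, i, o, c; plus `Hk` (U x 4U) for the hidden-kernel cell.
#' @return `list(h, c)`.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, w) {
  U <- length(h_prev)
  if (length(x_t) != nrow(w$Wx) || ncol(w$Wx) != 4 * U || length(c_prev) != U)
    stop("shape mismatch in lstm_cell_step")
  z <- as.vector(x_t %*% w$Wx) + as.vector(h_prev %*% w$Wh) + w$b
  gate_combine(z, c_prev, U)
}

#' @rdname lstm_cell_step
#' @export
hlstm_cell_step <- function(x_t, h_prev, c_prev, w) {
  U <- length(h_prev)
  if (length(x_t) != nrow(w$Wx) || ncol(w$Wx) != 4 * U || is.null(w$Hk))
    stop("shape mismatch in hlstm_cell_step")
  r <- pmax(as.vector(x_t %*% w$Wx), 0)
  z <- as.vector(h_prev %*% w$Wh) + w$b
  for (g in 1:4) {
    idx <- ((g - 1) * U + 1):(g * U)
    z[idx] <- z[idx] + as.vector(r[idx] %*% w$Hk[, idx])
  }
  gate_combine(z, c_prev, U)
}

gate_combine <- function(z, c_prev, U) {
  f <- stats::plogis(z[seq_len(U)])
  i <- stats::plogis(z[U + seq_len(U)])
  o <- stats::plogis(z[2 * U + seq_len(U)])
  g <- tanh(z[3 * U + seq_len(U)])
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

# Active-step matrix (B x T): a step is processed unless its input row is
# entirely zero (the masking-layer contract).
active_steps <- function(X) {
  B <- dim(X)[1]; T_ <- dim(X)[3]
  a <- matrix(1, B, T_)
  for (t in seq_len(T_)) a[, t] <- as.numeric(rowSums(abs(X[, , t, drop = FALSE])) > 0)
  a
}

# Forward pass over one batch cube (B x D x T), inference mode.
rnn_forward_batch <- function(model, Xc) {
  active <- matrix(1, dim(Xc)[1], dim(Xc)[3])
  cur <- Xc
  h_last <- NULL
  for (l in model$layers) {
    if (l$type == "masking") {
      active <- active_steps(cur)
    } else if (l$type == "lstm") {
      out <- cpp_lstm_forward(cur, l$Wx, l$Wh, l$b, active)
      cur <- out$H
      h_last <- out$H[, , dim(out$H)[3], drop = TRUE]
    } else if (l$type == "hlstm") {
      out <- cpp_hlstm_forward(cur, l$Wx, l$Wh, l$Hk, l$b, active)
      cur <- out$H
      h_last <- out$H[, , dim(out$H)[3], drop = TRUE]
    } else if (l$type == "dropout") {
      # identity at inference
    } else if (l$type == "dense") {
      h_last <- dense_forward(matrix(h_last, nrow = dim(Xc)[1]), l)
    }
  }
  as.vector(h_last)
}

dense_forward <- function(x, l) {
  z <- sweep(x %*% l$W, 2, l$b, "+")
  switch(l$activation,
         relu = pmax(z, 0),
         sigmoid = stats::plogis(z),
         linear = z,
         stop("unknown activation ", l$activation))
}

dnn_forward <- function(model, x, drop_masks = NULL) {
  cur <- x
  k <- 0
  for (l in model$layers) {
    if (l$type == "dense") {
      cur <- dense_forward(cur, l)
    } else if (l$type == "dropout") {
      k <- k + 1
      if (!is.null(drop_masks)) cur <- cur * drop_masks[[k]]
    }
  }
  cur
}

#' Predicted mortality risk
#'
#' Deterministic inference pass (dropout disabled). Recurrent models take a
#' `T x D x N` array (or `T x D` matrix for one patient); the feedforward
#' model takes an `N x D` matrix of time-collapsed inputs.
#'
#' @param object An `nnc_model`.
#' @param x Input array or matrix.
#' @param batch_size Internal batch size for recurrent evaluation.
#' @param ... Unused.
#' @return Numeric vector of risk scores in (0, 1), one per patient.
#' @export
predict.nnc_model <- function(object, x, batch_size = 512, ...) {
  if (object$kind == "dnn") {
    x <- matrix(x, ncol = object$input_dim)
    return(as.vector(dnn_forward(object, x)))
  }
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  if (dim(x)[2] != object$input_dim)
    stop("input has ", dim(x)[2], " dimensions; model expects ",
         object$input_dim)
  n <- dim(x)[3]
  scores <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    Xc <- aperm(x[, , idx, drop = FALSE], c(3, 2, 1))
    scores[idx] <- rnn_forward_batch(object, Xc)
  }
  scores
}
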