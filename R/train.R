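#' Training configuration
#'
#' The published training regime: Adam at learning rate 0.001, binary
#' cross-entropy, batch size 8, 20 epochs, dropout as set per model.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes over the training data (>= 0).
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param seed Integer seed covering shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 8, epochs = 20,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1 || epochs < 0) stop("batch_size >= 1 and epochs >= 0 required")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function() new.env(parent = emptyenv())

adam_update <- function(state, key, w, g, cfg, step) {
  if (is.null(state[[key]]))
    state[[key]] <- list(m = 0 * w, v = 0 * w)
  s <- state[[key]]
  s$m <- cfg$beta1 * s$m + (1 - cfg$beta1) * g
  s$v <- cfg$beta2 * s$v + (1 - cfg$beta2) * g * g
  state[[key]] <- s
  mhat <- s$m / (1 - cfg$beta1^step)
  vhat <- s$v / (1 - cfg$beta2^step)
  w - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$epsilon)
}

# ---- one mini-batch, recurrent models --------------------------------------

rnn_batch_grads <- function(model, Xc, y, drop_mask) {
  B <- dim(Xc)[1]
  active <- matrix(1, B, dim(Xc)[3])
  caches <- vector("list", length(model$layers))
  cur <- Xc
  h_last <- NULL
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "masking") {
      active <- active_steps(cur)
    } else if (l$type %in% c("lstm", "hlstm")) {
      out <- if (l$type == "lstm")
        cpp_lstm_forward(cur, l$Wx, l$Wh, l$b, active)
      else cpp_hlstm_forward(cur, l$Wx, l$Wh, l$Hk, l$b, active)
      caches[[li]] <- list(input = cur, out = out)
      cur <- out$H
      h_last <- matrix(out$H[, , dim(out$H)[3]], nrow = B)
    } else if (l$type == "dropout") {
      caches[[li]] <- list(pre = h_last)
      h_last <- h_last * drop_mask
    } else if (l$type == "dense") {
      caches[[li]] <- list(input = h_last)
      h_last <- dense_forward(h_last, l)
    }
  }
  p <- as.vector(h_last)
  loss <- bce_loss(p, y)

  grads <- vector("list", length(model$layers))
  dcur <- NULL  # gradient w.r.t. the running head activation
  dH_seq <- NULL  # gradient w.r.t. a hidden-state sequence (cube)
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    if (l$type == "dense") {
      dz <- matrix((p - y) / B, ncol = 1)  # sigmoid + BCE
      inp <- caches[[li]]$input
      grads[[li]] <- list(W = crossprod(inp, dz), b = colSums(dz))
      dcur <- dz %*% t(l$W)
    } else if (l$type == "dropout") {
      dcur <- dcur * drop_mask
    } else if (l$type %in% c("lstm", "hlstm")) {
      cc <- caches[[li]]
      U <- l$units; T_ <- dim(cc$input)[3]
      if (is.null(dH_seq)) {
        dH <- array(0, c(B, U, T_))
        dH[, , T_] <- dcur
      } else dH <- dH_seq
      g <- if (l$type == "lstm")
        cpp_lstm_backward(cc$input, l$Wx, l$Wh, cc$out$H, cc$out$C,
                          cc$out$G, active, dH)
      else cpp_hlstm_backward(cc$input, l$Wx, l$Wh, l$Hk, cc$out$H,
                              cc$out$C, cc$out$G, cc$out$R, active, dH)
      grads[[li]] <- g
      dH_seq <- g$dX
      dcur <- NULL
    }
  }
  list(loss = loss, grads = grads)
}

# ---- one mini-batch, feedforward models ------------------------------------

dnn_batch_grads <- function(model, x, y, drop_masks) {
  caches <- vector("list", length(model$layers))
  cur <- x
  k <- 0
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "dense") {
      caches[[li]] <- list(input = cur)
      cur <- dense_forward(cur, l)
      caches[[li]]$output <- cur
    } else if (l$type == "dropout") {
      k <- k + 1
      cur <- cur * drop_masks[[k]]
    }
  }
  p <- as.vector(cur)
  loss <- bce_loss(p, y)
  B <- length(y)

  grads <- vector("list", length(model$layers))
  dcur <- NULL
  k <- length(drop_masks)
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    if (l$type == "dense") {
      dz <- if (l$activation == "sigmoid" && is.null(dcur))
        matrix((p - y) / B, ncol = 1)
      else if (l$activation == "relu")
        dcur * (caches[[li]]$output > 0)
      else stop("unsupported backprop activation ", l$activation)
      inp <- caches[[li]]$input
      grads[[li]] <- list(W = crossprod(inp, dz), b = colSums(dz))
      dcur <- dz %*% t(l$W)
    } else if (l$type == "dropout") {
      dcur <- dcur * drop_masks[[k]]
      k <- k - 1
    }
  }
  list(loss = loss, grads = grads)
}

apply_grads <- function(model, grads, adam, cfg, step) {
  gmap <- c(dWx = "Wx", dWh = "Wh", dHk = "Hk", db = "b", W = "W", b = "b")
  for (li in seq_along(grads)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (gn in intersect(names(g), names(gmap))) {
      wn <- gmap[[gn]]
      w <- model$layers[[li]][[wn]]
      gv <- g[[gn]]
      if (is.null(dim(w))) gv <- as.vector(gv) else dim(gv) <- dim(w)
      model$layers[[li]][[wn]] <-
        adam_update(adam, paste0(li, ".", wn), w, gv, cfg, step)
    }
  }
  model
}

#' Train a model with Adam and binary cross-entropy
#'
#' Mini-batch gradient descent with seeded shuffling and inverted dropout.
#' When a test set is supplied, the test AUROC is recorded after every epoch
#' (the published learning-curve protocol); the reported score is always the
#' last epoch's.
#'
#' @param model An `nnc_model`.
#' @param x Training inputs: `T x D x N` array (recurrent) or `N x D` matrix
#'   (feedforward).
#' @param y Binary labels, length N.
#' @param config A [train_config()].
#' @param test Optional `list(x, y)` evaluated each epoch.
#' @return `list(model, history)`; `history` has one row per epoch with the
#'   mean training loss and, if available, the test AUROC.
#' @export
train <- function(model, x, y, config = train_config(), test = NULL) {
  stopifnot(inherits(model, "nnc_model"))
  is_rnn <- model$kind == "rnn"
  n <- if (is_rnn) dim(x)[3] else nrow(x)
  stopifnot(n == length(y))
  set.seed(config$seed)
  adam <- adam_new()
  step <- 0
  hist <- data.frame(epoch = integer(), loss = numeric(), test_auroc = numeric())
  drop_layers <- Filter(function(l) l$type == "dropout", model$layers)
  widths <- dropout_widths(model)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1, n)]
      B <- length(idx)
      step <- step + 1
      if (is_rnn) {
        Xc <- aperm(x[, , idx, drop = FALSE], c(3, 2, 1))
        rate <- drop_layers[[1]]$rate
        dm <- matrix(stats::rbinom(B * widths[1], 1, 1 - rate), B) / (1 - rate)
        res <- rnn_batch_grads(model, Xc, y[idx], dm)
      } else {
        dms <- lapply(seq_along(drop_layers), function(k) {
          rate <- drop_layers[[k]]$rate
          matrix(stats::rbinom(B * widths[k], 1, 1 - rate), B) / (1 - rate)
        })
        res <- dnn_batch_grads(model, x[idx, , drop = FALSE], y[idx], dms)
      }
      if (!is.finite(res$loss))
        stop("non-finite training loss at epoch ", epoch, ", step ", step,
             "; inputs may be unnormalized or the learning rate too high")
      losses <- c(losses, res$loss)
      model <- apply_grads(model, res$grads, adam, config, step)
    }
    test_auc <- if (!is.null(test))
      auroc(predict(model, test$x), test$y) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   test_auroc = test_auc))
  }
  list(model = model, history = hist)
}

# width of the activation entering each dropout layer
dropout_widths <- function(model) {
  w <- integer(0)
  last_units <- model$input_dim
  for (l in model$layers) {
    if (!is.null(l$units)) last_units <- l$units
    if (l$type == "dropout") w <- c(w, last_units)
  }
  w
}
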