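# Shared fixtures and independent oracles. Everything here is deliberately
# scalar / brute-force so it cannot share bugs with the package's vectorized
# and compiled paths.

tiny_features <- function() {
  list(
    feature_spec("hr", "continuous", normal_value = 80,
                 population_mean = 85, population_sd = 15, observe_rate = 1),
    feature_spec("bp", "continuous", normal_value = 120,
                 population_mean = 120, population_sd = 20, observe_rate = 0.5),
    feature_spec("gcs", "categorical", normal_value = "high",
                 categories = c("low", "high"), observe_rate = 0.25)
  )
}

record_from_events <- function(times, vars, vals, id = "p1", label = 0L) {
  structure(list(patient_id = id,
                 events = data.frame(time_hours = times, variable = vars,
                                     value = as.character(vals),
                                     stringsAsFactors = FALSE),
                 label = as.integer(label)),
            class = "patient_record")
}

# Scalar, loop-based evaluation of one LSTM step (independent of the package
# implementation and of the compiled kernels).
oracle_lstm_step <- function(x, h, c, Wx, Wh, b, Hk = NULL) {
  U <- length(h)
  z <- numeric(4 * U)
  for (k in seq_len(4 * U)) {
    acc <- b[k]
    if (is.null(Hk)) {
      for (d in seq_along(x)) acc <- acc + x[d] * Wx[d, k]
    } else {
      # hidden-kernel path: H_g ReLU(W_x,g x) per gate block
      g <- (k - 1) %/% U
      for (j in seq_len(U)) {
        a <- 0
        for (d in seq_along(x)) a <- a + x[d] * Wx[d, g * U + j]
        acc <- acc + max(a, 0) * Hk[j, k]
      }
    }
    for (j in seq_len(U)) acc <- acc + h[j] * Wh[j, k]
    z[k] <- acc
  }
  sig <- function(v) 1 / (1 + exp(-v))
  f <- sig(z[1:U]); i <- sig(z[U + 1:U]); o <- sig(z[2 * U + 1:U])
  g <- tanh(z[3 * U + 1:U])
  c_new <- f * c + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# Full-sequence scalar forward of a recurrent model for one patient
# (T x D matrix), with the all-zero-row masking contract.
oracle_rnn_forward <- function(model, x) {
  T_ <- nrow(x)
  state <- list()
  cur <- x
  out <- NULL
  active <- apply(abs(cur), 1, sum) > 0
  for (l in model$layers) {
    if (l$type %in% c("lstm", "hlstm")) {
      h <- numeric(l$units); c <- numeric(l$units)
      hs <- matrix(0, T_, l$units)
      for (t in seq_len(T_)) {
        if (active[t]) {
          st <- oracle_lstm_step(cur[t, ], h, c, l$Wx, l$Wh, l$b, l$Hk)
          h <- st$h; c <- st$c
        }
        hs[t, ] <- h
      }
      cur <- hs
      out <- h
    } else if (l$type == "dense") {
      z <- sum(out * l$W[, 1]) + l$b[1]
      out <- 1 / (1 + exp(-z))
    }
  }
  out
}

# All-pairs AUROC with half credit for ties: the O(n^2) oracle.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Forward pass of the original model with pruned units disconnected: their
# outgoing recurrent rows and next-layer rows are zeroed, so the surviving
# units evolve exactly as in the surgically pruned model.
zero_out_oracle <- function(model, plan, x) {
  idx <- nncondense:::prunable_idx(model)
  for (li in idx) {
    l <- model$layers[[li]]
    drop <- plan$layers[[l$name]]$drop
    if (length(drop) == 0) next
    if (l$type %in% c("lstm", "hlstm")) {
      U <- l$units
      gcols_all <- as.vector(outer(drop, (0:3) * U, `+`))
      l$Wh[drop, ] <- 0          # no influence on any gate of other units
      l$Wh[, gcols_all] <- 0     # and nothing feeds the dropped units back
      model$layers[[li]] <- l
    } else {
      model$layers[[li]]$W[, drop] <- 0
    }
    for (lj in seq(li + 1, length(model$layers))) {
      nxt <- model$layers[[lj]]
      if (nxt$type == "dense") { nxt$W[drop, ] <- 0; model$layers[[lj]] <- nxt; break }
      if (nxt$type %in% c("lstm", "hlstm")) {
        nxt$Wx[drop, ] <- 0; model$layers[[lj]] <- nxt; break
      }
    }
  }
  predict(model, x)
}

random_episode_array <- function(n, d = 76, t = 48) {
  array(stats::rnorm(t * d * n), c(t, d, n))
}
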