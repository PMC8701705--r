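#' Score neurons of one layer by mean incoming weight
#'
#' The pruning criterion: a neuron's score is the mean absolute weight over
#' all of its incoming connections. For a dense layer that is the mean of its
#' kernel column; for a recurrent layer a "neuron" is one hidden unit spanning
#' all four gates, so the mean runs over the unit's column in every gate block
#' of the input, recurrent and (hLSTM) hidden kernels. Setting
#' `use_abs = FALSE` scores by the signed mean instead.
#'
#' @param layer A weight-bearing layer of an `nnc_model`.
#' @param use_abs Use absolute weights (default, the magnitude criterion).
#' @return Numeric score per neuron (length = layer width).
#' @export
score_neurons <- function(layer, use_abs = TRUE) {
  f <- if (use_abs) abs else identity
  if (layer$type == "dense") {
    if (layer$activation == "sigmoid" && layer$units == 1)
      stop("the output layer is never prunable")
    return(colMeans(f(layer$W)))
  }
  if (!layer$type %in% c("lstm", "hlstm"))
    stop("layer type '", layer$type, "' has no neurons to score")
  U <- layer$units
  vapply(seq_len(U), function(j) {
    cols <- (0:3) * U + j  # unit j in every gate block
    w <- c(layer$Wx[, cols], layer$Wh[, cols])
    if (!is.null(layer$Hk)) w <- c(w, layer$Hk[, cols])
    mean(f(w))
  }, 0)
}

prunable_idx <- function(model) {
  idx <- which(vapply(model$layers, function(l)
    l$type %in% c("lstm", "hlstm") ||
      (l$type == "dense" && !(l$activation == "sigmoid" && l$units == 1)),
    TRUE))
  idx
}

#' Plan a channel-level prune at quantile q
#'
#' Per prunable layer (every hidden layer; the output head is exempt), selects
#' the `floor(q * width)` lowest-scoring neurons. Ties break toward the lowest
#' index for determinism.
#'
#' @param model An `nnc_model`.
#' @param q Pruning quantile in (0, 1); the study used 0.25 and 0.5.
#' @param use_abs Passed to [score_neurons()].
#' @return A `prune_plan`: per layer, the indices slated for removal and the
#'   scores they were ranked by.
#' @export
plan_prune <- function(model, q, use_abs = TRUE) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1)
    stop("pruning quantile q must lie strictly in (0, 1)")
  idx <- prunable_idx(model)
  if (length(idx) == 0) stop("model has no prunable layer")
  layers <- list()
  for (li in idx) {
    l <- model$layers[[li]]
    sc <- score_neurons(l, use_abs)
    k <- floor(q * l$units)
    drop <- if (k > 0) sort(order(sc, seq_along(sc))[seq_len(k)]) else integer(0)
    layers[[l$name]] <- list(drop = drop, scores = sc)
  }
  structure(list(quantile = q, layers = layers), class = "prune_plan")
}

#' Apply a prune plan by surgical weight removal
#'
#' Each pruned neuron is removed together with every connection that touches
#' it: its incoming kernel columns (all four gate blocks for recurrent units),
#' its bias entries, its recurrent row and column, its hidden-kernel row and
#' column (hLSTM), and its outgoing rows in the next weight-bearing layer.
#' Surviving weights are carried over bit-identically.
#'
#' @param model An `nnc_model`.
#' @param plan A `prune_plan` built for this model.
#' @return The pruned `nnc_model` with reduced widths.
#' @export
apply_prune <- function(model, plan) {
  stopifnot(inherits(plan, "prune_plan"))
  idx <- prunable_idx(model)
  for (li in idx) {
    l <- model$layers[[li]]
    pl <- plan$layers[[l$name]]
    if (is.null(pl))
      stop("plan has no entry for layer '", l$name, "'")
    if (length(pl$drop) > 0 &&
        (min(pl$drop) < 1 || max(pl$drop) > l$units || anyDuplicated(pl$drop)))
      stop("plan indices out of range for layer '", l$name, "'")
    keep <- setdiff(seq_len(l$units), pl$drop)
    U <- l$units
    if (l$type == "dense") {
      l$W <- l$W[, keep, drop = FALSE]
      l$b <- l$b[keep]
    } else {
      gcols <- as.vector(vapply(0:3, function(g) g * U + keep,
                                numeric(length(keep))))
      l$Wx <- l$Wx[, gcols, drop = FALSE]
      l$Wh <- l$Wh[keep, gcols, drop = FALSE]
      if (!is.null(l$Hk)) l$Hk <- l$Hk[keep, gcols, drop = FALSE]
      l$b <- l$b[gcols]
    }
    l$units <- length(keep)
    model$layers[[li]] <- l

    # remove the outgoing connections in the next weight-bearing layer
    for (lj in seq(li + 1, length(model$layers))) {
      if (lj > length(model$layers)) break
      nxt <- model$layers[[lj]]
      if (nxt$type == "dense") {
        nxt$W <- nxt$W[keep, , drop = FALSE]
        nxt$input_dim <- length(keep)
        model$layers[[lj]] <- nxt
        break
      }
      if (nxt$type %in% c("lstm", "hlstm")) {
        nxt$Wx <- nxt$Wx[keep, , drop = FALSE]
        nxt$input_dim <- length(keep)
        model$layers[[lj]] <- nxt
        break
      }
    }
  }
  model
}

#' Train, prune, retrain
#'
#' The published schedule: train the full model for `pre_epochs` (1), plan and
#' apply the prune at quantile `q`, then train the pruned model for
#' `post_epochs` (19) more epochs. Surviving weights are carried over, not
#' reinitialized; the optimizer state restarts after surgery.
#'
#' @param model Freshly built `nnc_model`.
#' @param x,y Training data (see [train()]).
#' @param q Pruning quantile in (0, 1).
#' @param config A [train_config()]; its `epochs` field is overridden by the
#'   schedule.
#' @param pre_epochs,post_epochs The 1 + 19 schedule by default.
#' @param test Optional test set for the per-epoch AUROC curve.
#' @return `list(model, plan, history)`; `history` spans all
#'   `pre_epochs + post_epochs` epochs with a `phase` column.
#' @export
prune_retrain <- function(model, x, y, q, config = train_config(),
                          pre_epochs = 1, post_epochs = 19, test = NULL) {
  cfg1 <- config; cfg1$epochs <- as.integer(pre_epochs)
  fit1 <- train(model, x, y, cfg1, test = test)
  plan <- plan_prune(fit1$model, q)
  pruned <- apply_prune(fit1$model, plan)
  cfg2 <- config; cfg2$epochs <- as.integer(post_epochs)
  cfg2$seed <- config$seed + 1L
  fit2 <- train(pruned, x, y, cfg2, test = test)
  tag <- function(h, phase) if (nrow(h) > 0) cbind(h, phase = phase)
    else cbind(h, phase = character(0))
  hist <- rbind(tag(fit1$history, "pre"), tag(fit2$history, "post"))
  hist$epoch <- seq_len(nrow(hist))
  list(model = fit2$model, plan = plan, history = hist)
}

#' Prune-plan JSON I/O
#' @param plan A `prune_plan`.
#' @param path File path.
#' @name prune_plan_io
#' @export
write_prune_plan <- function(plan, path) {
  jsonlite::write_json(list(quantile = plan$quantile, layers = plan$layers),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname prune_plan_io
#' @export
read_prune_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(quantile = x$quantile,
                 layers = lapply(x$layers, function(l)
                   list(drop = as.integer(l$drop), scores = l$scores))),
            class = "prune_plan")
}
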