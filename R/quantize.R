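#' Uniform affine 8-bit quantization of a tensor
#'
#' Maps the float range `(F_min, F_max)` of the tensor onto integer codes
#' `(0, 255)`: `scale = (F_max - F_min) / 255` and
#' `code = round((x - F_min) / scale)` with round-half-away-from-zero,
#' clipped to `[0, 255]`. A constant tensor degenerates to `scale = 0` and
#' all-zero codes, which dequantize exactly to the constant.
#'
#' @param x Numeric tensor (vector, matrix or array) with finite entries.
#' @return A `quantized_tensor`: integer `codes` (same shape), `f_min`,
#'   `f_max`, `scale`.
#' @export
quantize_tensor <- function(x) {
  if (!all(is.finite(x))) stop("cannot quantize non-finite entries")
  f_min <- min(x); f_max <- max(x)
  scale <- (f_max - f_min) / 255
  codes <- if (scale == 0) rep(0L, length(x))
  else {
    v <- (x - f_min) / scale
    k <- floor(v + 0.5)  # v >= 0, so this is round-half-away-from-zero
    as.integer(pmin(pmax(k, 0), 255))
  }
  dim(codes) <- dim(x)
  structure(list(codes = codes, f_min = f_min, f_max = f_max, scale = scale),
            class = "quantized_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname quantize_tensor
#' @param q A `quantized_tensor`.
#' @return `dequantize_tensor()`: the reconstruction
#'   `F_min + scale * codes`; elementwise error of a round trip is at most
#'   `scale / 2`.
#' @export
dequantize_tensor <- function(q) {
  stopifnot(inherits(q, "quantized_tensor"))
  out <- q$f_min + q$scale * as.vector(q$codes)
  dim(out) <- dim(q$codes)
  out
}

#' Post-training quantization of a whole model
#'
#' Every weight and bias tensor is quantized per tensor (one
#' `(F_min, F_max)` pair each). Inference is simulated quantization: weights
#' are dequantized and the forward pass runs in real arithmetic, which is
#' what the accuracy comparison measures. The stored payload is 1 byte per
#' parameter plus 8 bytes of range metadata per tensor, against 4 bytes per
#' parameter for the float model.
#'
#' @param model A trained `nnc_model`.
#' @return An `nnc_qmodel` whose weight slots hold `quantized_tensor`s.
#' @export
quantize_model <- function(model) {
  stopifnot(inherits(model, "nnc_model"))
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    for (w in intersect(names(l), c("Wx", "Wh", "Hk", "b", "W")))
      l[[w]] <- quantize_tensor(l[[w]])
    model$layers[[li]] <- l
  }
  class(model) <- c("nnc_qmodel", "nnc_model")
  model
}

#' @rdname quantize_model
#' @param qmodel An `nnc_qmodel`.
#' @return `dequantize_model()`: the `nnc_model` with reconstructed float
#'   weights that simulated-quantization inference runs on.
#' @export
dequantize_model <- function(qmodel) {
  stopifnot(inherits(qmodel, "nnc_qmodel"))
  for (li in seq_along(qmodel$layers)) {
    l <- qmodel$layers[[li]]
    for (w in intersect(names(l), c("Wx", "Wh", "Hk", "b", "W")))
      if (inherits(l[[w]], "quantized_tensor")) {
        x <- dequantize_tensor(l[[w]])
        if (w == "b") x <- as.vector(x)
        l[[w]] <- x
      }
    qmodel$layers[[li]] <- l
  }
  class(qmodel) <- "nnc_model"
  qmodel
}

#' @rdname quantize_model
#' @param x Model inputs (see [predict.nnc_model()]).
#' @param quantize_activations Also quantize/dequantize each hidden
#'   activation on the fly (dynamic ranges). Off by default; accuracy
#'   comparisons use weights-only quantization.
#' @return `quantized_forward()`: risk scores in (0, 1).
#' @export
quantized_forward <- function(qmodel, x, quantize_activations = FALSE) {
  m <- dequantize_model(qmodel)
  if (!quantize_activations) return(predict(m, x))
  if (m$kind != "dnn")
    stop("activation quantization is implemented for feedforward models only")
  cur <- matrix(x, ncol = m$input_dim)
  for (l in m$layers) {
    if (l$type == "dense") {
      cur <- dense_forward(cur, l)
      if (!(l$activation == "sigmoid" && l$units == 1))
        cur <- dequantize_tensor(quantize_tensor(cur))
    }
  }
  as.vector(cur)
}

#' Serialized weight payload in bytes
#'
#' Float models store each parameter as a 32-bit float; quantized models store
#' one byte per parameter plus two 32-bit range floats per tensor. This is the
#' byte count of the on-disk payload written by [serialize_weights_bin()].
#'
#' @param model An `nnc_model` or `nnc_qmodel`.
#' @return Integer byte count.
#' @export
payload_bytes <- function(model) {
  n_tensors <- 0L
  n_params <- 0L
  for (l in model$layers)
    for (w in intersect(names(l), c("Wx", "Wh", "Hk", "b", "W"))) {
      n_tensors <- n_tensors + 1L
      t_ <- l[[w]]
      n_params <- n_params + length(if (inherits(t_, "quantized_tensor"))
        t_$codes else t_)
    }
  if (inherits(model, "nnc_qmodel")) n_params + 8L * n_tensors
  else 4L * n_params
}
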