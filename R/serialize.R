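#' Bit-exact weight container (JSON, one group per layer)
#'
#' Layers are written in order with their structural fields; each tensor is
#' stored as its dimensions plus a base64 string of little-endian IEEE-754
#' doubles (quantized tensors: unsigned bytes plus their float range), so a
#' reload reproduces the weights bit-exactly. Gate blocks keep the fixed
#' f, i, o, c order.
#'
#' @param model An `nnc_model` or `nnc_qmodel`.
#' @param path Output path.
#' @name weights_io
#' @export
save_weights <- function(model, path) {
  enc_num <- function(x) list(dim = dim(x) %||% length(x),
                              data = jsonlite::base64_enc(
                                writeBin(as.vector(as.numeric(x)), raw(),
                                         size = 8, endian = "little")))
  enc <- function(t_) {
    if (inherits(t_, "quantized_tensor"))
      list(quantized = TRUE, dim = dim(t_$codes) %||% length(t_$codes),
           range = jsonlite::base64_enc(
             writeBin(c(t_$f_min, t_$f_max), raw(), size = 8,
                      endian = "little")),
           data = jsonlite::base64_enc(as.raw(as.vector(t_$codes))))
    else enc_num(t_)
  }
  layers <- lapply(model$layers, function(l) {
    out <- l[intersect(names(l),
                       c("type", "name", "units", "input_dim", "rate",
                         "activation"))]
    for (w in intersect(names(l), c("Wx", "Wh", "Hk", "b", "W")))
      out[[w]] <- enc(l[[w]])
    out
  })
  jsonlite::write_json(list(format = "nncondense-weights-1",
                            kind = model$kind, input_dim = model$input_dim,
                            quantized = inherits(model, "nnc_qmodel"),
                            layers = layers),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname weights_io
#' @export
load_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec <- function(t_) {
    dm <- unlist(t_$dim)
    if (isTRUE(t_$quantized)) {
      codes <- as.integer(jsonlite::base64_dec(t_$data))
      if (length(dm) > 1) dim(codes) <- dm
      rng <- readBin(jsonlite::base64_dec(t_$range), "double", n = 2,
                     size = 8, endian = "little")
      f_min <- rng[1]; f_max <- rng[2]
      structure(list(codes = codes, f_min = f_min, f_max = f_max,
                     scale = (f_max - f_min) / 255),
                class = "quantized_tensor")
    } else {
      v <- readBin(jsonlite::base64_dec(t_$data), "double",
                   n = prod(dm), size = 8, endian = "little")
      if (length(dm) > 1) dim(v) <- dm
      v
    }
  }
  layers <- lapply(x$layers, function(l) {
    out <- l[intersect(names(l),
                       c("type", "name", "units", "input_dim", "rate",
                         "activation"))]
    if (!is.null(l$units)) out$units <- as.integer(l$units)
    if (!is.null(l$input_dim)) out$input_dim <- as.integer(l$input_dim)
    if (!is.null(l$rate)) out$rate <- as.numeric(l$rate)
    for (w in intersect(names(l), c("Wx", "Wh", "Hk", "b", "W")))
      out[[w]] <- dec(l[[w]])
    out
  })
  m <- new_model(layers, kind = x$kind, input_dim = as.integer(x$input_dim))
  if (isTRUE(x$quantized)) class(m) <- c("nnc_qmodel", "nnc_model")
  m
}

#' Raw binary weight payload (for size accounting)
#'
#' Writes only the numeric payload: 32-bit floats for float models, or one
#' unsigned byte per parameter plus the two 32-bit range floats per tensor for
#' quantized models. The resulting file size is the `serialized_bytes`
#' reported by [measure()].
#'
#' @param model An `nnc_model` or `nnc_qmodel`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
serialize_weights_bin <- function(model, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (l in model$layers)
    for (w in intersect(names(l), c("Wx", "Wh", "Hk", "b", "W"))) {
      t_ <- l[[w]]
      if (inherits(t_, "quantized_tensor")) {
        writeBin(c(t_$f_min, t_$f_max), con, size = 4, endian = "little")
        writeBin(as.raw(as.vector(t_$codes)), con)
      } else {
        writeBin(as.vector(as.numeric(t_)), con, size = 4, endian = "little")
      }
    }
  invisible(path)
}
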