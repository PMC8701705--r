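#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) form with midranks, so ties receive half
#' credit: the returned value equals
#' `P(score_pos > score_neg) + 0.5 P(score_pos == score_neg)` over all
#' positive/negative pairs.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1), same length; both classes must be
#'   present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC needs at least one positive and one negative label")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained model
#'
#' Fills the published performance sheet: test AUROC, trainable parameter
#' count, on-disk weight-payload size, and per-patient inference time
#' (averaged over at least `repeats` timed passes over the test set).
#'
#' @param model A trained `nnc_model` or `nnc_qmodel`.
#' @param x,y Test inputs and labels (shapes as in [predict.nnc_model()]).
#' @param history Optional per-epoch history to attach.
#' @param repeats Timing repeats (>= 3 recommended).
#' @return An `eval_report` list.
#' @export
measure <- function(model, x, y, history = NULL, repeats = 3) {
  fwd <- function() {
    if (inherits(model, "nnc_qmodel")) quantized_forward(model, x)
    else predict(model, x)
  }
  scores <- fwd()
  n <- length(y)
  times <- vapply(seq_len(max(repeats, 1)), function(i)
    unname(system.time(fwd())["elapsed"]), 0)
  path <- tempfile(fileext = ".bin")
  on.exit(unlink(path))
  serialize_weights_bin(model, path)
  structure(list(
    auroc = auroc(scores, y),
    param_count = count_params(model),
    serialized_bytes = as.integer(file.size(path)),
    inference_seconds_per_sample = mean(times) / n,
    n_test = n,
    history = history
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUROC %.3f, %d parameters, %d payload bytes, %.2e s/sample (n = %d)\n",
              x$auroc, x$param_count, x$serialized_bytes,
              x$inference_seconds_per_sample, x$n_test))
  invisible(x)
}

#' Evaluation-report JSON I/O
#'
#' Reports round-trip losslessly (numbers written at full precision).
#' @param report An `eval_report`.
#' @param path File path.
#' @name report_io
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname report_io
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$history)) x$history <- as.data.frame(x$history)
  structure(x, class = "eval_report")
}
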