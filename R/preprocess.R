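#' Model input layout implied by a feature roster
#'
#' Continuous variables contribute one value column; categorical variables
#' contribute one column per category (one-hot). Each raw variable also gets
#' one binary observation-mask channel, appended after the value columns in
#' the model input. The default roster yields 40 value columns + 36 mask
#' channels = 76 input dimensions.
#'
#' @param features List of [feature_spec()]s.
#' @return List with `value_cols` (column names), `col_map` (per raw variable,
#'   the value-column indices), `raw_names`, and `input_dim`.
#' @export
feature_layout <- function(features) {
  raw_names <- vapply(features, `[[`, "", "name")
  cols <- character(0)
  col_map <- vector("list", length(features))
  for (j in seq_along(features)) {
    f <- features[[j]]
    cj <- if (f$kind == "continuous") f$name
          else paste(f$name, f$categories, sep = "=")
    col_map[[j]] <- length(cols) + seq_along(cj)
    cols <- c(cols, cj)
  }
  names(col_map) <- raw_names
  list(value_cols = cols, col_map = col_map, raw_names = raw_names,
       input_dim = length(cols) + length(features))
}

#' Resample an irregular event stream onto a regular grid
#'
#' Bins the first `horizon` hours into `horizon / bin_width` steps. Within a
#' bin, the chronologically last measurement of each variable wins. Bins with
#' a measurement get mask 1; empty bins keep an `NA` placeholder (value
#' columns) and mask 0 until [impute_episode()] fills them. Categorical
#' observations are one-hot encoded.
#'
#' @param record A `patient_record`.
#' @param features Feature roster (list of [feature_spec()]).
#' @param bin_width Bin width in hours; must divide `horizon`.
#' @param horizon Window length in hours (default 48).
#' @return An `episode_tensor`: `values` (T x value-columns, `NA` where
#'   unobserved), `mask` (T x raw variables, 0/1), `label`, `patient_id`.
#' @export
resample_episode <- function(record, features, bin_width = 1, horizon = 48) {
  lay <- feature_layout(features)
  T_ <- horizon / bin_width
  if (abs(T_ - round(T_)) > 1e-9) stop("bin_width must divide horizon")
  T_ <- as.integer(round(T_))
  values <- matrix(NA_real_, T_, length(lay$value_cols),
                   dimnames = list(NULL, lay$value_cols))
  mask <- matrix(0L, T_, length(features),
                 dimnames = list(NULL, lay$raw_names))
  ev <- record$events
  if (nrow(ev) > 0) {
    if (any(ev$time_hours < 0 | ev$time_hours > horizon))
      stop("event outside [0, horizon] for patient ", record$patient_id)
    unknown <- setdiff(unique(ev$variable), lay$raw_names)
    if (length(unknown) > 0)
      stop("unknown variable(s): ", paste(unknown, collapse = ", "))
    bin <- pmin(floor(ev$time_hours / bin_width) + 1L, T_)
    ord <- order(ev$variable, bin, ev$time_hours)
    last <- ord[!duplicated(cbind(ev$variable, bin)[ord, , drop = FALSE],
                            fromLast = TRUE)]
    for (i in last) {
      j <- match(ev$variable[i], lay$raw_names)
      f <- features[[j]]
      cols <- lay$col_map[[j]]
      if (f$kind == "continuous") {
        values[bin[i], cols] <- as.numeric(ev$value[i])
      } else {
        oh <- as.numeric(f$categories == ev$value[i])
        if (sum(oh) != 1)
          stop("value '", ev$value[i], "' is not a category of ", f$name)
        values[bin[i], cols] <- oh
      }
      mask[bin[i], j] <- 1L
    }
  }
  structure(list(values = values, mask = mask, label = record$label,
                 patient_id = record$patient_id,
                 bin_width = bin_width, horizon = horizon,
                 imputed = FALSE, normalized = FALSE),
            class = "episode_tensor")
}

# last-observation-carried-forward with a fallback for the leading run
locf <- function(x, fallback) {
  obs <- !is.na(x)
  idx <- cumsum(obs)
  out <- c(fallback, x[obs])[idx + 1L]
  out
}

#' Impute a resampled episode
#'
#' Missing bins take the most recent observed value of the same variable
#' (forward fill); bins before the first observation take the variable's
#' prespecified normal value. The observation mask is unchanged.
#'
#' @param episode An `episode_tensor` from [resample_episode()].
#' @param features Feature roster used to resample it.
#' @return The episode with no missing values and `imputed = TRUE`.
#' @export
impute_episode <- function(episode, features) {
  lay <- feature_layout(features)
  v <- episode$values
  for (j in seq_along(features)) {
    f <- features[[j]]
    cols <- lay$col_map[[j]]
    if (f$kind == "continuous") {
      if (is.null(f$normal_value) || is.na(f$normal_value))
        stop("feature '", f$name, "' needs a normal_value for imputation")
      v[, cols] <- locf(v[, cols], as.numeric(f$normal_value))
    } else {
      # carry the observed category index forward, then re-expand one-hot
      block <- v[, cols, drop = FALSE]
      cat_idx <- rep(NA_integer_, nrow(block))
      obs <- episode$mask[, j] == 1L | !is.na(block[, 1])
      if (any(obs))
        cat_idx[obs] <- max.col(block[obs, , drop = FALSE], ties.method = "first")
      cat_idx <- locf(cat_idx, match(f$normal_value, f$categories))
      v[, cols] <- 0
      v[cbind(seq_len(nrow(block)), cols[cat_idx])] <- 1
    }
  }
  episode$values <- v
  episode$imputed <- TRUE
  episode
}

#' Normalization statistics
#'
#' Per value-column mean and standard deviation, computed on imputed training
#' episodes (all bins pooled). Constant columns get their sd replaced by 1 so
#' they normalize to exact zeros. Mask channels are never normalized.
#'
#' @param episodes List of imputed `episode_tensor`s (training split only).
#' @return A `norm_stats` object with `mean` and `sd` vectors.
#' @export
fit_norm_stats <- function(episodes) {
  stopifnot(length(episodes) > 0)
  d <- ncol(episodes[[1]]$values)
  n <- 0; s1 <- numeric(d); s2 <- numeric(d)
  for (e in episodes) {
    if (!e$imputed) stop("fit_norm_stats expects imputed episodes")
    s1 <- s1 + colSums(e$values)
    s2 <- s2 + colSums(e$values^2)
    n <- n + nrow(e$values)
  }
  mu <- s1 / n
  var <- pmax(s2 / n - mu^2, 0)
  sd <- sqrt(var)
  sd[sd < 1e-12] <- 1
  structure(list(mean = stats::setNames(mu, colnames(episodes[[1]]$values)),
                 sd = sd, n_bins = n),
            class = "norm_stats")
}

#' @rdname fit_norm_stats
#' @param episode Episode to normalize.
#' @param stats A `norm_stats` fitted on the training split.
#' @export
normalize_episode <- function(episode, stats) {
  if (ncol(episode$values) != length(stats$mean))
    stop("dimension mismatch between episode and normalization statistics")
  episode$values <- sweep(sweep(episode$values, 2, stats$mean), 2, stats$sd, "/")
  episode$normalized <- TRUE
  episode
}

#' @rdname fit_norm_stats
#' @param path YAML file path.
#' @export
write_norm_stats <- function(stats, path) {
  yaml::write_yaml(list(mean = as.list(stats$mean), sd = as.list(stats$sd),
                        n_bins = stats$n_bins), path)
  invisible(path)
}

#' @rdname fit_norm_stats
#' @export
read_norm_stats <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(mean = unlist(x$mean), sd = unlist(x$sd), n_bins = x$n_bins),
            class = "norm_stats")
}

#' Concatenated model input of one episode
#'
#' Value columns followed by the observation-mask channels; with the default
#' roster this is the 76-wide recurrent-model input.
#' @param episode Imputed (and normally normalized) episode.
#' @return T x D numeric matrix.
#' @export
model_input <- function(episode) {
  cbind(episode$values, episode$mask)
}

#' Time-collapsed input vector for the feedforward model
#'
#' Per value column, the mean over bins whose variable was truly observed
#' (mask 1); never-observed variables fall back to their (constant) imputed,
#' normalized value. Mask channels are collapsed to the observed fraction.
#'
#' @param episode Imputed, normalized episode.
#' @param features Feature roster.
#' @return Numeric vector of length `feature_layout(features)$input_dim`.
#' @export
flatten_for_dnn <- function(episode, features) {
  lay <- feature_layout(features)
  out <- numeric(length(lay$value_cols))
  for (j in seq_along(features)) {
    cols <- lay$col_map[[j]]
    obs <- episode$mask[, j] == 1L
    out[cols] <- if (any(obs))
      colMeans(episode$values[obs, cols, drop = FALSE])
    else colMeans(episode$values[, cols, drop = FALSE])
  }
  stats::setNames(c(out, colMeans(episode$mask)),
                  c(lay$value_cols, paste0("mask_", lay$raw_names)))
}

#' End-to-end preprocessing of a split cohort
#'
#' Resamples, imputes, fits normalization statistics on the training split
#' only, normalizes both splits, and assembles the recurrent-model arrays
#' (T x D x N) and the feedforward design matrices (N x D).
#'
#' @param train,test Lists of `patient_record`s.
#' @param features Feature roster.
#' @param bin_width,horizon Grid parameters in hours.
#' @return List with `train`/`test` (each `x` array, `flat` matrix, `y`,
#'   `ids`), the fitted `stats`, and the layout.
#' @export
preprocess_cohort <- function(train, test, features = default_features(),
                              bin_width = 1, horizon = 48) {
  prep <- function(recs) lapply(recs, function(r)
    impute_episode(resample_episode(r, features, bin_width, horizon), features))
  tr <- prep(train)
  te <- prep(test)
  stats <- fit_norm_stats(tr)
  pack <- function(eps) {
    eps <- lapply(eps, normalize_episode, stats = stats)
    T_ <- nrow(eps[[1]]$values)
    D <- feature_layout(features)$input_dim
    x <- array(0, c(T_, D, length(eps)))
    flat <- matrix(0, length(eps), D)
    for (i in seq_along(eps)) {
      x[, , i] <- model_input(eps[[i]])
      flat[i, ] <- flatten_for_dnn(eps[[i]], features)
    }
    list(x = x, flat = flat,
         y = vapply(eps, `[[`, 0L, "label"),
         ids = vapply(eps, `[[`, "", "patient_id"))
  }
  list(train = pack(tr), test = pack(te), stats = stats,
       layout = feature_layout(features))
}
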