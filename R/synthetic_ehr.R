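#' Feature specification
#'
#' Describes one raw clinical variable: how it is generated, how often it is
#' observed, and what "normal" value is used for imputation when a patient has
#' no prior observation of it.
#'
#' @param name Variable identifier.
#' @param kind `"continuous"` or `"categorical"`.
#' @param normal_value Fallback value used by the imputer when no previous
#'   observation exists. For categorical variables, one of `categories`.
#' @param categories Ordered character vector of category labels
#'   (categorical variables only, at least two).
#' @param population_mean,population_sd Generating-distribution parameters of
#'   the latent patient level (continuous variables; `population_sd > 0`).
#' @param observe_rate Expected number of observations per hour (>= 0); event
#'   times follow a homogeneous Poisson process at this rate.
#'
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("continuous", "categorical"),
                         normal_value, categories = NULL,
                         population_mean = 0, population_sd = 1,
                         observe_rate = 1) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2)
      stop("categorical feature '", name, "' needs >= 2 categories")
    if (!normal_value %in% categories)
      stop("normal_value of '", name, "' must be one of its categories")
  } else {
    if (!is.finite(population_sd) || population_sd <= 0)
      stop("continuous feature '", name, "' needs population_sd > 0")
    categories <- NULL
  }
  if (observe_rate < 0) stop("observe_rate of '", name, "' must be >= 0")
  structure(list(name = name, kind = kind, normal_value = normal_value,
                 categories = categories, population_mean = population_mean,
                 population_sd = population_sd, observe_rate = observe_rate),
            class = "feature_spec")
}

#' Default ICU feature roster
#'
#' 36 raw variables: 34 continuous (vital signs plus generic laboratory
#' channels) and 2 categorical (capillary refill, a banded coma score).
#' One-hot expansion yields 40 value columns; together with one observation
#' mask channel per raw variable this produces the 76 model input dimensions
#' consumed by all bundled architectures.
#'
#' @return List of [feature_spec()] objects.
#' @export
default_features <- function() {
  vitals <- list(
    # name, mean, sd, normal, rate (per hour)
    list("heart_rate",                85,   15,  80,   1),
    list("respiratory_rate",          19,    5,  16,   1),
    list("systolic_blood_pressure",  120,   20, 120,   1),
    list("diastolic_blood_pressure",  65,   12,  70,   1),
    list("mean_blood_pressure",       80,   12,  85,   1),
    list("oxygen_saturation",         96.5,  2.5, 98,  1),
    list("temperature",               37,    0.7, 36.8, 0.5),
    list("glucose",                  130,   40, 110,   0.25),
    list("ph",                         7.38, 0.06, 7.4, 0.25),
    list("fraction_inspired_oxygen",   0.5,  0.15, 0.21, 0.25),
    list("height",                   170,   10, 170,   0.05),
    list("weight",                    80,   15,  80,   0.1)
  )
  feats <- lapply(vitals, function(v)
    feature_spec(v[[1]], "continuous", normal_value = v[[4]],
                 population_mean = v[[2]], population_sd = v[[3]],
                 observe_rate = v[[5]]))
  labs <- lapply(sprintf("lab_%02d", 1:22), function(nm)
    feature_spec(nm, "continuous", normal_value = 0,
                 population_mean = 0, population_sd = 1,
                 observe_rate = 0.125))
  cats <- list(
    feature_spec("capillary_refill", "categorical", normal_value = "normal",
                 categories = c("normal", "abnormal"), observe_rate = 0.25),
    feature_spec("gcs_band", "categorical", normal_value = "normal",
                 categories = c("severe", "moderate", "mild", "normal"),
                 observe_rate = 0.25)
  )
  c(feats, labs, cats)
}

#' Cohort configuration
#'
#' @param n_patients Number of ICU stays to simulate.
#' @param features List of [feature_spec()]; defaults to [default_features()].
#' @param horizon_hours Observation window in hours (default 48, the standard
#'   early-mortality-prediction window).
#' @param prevalence Target in-hospital mortality rate in (0, 1); default
#'   0.109.
#' @param signal_weights Per-feature coefficients of the logistic label model
#'   acting on the per-patient latent levels; length must equal
#'   `length(features)`. The default puts weight on twelve physiology channels
#'   and both categorical scores, a strong, learnable signal.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   linear predictor (> 0).
#' @param latent_cor Correlation of every latent channel with one shared
#'   patient-severity factor (0 = independent channels, the default).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#'
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, features = default_features(),
                          horizon_hours = 48, prevalence = 0.109,
                          signal_weights = default_signal_weights(features),
                          noise_sd = 0.5, latent_cor = 0, seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1)
    stop("invalid config: n_patients must be a positive integer")
  if (prevalence <= 0 || prevalence >= 1)
    stop("invalid config: prevalence must lie strictly in (0, 1)")
  if (length(signal_weights) != length(features))
    stop("invalid config: signal_weights must have one entry per feature")
  if (noise_sd <= 0) stop("invalid config: noise_sd must be > 0")
  if (latent_cor < 0 || latent_cor >= 1)
    stop("invalid config: latent_cor must lie in [0, 1)")
  structure(list(n_patients = as.integer(n_patients), features = features,
                 horizon_hours = horizon_hours, prevalence = prevalence,
                 signal_weights = as.numeric(signal_weights),
                 noise_sd = noise_sd, latent_cor = latent_cor,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_signal_weights <- function(features) {
  nm <- vapply(features, `[[`, "", "name")
  w <- numeric(length(features))
  strong <- c("heart_rate", "respiratory_rate", "systolic_blood_pressure",
              "mean_blood_pressure", "oxygen_saturation", "temperature",
              "glucose", "ph", "fraction_inspired_oxygen",
              "lab_01", "lab_02", "lab_03")
  w[nm %in% strong] <- 0.8
  w[nm %in% c("capillary_refill", "gcs_band")] <- 0.6
  w
}

# Relative measurement noise (in units of population_sd) added to each
# observation around the patient's latent level.
MEASUREMENT_NOISE <- 0.3

#' Generate a synthetic ICU cohort
#'
#' Each patient has one latent level per raw variable (standard normal,
#' optionally sharing a severity factor). Observations arrive as a homogeneous
#' Poisson process per variable over the horizon; continuous values are the
#' latent level plus measurement noise on the variable's population scale, and
#' categorical values are drawn by thresholding the noisy latent at equal
#' population quantiles. The in-hospital mortality label is Bernoulli with a
#' logistic probability that is linear in the latent levels; the intercept is
#' solved by bisection so the expected prevalence over the realized cohort
#' equals the configured prevalence.
#'
#' @param config A [cohort_config()].
#' @return A list of `patient_record` objects, each with `patient_id`,
#'   `events` (data.frame: `time_hours`, `variable`, `value`) and binary
#'   `label`. The patients-by-features matrix of latent levels is attached as
#'   attribute `"latent"` (ground truth for calibration studies; the Bayes
#'   linear score is `latent %*% signal_weights`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  feats <- config$features
  R <- length(feats)
  horizon <- config$horizon_hours

  rho <- config$latent_cor
  common <- rnorm(n)
  Z <- matrix(rnorm(n * R), n, R)
  if (rho > 0) Z <- sqrt(1 - rho) * Z + sqrt(rho) * common

  # labels: logistic in the latent levels, intercept calibrated by bisection
  s <- as.vector(Z %*% config$signal_weights) + config$noise_sd * rnorm(n)
  b0 <- calibrate_intercept(s, config$prevalence)
  p <- stats::plogis(b0 + s)
  labels <- as.integer(stats::runif(n) < p)

  # observation process, vectorized per feature
  pieces <- vector("list", R)
  for (j in seq_len(R)) {
    f <- feats[[j]]
    counts <- stats::rpois(n, f$observe_rate * horizon)
    tot <- sum(counts)
    if (tot == 0) next
    pid <- rep.int(seq_len(n), counts)
    times <- stats::runif(tot, 0, horizon)
    latent <- Z[pid, j] + MEASUREMENT_NOISE * stats::rnorm(tot)
    if (f$kind == "continuous") {
      val <- f$population_mean + f$population_sd * latent
      value <- formatC(val, digits = 15, format = "g")
    } else {
      k <- length(f$categories)
      idx <- findInterval(stats::pnorm(latent / sqrt(1 + MEASUREMENT_NOISE^2)),
                          seq_len(k - 1) / k) + 1L
      value <- f$categories[idx]
    }
    pieces[[j]] <- data.frame(patient = pid, time_hours = times,
                              variable = f$name, value = value,
                              stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, pieces)

  records <- vector("list", n)
  ids <- sprintf("pt%06d", seq_len(n))
  if (is.null(ev)) {
    empty <- data.frame(time_hours = numeric(), variable = character(),
                        value = character(), stringsAsFactors = FALSE)
    for (i in seq_len(n))
      records[[i]] <- patient_record(ids[i], empty, labels[i])
  } else {
    ev <- ev[order(ev$patient, ev$time_hours), ]
    idx <- split(seq_len(nrow(ev)), factor(ev$patient, levels = seq_len(n)))
    for (i in seq_len(n)) {
      e <- ev[idx[[i]], c("time_hours", "variable", "value")]
      rownames(e) <- NULL
      records[[i]] <- patient_record(ids[i], e, labels[i])
    }
  }
  attr(records, "latent") <- Z
  records
}

#' @keywords internal
patient_record <- function(patient_id, events, label) {
  structure(list(patient_id = patient_id, events = events,
                 label = as.integer(label)),
            class = "patient_record")
}

# Bisection for the intercept b of mean(plogis(b + s)) = prevalence; the mean
# is strictly increasing in b so the root is unique.
calibrate_intercept <- function(s, prevalence, tol = 1e-10) {
  f <- function(b) mean(stats::plogis(b + s)) - prevalence
  lo <- -30; hi <- 30
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Patient-level train/test split
#'
#' Seeded shuffle followed by a disjoint partition; the test set receives
#' `round(test_fraction * n)` stays (15% of 33,798 stays gives the
#' conventional 5070-stay test set).
#'
#' @param records List of `patient_record`s.
#' @param test_fraction Fraction in (0, 1).
#' @param seed Integer seed for the shuffle.
#' @return `list(train = ..., test = ...)`.
#' @export
split_cohort <- function(records, test_fraction, seed = 1L) {
  n <- length(records)
  if (n == 0) stop("cannot split an empty cohort")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly in (0, 1)")
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- round(test_fraction * n)
  list(train = records[perm[(n_test + 1):n]],
       test = records[perm[seq_len(n_test)]])
}

#' Cohort I/O: long-format event tables and labels
#'
#' Events are written one per row as (`patient_id`, `time_hours`, `variable`,
#' `value`); labels as a two-column table. `write_events_jsonl()` writes one
#' JSON object per line instead.
#'
#' @param records List of `patient_record`s.
#' @param events_path,labels_path Output file paths.
#' @name cohort_io
#' @export
write_cohort_csv <- function(records, events_path, labels_path) {
  ev <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$events) == 0) return(NULL)
    cbind(patient_id = r$patient_id, r$events)
  }))
  if (is.null(ev))
    ev <- data.frame(patient_id = character(), time_hours = numeric(),
                     variable = character(), value = character())
  utils::write.csv(ev, events_path, row.names = FALSE)
  lab <- data.frame(patient_id = vapply(records, `[[`, "", "patient_id"),
                    label = vapply(records, `[[`, 0L, "label"))
  utils::write.csv(lab, labels_path, row.names = FALSE)
  invisible(c(events_path, labels_path))
}

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(events_path, labels_path) {
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(ev)), factor(ev$patient_id, levels = lab$patient_id))
  lapply(seq_len(nrow(lab)), function(i) {
    e <- ev[idx[[i]], c("time_hours", "variable", "value")]
    rownames(e) <- NULL
    patient_record(lab$patient_id[i], e, lab$label[i])
  })
}

#' @rdname cohort_io
#' @export
write_events_jsonl <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in records) {
    if (nrow(r$events) == 0) next
    for (i in seq_len(nrow(r$events)))
      writeLines(jsonlite::toJSON(
        list(patient_id = r$patient_id,
             time_hours = r$events$time_hours[i],
             variable = r$events$variable[i],
             value = r$events$value[i]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Feature roster I/O as a plain CSV table
#'
#' Categories are pipe-separated in a single column.
#' @param features List of [feature_spec()]s.
#' @param path File path.
#' @name roster_io
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(
    name = vapply(features, `[[`, "", "name"),
    kind = vapply(features, `[[`, "", "kind"),
    normal_value = vapply(features, function(f) as.character(f$normal_value), ""),
    categories = vapply(features, function(f)
      if (is.null(f$categories)) "" else paste(f$categories, collapse = "|"), ""),
    population_mean = vapply(features, `[[`, 0, "population_mean"),
    population_sd = vapply(features, `[[`, 0, "population_sd"),
    observe_rate = vapply(features, `[[`, 0, "observe_rate"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname roster_io
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    cats <- if (nzchar(df$categories[i]))
      strsplit(df$categories[i], "|", fixed = TRUE)[[1]] else NULL
    nv <- if (df$kind[i] == "continuous") as.numeric(df$normal_value[i])
          else df$normal_value[i]
    feature_spec(df$name[i], df$kind[i], normal_value = nv, categories = cats,
                 population_mean = df$population_mean[i],
                 population_sd = df$population_sd[i],
                 observe_rate = df$observe_rate[i])
  })
}
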