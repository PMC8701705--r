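#' Validate a pipeline run configuration
#'
#' A run configuration (usually read from YAML) has sections `cohort`
#' (n_patients, prevalence, noise_sd, seed, ...), `preprocess` (bin_width,
#' horizon), `model` (one of lstm, hlstm, dnn), `condense` (one of none,
#' prune, quantize, prune+quantize, plus prune options), `train`
#' (learning_rate, batch_size, epochs), `test_fraction`, and `output_dir`.
#' Violations are reported with the offending field's name before any compute
#' starts.
#'
#' @param config Named list (parsed YAML).
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  fail <- function(field, msg) stop("invalid config field '", field, "': ",
                                    msg, call. = FALSE)
  cohort <- config$cohort %||% list()
  if (is.null(cohort$n_patients) || cohort$n_patients < 1)
    fail("cohort.n_patients", "must be a positive integer")
  prevalence <- cohort$prevalence %||% 0.109
  if (prevalence <= 0 || prevalence >= 1)
    fail("cohort.prevalence", "must lie strictly in (0, 1)")
  model <- config$model %||% "lstm"
  if (!model %in% c("lstm", "hlstm", "dnn"))
    fail("model", "must be one of lstm, hlstm, dnn")
  condense <- config$condense %||% "none"
  if (!condense %in% c("none", "prune", "quantize", "prune+quantize"))
    fail("condense", "must be one of none, prune, quantize, prune+quantize")
  q <- config$prune_quantile %||% 0.5
  if (q <= 0 || q >= 1)
    fail("prune_quantile", "must lie strictly in (0, 1)")
  tf <- config$test_fraction %||% 0.15
  if (tf <= 0 || tf >= 1)
    fail("test_fraction", "must lie strictly in (0, 1)")
  pp <- config$preprocess %||% list()
  bw <- pp$bin_width %||% 1
  hz <- pp$horizon %||% 48
  if (abs(hz / bw - round(hz / bw)) > 1e-9)
    fail("preprocess.bin_width", "must divide preprocess.horizon")
  tr <- config$train %||% list()
  epochs <- tr$epochs %||% 20
  if (epochs < 0) fail("train.epochs", "must be >= 0")
  list(cohort = list(n_patients = as.integer(cohort$n_patients),
                     prevalence = prevalence,
                     noise_sd = cohort$noise_sd %||% 0.5,
                     latent_cor = cohort$latent_cor %||% 0,
                     seed = as.integer(cohort$seed %||% 1)),
       preprocess = list(bin_width = bw, horizon = hz),
       model = model, condense = condense, prune_quantile = q,
       pre_epochs = as.integer(config$pre_epochs %||% 1),
       post_epochs = as.integer(config$post_epochs %||% (epochs - 1)),
       test_fraction = tf,
       train = list(learning_rate = tr$learning_rate %||% 0.001,
                    batch_size = as.integer(tr$batch_size %||% 8),
                    epochs = as.integer(epochs),
                    seed = as.integer(tr$seed %||% 1)),
       output_dir = config$output_dir %||% tempfile("nncondense_run_"))
}

#' Run the full pipeline from a YAML configuration
#'
#' simulate -> split -> preprocess -> build -> train -> condense -> evaluate.
#' Writes the weight container, prune plan (if any), evaluation report,
#' training history and a manifest of seeds and versions into
#' `output_dir`, and returns the reports invisibly.
#'
#' @param config Path to a YAML file, or an already-parsed named list.
#' @return (Invisibly) `list(report, float_report, manifest, output_dir)`;
#'   `float_report` is non-NULL when a condensation step produced a second
#'   model to compare against.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  features <- default_features()
  cc <- cohort_config(cfg$cohort$n_patients, features = features,
                      horizon_hours = cfg$preprocess$horizon,
                      prevalence = cfg$cohort$prevalence,
                      noise_sd = cfg$cohort$noise_sd,
                      latent_cor = cfg$cohort$latent_cor,
                      seed = cfg$cohort$seed)
  cohort <- generate_cohort(cc)
  sp <- split_cohort(cohort, cfg$test_fraction, seed = cfg$cohort$seed)
  prep <- preprocess_cohort(sp$train, sp$test, features,
                            bin_width = cfg$preprocess$bin_width,
                            horizon = cfg$preprocess$horizon)
  d <- prep$layout$input_dim
  is_dnn <- cfg$model == "dnn"
  builder <- switch(cfg$model, lstm = build_baseline_rnn,
                    hlstm = build_hlstm_rnn, dnn = build_dnn)
  model <- builder(input_dim = d, seed = cfg$train$seed)
  tcfg <- train_config(learning_rate = cfg$train$learning_rate,
                       batch_size = cfg$train$batch_size,
                       epochs = cfg$train$epochs, seed = cfg$train$seed)
  trx <- if (is_dnn) prep$train$flat else prep$train$x
  tex <- if (is_dnn) prep$test$flat else prep$test$x
  test <- list(x = tex, y = prep$test$y)

  plan <- NULL
  float_report <- NULL
  if (cfg$condense %in% c("prune", "prune+quantize")) {
    fit <- prune_retrain(model, trx, prep$train$y, cfg$prune_quantile, tcfg,
                         pre_epochs = cfg$pre_epochs,
                         post_epochs = cfg$post_epochs, test = test)
    plan <- fit$plan
    write_prune_plan(plan, file.path(cfg$output_dir, "prune_plan.json"))
  } else {
    fit <- train(model, trx, prep$train$y, tcfg, test = test)
  }
  final <- fit$model
  if (cfg$condense %in% c("quantize", "prune+quantize")) {
    float_report <- measure(final, tex, prep$test$y)
    final <- quantize_model(final)
  }

  report <- measure(final, tex, prep$test$y, history = fit$history)
  save_weights(final, file.path(cfg$output_dir, "weights.json"))
  write_report(report, file.path(cfg$output_dir, "report.json"))
  utils::write.csv(fit$history, file.path(cfg$output_dir, "history.csv"),
                   row.names = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("nncondense")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = cfg[setdiff(names(cfg), "output_dir")],
                   param_count = report$param_count)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, float_report = float_report,
                 manifest = manifest, output_dir = cfg$output_dir))
}
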