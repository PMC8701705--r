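feats <- tiny_features()

test_that("resampling keeps the last measurement per bin and sets the mask", {
  r <- record_from_events(c(0.2, 0.9, 3.5), c("hr", "hr", "hr"),
                          c(5, 7, 9))
  ep <- resample_episode(r, feats, bin_width = 1, horizon = 48)
  expect_equal(nrow(ep$values), 48)
  expect_equal(unname(ep$values[1, "hr"]), 7)  # 0.9 h beats 0.2 h within bin 1
  expect_equal(unname(ep$values[4, "hr"]), 9)
  expect_identical(unname(ep$mask[, "hr"]), c(1L, 0L, 0L, 1L, rep(0L, 44)))
  expect_true(all(is.na(ep$values[2:3, "hr"])))

  empty <- resample_episode(record_from_events(numeric(), character(),
                                               character()), feats)
  expect_true(all(empty$mask == 0L))
  expect_equal(dim(empty$values), c(48, 4))  # hr, bp, gcs one-hot (2)

  expect_error(resample_episode(record_from_events(49, "hr", 1), feats),
               "outside")
  expect_error(resample_episode(record_from_events(1, "unknown", 1), feats),
               "unknown variable")
})

test_that("categorical observations are one-hot encoded per time step", {
  r <- record_from_events(c(1.5, 5.5), c("gcs", "gcs"), c("low", "high"))
  ep <- resample_episode(r, feats)
  expect_equal(unname(ep$values[2, c("gcs=low", "gcs=high")]), c(1, 0))
  expect_equal(unname(ep$values[6, c("gcs=low", "gcs=high")]), c(0, 1))
  expect_identical(unname(ep$mask[c(2, 6), "gcs"]), c(1L, 1L))
  imp <- impute_episode(ep, feats)
  # forward fill of the category, normal category before the first observation
  expect_equal(unname(imp$values[1, c("gcs=low", "gcs=high")]), c(0, 1))
  expect_equal(unname(imp$values[4, c("gcs=low", "gcs=high")]), c(1, 0))
  expect_equal(unname(imp$values[48, c("gcs=low", "gcs=high")]), c(0, 1))
})

test_that("imputation forward-fills and falls back to the normal value", {
  r <- record_from_events(10.5, "hr", 99)  # observed only in bin 11
  ep <- impute_episode(resample_episode(r, feats), feats)
  expect_true(all(ep$values[1:10, "hr"] == 80))   # normal value
  expect_true(all(ep$values[11:48, "hr"] == 99))  # carried forward
  expect_true(all(ep$values[, "bp"] == 120))      # fully missing column
  expect_true(all(ep$mask[, "bp"] == 0L))
  expect_identical(unname(ep$mask[, "hr"])[11], 1L)  # mask untouched
  # idempotence
  expect_identical(impute_episode(ep, feats), ep)
})

test_that("mask bits equal a brute-force bin scan of the raw events", {
  set.seed(31)
  for (rep in 1:5) {
    n_ev <- 40
    r <- record_from_events(
      runif(n_ev, 0, 48),
      sample(c("hr", "bp"), n_ev, replace = TRUE),
      round(rnorm(n_ev, 100, 10), 3))
    ep <- resample_episode(r, feats)
    for (v in c("hr", "bp")) for (t in 1:48) {
      hit <- any(r$events$variable == v &
                   r$events$time_hours >= t - 1 & r$events$time_hours < t)
      expect_identical(unname(ep$mask[t, v] == 1L), hit)
    }
  }
})

test_that("z-normalization centers and scales the training split", {
  set.seed(32)
  recs <- lapply(1:12, function(i) {
    n_ev <- 30
    record_from_events(runif(n_ev, 0, 48),
                       sample(c("hr", "bp"), n_ev, replace = TRUE),
                       rnorm(n_ev, 100, 10), id = paste0("p", i))
  })
  eps <- lapply(recs, function(r)
    impute_episode(resample_episode(r, feats), feats))
  st <- fit_norm_stats(eps)
  normed <- lapply(eps, normalize_episode, stats = st)
  pooled <- do.call(rbind, lapply(normed, `[[`, "values"))
  expect_lt(max(abs(colMeans(pooled))), 1e-6)
  sds <- sqrt(colMeans(pooled^2))  # population sd of a centered column
  expect_lt(max(abs(sds[c("hr", "bp")] - 1)), 1e-6)

  # explicit arithmetic and the constant-column fallback
  st2 <- st; st2$mean[] <- 10; st2$sd[] <- 2
  ep2 <- eps[[1]]; ep2$values[] <- 14
  expect_true(all(normalize_episode(ep2, st2)$values == 2))
  constant <- eps[[1]]; constant$values[, "hr"] <- 7
  stc <- fit_norm_stats(list(constant))
  expect_equal(stc$sd[["hr"]], 1)  # sd fallback
  expect_true(all(normalize_episode(constant, stc)$values[, "hr"] == 0))

  st_bad <- st; st_bad$mean <- st_bad$mean[1:2]; st_bad$sd <- st_bad$sd[1:2]
  expect_error(normalize_episode(eps[[1]], st_bad), "mismatch")
})

test_that("flattening averages observed bins and keeps imputed constants", {
  r <- record_from_events(c(0.5, 5.5), c("hr", "hr"), c(2, 4))
  ep <- impute_episode(resample_episode(r, feats), feats)
  ident <- structure(list(mean = setNames(numeric(4), colnames(ep$values)),
                          sd = rep(1, 4), n_bins = 1), class = "norm_stats")
  flat <- flatten_for_dnn(normalize_episode(ep, ident), feats)
  expect_equal(unname(flat["hr"]), 3)            # mean of 2 and 4
  expect_equal(unname(flat["bp"]), 120)          # never observed: normal value
  expect_equal(unname(flat["mask_hr"]), 2 / 48)  # observed fraction
  expect_length(flat, feature_layout(feats)$input_dim)

  # all variables observed exactly once: flatten equals that time slice
  r1 <- record_from_events(c(1.2, 1.4, 1.8), c("hr", "bp", "gcs"),
                           c("95", "130", "low"))
  ep1 <- impute_episode(resample_episode(r1, feats), feats)
  flat1 <- flatten_for_dnn(normalize_episode(ep1, ident), feats)
  expect_equal(unname(flat1[1:4]), unname(ep1$values[2, ]))
})

test_that("the full pipeline is deterministic and 76-wide by default", {
  cc <- cohort_config(12, seed = 13)
  co <- generate_cohort(cc)
  sp <- split_cohort(co, 0.25, seed = 13)
  p1 <- preprocess_cohort(sp$train, sp$test)
  p2 <- preprocess_cohort(sp$train, sp$test)
  expect_identical(p1, p2)
  expect_equal(dim(p1$train$x)[1:2], c(48, 76))
  expect_equal(ncol(p1$train$flat), 76)
  expect_false(anyNA(p1$train$x))
})

test_that("normalization statistics round-trip through YAML", {
  cc <- cohort_config(4, features = feats, signal_weights = numeric(3),
                      seed = 3)
  eps <- lapply(generate_cohort(cc), function(r)
    impute_episode(resample_episode(r, feats), feats))
  st <- fit_norm_stats(eps)
  f <- tempfile(fileext = ".yaml")
  write_norm_stats(st, f)
  back <- read_norm_stats(f)
  expect_equal(back$mean, st$mean)
  expect_equal(unname(back$sd), unname(st$sd))
  unlink(f)
})
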