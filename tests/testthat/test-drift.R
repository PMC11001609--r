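test_that("xi-alpha and exact LOO agree on wide-margin separable data", {
  d <- blob_data(seed = 41)
  m <- train_svm(d$x, d$y, cost = 1)
  expect_equal(loo_estimate(m, d$x, d$y, "xi_alpha"), 0)
  expect_equal(loo_estimate(m, d$x, d$y, "exact"), 0)
  expect_error(loo_estimate(list(), d$x, d$y), "untrained")
  expect_error(loo_estimate(m, d$x[1, , drop = FALSE], d$y[1], "exact"),
               "n < 2")
})

test_that("weight-vector angles reproduce analytic values and invariances", {
  expect_equal(sbr_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(sbr_angle(c(1, 1), c(1, 0)), 45, tolerance = 1e-9)
  w <- c(0.3, -2, 5)
  expect_equal(sbr_angle(w, w), 0)
  expect_equal(sbr_angle(w, -w), 180)
  expect_error(sbr_angle(w, c(0, 0, 0)), "zero vector")
  expect_error(sbr_angle(w, c(1, 2)), "dimension")
  set.seed(43)
  for (i in 1:50) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(sbr_angle(a, b), sbr_angle(b, a), tolerance = 1e-9)
    expect_equal(sbr_angle(runif(1, 0.1, 10) * a, b), sbr_angle(a, b),
                 tolerance = 1e-9)
    expect_true(sbr_angle(a, b) >= 0 && sbr_angle(a, b) <= 180)
  }
})

test_that("BLW patience stops the window search without evaluating beyond it", {
  # 20 hours of perfectly separable data: every window's estimate is 0,
  # so the best never improves after window 1
  set.seed(45)
  n_per_h <- 30
  hours <- 20
  times <- sort(runif(n_per_h * hours, 0, hours * 3600))
  labels <- rbinom(length(times), 1, 0.3)
  x <- matrix(rnorm(length(times) * 2, sd = 0.1), ncol = 2)
  x[, 1] <- x[, 1] + ifelse(labels == 1, 10, -10)
  r <- blw_select(x, labels, times, anchor = hours * 3600, early_stop = 12)
  expect_equal(r$window_hours, 1)
  expect_equal(nrow(r$candidates), 12)   # window 13 never evaluated
  expect_equal(r$candidates$loo, rep(0, 12))
  # the selected estimate is never beaten by any evaluated candidate
  expect_true(all(r$candidates$loo >=
                    r$candidates$loo[r$candidates$window_hours ==
                                       r$window_hours]))
})

test_that("BLW prefers recent windows after a label-inverting change", {
  set.seed(47)
  hours <- 8
  times <- sort(runif(240 * hours, 0, hours * 3600))
  labels <- rbinom(length(times), 1, 0.3)
  x <- matrix(rnorm(length(times)), ncol = 1)
  flip <- times < (hours - 3) * 3600    # old concept: inverted
  x[labels == 1 & !flip, 1] <- x[labels == 1 & !flip, 1] + 4
  x[labels == 1 & flip, 1] <- x[labels == 1 & flip, 1] - 4
  r <- blw_select(x, labels, times, anchor = hours * 3600)
  expect_lte(r$window_hours, 3)
})

test_that("SbR excludes a drift-contaminated seizure and keeps consistent ones", {
  fs <- small_stream(seed = 49, drift = "abrupt", drift_at = 2)
  b <- label_samples(fs$features, fs$annotations, labeling_config(sop = 20))
  rows <- unlist(lapply(b[1:3], `[[`, "rows"))
  labs <- unlist(lapply(b[1:3], `[[`, "labels"))
  bid <- unlist(lapply(b[1:3], function(x) rep(x$seizure_id, length(x$rows))))
  std <- fit_standardiser(fs$features$values[rows, ])
  x <- apply_standardiser(std, fs$features$values[rows, ])
  sel <- select_features(x, labs, 10)
  r <- sbr_select(x[, sel], labs, bid, cost = 0.25)
  expect_false(1 %in% r$subset)
  expect_true(3 %in% r$subset)
  expect_equal(nrow(r$table), 6)        # 2^3 - 1 minus the reference singleton
  expect_error(sbr_select(x[, sel], labs, rep(1, length(labs))),
               "two training seizures")
})

test_that("DWE base models partition interictal hours and vote by weight", {
  set.seed(51)
  hours <- 5
  times <- seq(0, hours * 3600 - 60, by = 60)
  labels <- as.integer(times >= (hours - 1) * 3600)  # last hour preictal
  x <- matrix(rnorm(length(times)), ncol = 1)
  x[labels == 1, 1] <- x[labels == 1, 1] + 5
  base <- dwe_build(x, labels, times)
  expect_lte(length(base), hours - 1)
  expect_gte(length(base), 2)
  # identical segment data -> identical predictions
  probe <- matrix(c(-3, 0, 6), ncol = 1)
  p1 <- predict(base[[1]]$model, probe)
  p2 <- predict(base[[2]]$model, probe)
  expect_equal(p1, p2, tolerance = 0)

  w <- dwe_weigh(base, x, labels)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
  # hand-set accuracies 0.9 / 0.6 normalise to 0.6 / 0.4
  expect_equal(c(0.9, 0.6) / sum(c(0.9, 0.6)), c(0.6, 0.4))

  two <- base[1:2]
  expect_equal(dwe_predict(two, c(1, 0), probe),
               as.integer(predict(two[[1]]$model, probe)))
  expect_error(dwe_predict(two, c(0.7, 0.7), probe), "sum to 1")
  expect_error(dwe_predict(two, 1, probe), "mismatch")
})

test_that("weighted voting matches a brute-force vote on every pattern", {
  # stub models that return fixed predictions regardless of input
  mk <- function(bit) list(model = structure(list(bit = bit),
                                             class = "stub_model"))
  assign("predict.stub_model",
         function(object, newdata, ...) rep(object$bit, NROW(newdata)),
         envir = globalenv())
  on.exit(rm("predict.stub_model", envir = globalenv()))
  x <- matrix(0, 1, 1)
  for (nm in 2:4) {
    pats <- expand.grid(rep(list(c(0L, 1L)), nm))
    for (r in seq_len(nrow(pats))) {
      bits <- as.integer(pats[r, ])
      set.seed(53 + r)
      w <- runif(nm); w <- w / sum(w)
      models <- lapply(bits, mk)
      got <- dwe_predict(models, w, x)
      expect_identical(got, as.integer(sum(w * bits) >= 0.5 - 1e-12))
    }
  }
  # majority vote under uniform weights
  models <- lapply(c(1L, 1L, 0L), mk)
  expect_identical(dwe_predict(models, rep(1 / 3, 3), x), 1L)
})
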