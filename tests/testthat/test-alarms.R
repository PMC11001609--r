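brute_fp <- function(outputs, tau) {
  vapply(seq_along(outputs), function(i) {
    mean(c(rep(0, max(0, tau - i)), outputs[max(1, i - tau + 1):i]))
  }, 0)
}

test_that("Firing Power equals the zero-padded moving average", {
  expect_equal(firing_power(c(1, 1, 1, 1), 4)$values[4], 1)
  expect_equal(firing_power(c(0, 0, 1, 1, 1, 1), 4)$values,
               c(0, 0, 0.25, 0.5, 0.75, 1))
  expect_equal(firing_power(rep(0, 20), 7)$values, rep(0, 20))
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    tau <- sample(1:120, 1)
    o <- rbinom(n, 1, runif(1))
    expect_warning(fp <- firing_power(o, tau), if (tau > n) "padded" else NA)
    expect_equal(fp$values, brute_fp(o, tau))
  }
})

test_that("alarms fire on upward crossings and respect refractory periods", {
  tr <- firing_power(c(0, 0, 1, 1, 1, 1), 4)
  al <- raise_alarms(tr, 0.5, refractory = 600)
  expect_equal(al$alarm_times, 15)         # epoch index 3 at 5-s epochs

  # permanently-high trace: one alarm per refractory period
  high <- structure(list(values = rep(1, 100),
                         epoch_times = (0:99) * 5, tau = 1),
                    class = "firing_power_trace")
  al2 <- raise_alarms(high, 0.5, refractory = 60)
  expect_equal(al2$alarm_times, seq(0, 495, by = 60))
  expect_true(all(diff(al2$alarm_times) >= 60))

  low <- structure(list(values = rep(0.4, 50), epoch_times = (0:49) * 5,
                        tau = 1), class = "firing_power_trace")
  expect_length(raise_alarms(low, 0.5, refractory = 60)$alarm_times, 0)
})

test_that("alarm logic matches an exhaustive step-by-step simulator", {
  simulate <- function(v, t, thr, refr) {
    alarms <- numeric(0); block <- -Inf; armed <- TRUE
    for (i in seq_along(v)) {
      inref <- t[i] < block
      if (v[i] >= thr && armed && !inref) {
        alarms <- c(alarms, t[i]); block <- t[i] + refr; inref <- TRUE
      }
      armed <- (v[i] < thr) || inref
    }
    alarms
  }
  set.seed(63)
  for (i in 1:50) {
    n <- sample(20:150, 1)
    v <- round(runif(n), 2)
    t <- (seq_len(n) - 1) * 5
    refr <- sample(c(30, 60, 300), 1)
    tr <- structure(list(values = v, epoch_times = t, tau = 1),
                    class = "firing_power_trace")
    al <- raise_alarms(tr, 0.5, refr)
    expect_equal(al$alarm_times, simulate(v, t, 0.5, refr))
    if (length(al$alarm_times) > 1) {
      expect_true(all(diff(al$alarm_times) >= refr))
    }
    expect_lte(length(al$alarm_times), max(t) / refr + 1)
  }
})

test_that("alarm scoring follows the SPH/SOP window convention", {
  mk <- function(times, refr) structure(list(alarm_times = times,
                                             refractory = refr,
                                             threshold = 0.5),
                                        class = "alarm_series")
  # alarm 6000 s, sph 10, sop 30: window (6600, 8400] contains onset 7200
  sc <- score_alarms(mk(6000, 1800), onsets = 7200, sop = 30, sph = 10,
                     interictal_hours = 10)
  expect_equal(sc$ss, 1)
  expect_equal(sc$n_false, 0)
  # onset inside the SPH: miss, alarm counted false
  sc2 <- score_alarms(mk(6000, 1800), onsets = 6300, sop = 30, sph = 10,
                      interictal_hours = 10)
  expect_equal(sc2$ss, 0)
  expect_equal(sc2$n_false, 1)
  # 2 false alarms over 10 h with 30-min refractories: 2 / 9 per hour
  sc3 <- score_alarms(mk(c(1000, 4000), 1800), onsets = numeric(0),
                      sop = 30, sph = 10, interictal_hours = 10)
  expect_equal(sc3$fpr_h, 2 / 9)
  expect_true(is.na(sc3$ss))
  # each onset predicted at most once
  sc4 <- score_alarms(mk(c(1000, 1100), 1800), onsets = 2000, sop = 30,
                      sph = 10, interictal_hours = 10)
  expect_equal(sc4$n_true, 1)
  expect_equal(sc4$n_false, 1)
})

test_that("false alarm counts are non-increasing in the threshold", {
  set.seed(65)
  o <- rbinom(2000, 1, 0.3)
  tr <- firing_power(o, 60)
  nf <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    length(raise_alarms(tr, th, refractory = 1800)$alarm_times)
  }, 0)
  expect_true(all(diff(nf) <= 0))
})

test_that("surrogate validation is negative without alarms and tracks coverage", {
  empty <- structure(list(alarm_times = numeric(0), refractory = 1800,
                          threshold = 0.5), class = "alarm_series")
  sv <- surrogate_validate(empty, list(c(0, 36000)), sop = 30, sph = 10,
                           real_ss = 0, seed = 67)
  expect_equal(sv$surrogate_ss, rep(0, 30))
  expect_false(sv$validated)

  # alarm SOP windows tile a known fraction of the drawable onset region
  al <- structure(list(alarm_times = c(3000, 10000, 20000),
                       refractory = 1800, threshold = 0.5),
                  class = "alarm_series")
  sv2 <- surrogate_validate(al, list(c(0, 36000)), sop = 30, sph = 10,
                            real_ss = 1, n_runs = 500, seed = 69)
  covered <- 3 * 1800
  drawable <- 36000 - (30 + 10) * 60
  expect_lt(abs(sv2$surrogate_mean - covered / drawable), 0.05)
  expect_error(surrogate_validate(al, list(c(5, 5)), 30, 10, 1),
               "degenerate")
})
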