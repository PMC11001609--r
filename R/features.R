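#' EEG frequency bands
#'
#' The eight-band registry used throughout: delta 0.5-4, theta 4-8,
#' alpha 8-13, beta 13-30 Hz and four gamma sub-bands (30-47, 53-75,
#' 75-97, 103-128 Hz). The gaps at 47-53 and 97-103 Hz skirt the 50/100 Hz
#' mains notches.
#'
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta",
             "gamma1", "gamma2", "gamma3", "gamma4"),
    low  = c(0.5, 4, 8, 13, 30, 53, 75, 103),
    high = c(4, 8, 13, 30, 47, 75, 97, 128),
    stringsAsFactors = FALSE
  )
}

#' One-sided power spectral density of a single epoch
#'
#' Hann-tapered periodogram over the whole epoch (a single Welch segment),
#' normalised so that `sum(power) * df` approximates the signal variance
#' (Parseval). A 5-s epoch gives a 0.2 Hz grid.
#'
#' @param epoch numeric vector, one channel of one epoch.
#' @param rate sampling rate in Hz.
#' @return list with `freq` (Hz) and `power` (uV^2/Hz) plus `df`.
#' @export
power_spectrum <- function(epoch, rate) {
  n <- length(epoch)
  x <- epoch - mean(epoch)
  if (all(x == 0)) {
    freq <- seq(0, rate / 2, by = rate / n)
    return(list(freq = freq, power = rep(0, length(freq)), df = rate / n))
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)   # periodic Hann
  X <- stats::fft(x * w)
  nh <- floor(n / 2) + 1
  p <- (Mod(X[1:nh])^2) / (rate * sum(w^2))
  # fold negative frequencies into the one-sided spectrum
  if (n %% 2 == 0) p[2:(nh - 1)] <- 2 * p[2:(nh - 1)]
  else p[2:nh] <- 2 * p[2:nh]
  list(freq = (0:(nh - 1)) * rate / n, power = p, df = rate / n)
}

band_power <- function(spec, low, high) {
  sel <- spec$freq >= low & spec$freq < high
  sum(spec$power[sel]) * spec$df
}

#' Relative spectral power in a band
#'
#' Integral of the PSD over `band` divided by the integral over
#' `total_band` (default 0.5-128 Hz).
#'
#' @param spec output of [power_spectrum()].
#' @param band numeric length 2 (Hz).
#' @param total_band numeric length 2 (Hz).
#' @return fraction in `[0, 1]`, `NA` if total power is zero.
#' @export
relative_band_power <- function(spec, band, total_band = c(0.5, 128)) {
  tot <- band_power(spec, total_band[1], total_band[2])
  if (tot <= 0) return(NA_real_)
  band_power(spec, band[1], band[2]) / tot
}

#' Ratio between two band-power fractions
#'
#' `p_a / (p_b + eps)`; `eps` guards the division and is fixed at 1e-12.
#'
#' @param p_a,p_b non-negative band-power fractions.
#' @param eps regularisation constant.
#' @return non-negative real.
#' @export
band_ratio <- function(p_a, p_b, eps = 1e-12) {
  p_a / (p_b + eps)
}

#' Spectral edge frequency and power
#'
#' The smallest grid frequency below which `percentile` of the power in
#' `range` (default 0.5-100 Hz) has accumulated, plus that cumulative power.
#'
#' @param spec output of [power_spectrum()].
#' @param percentile fraction in (0, 1], default 0.5.
#' @param range numeric length 2 (Hz).
#' @return list `edge_frequency` (Hz), `edge_power`; both `NA` when the
#'   range carries no power.
#' @export
spectral_edge <- function(spec, percentile = 0.5, range = c(0.5, 100)) {
  sel <- which(spec$freq >= range[1] & spec$freq <= range[2])
  pw <- spec$power[sel] * spec$df
  tot <- sum(pw)
  if (tot <= 0) return(list(edge_frequency = NA_real_, edge_power = NA_real_))
  cs <- cumsum(pw)
  # relative guard so that an exactly-half split (e.g. two equal spectral
  # lines) resolves to the lower line despite window-leakage rounding
  i <- which(cs >= percentile * tot * (1 - 1e-6))[1]
  list(edge_frequency = spec$freq[sel[i]], edge_power = cs[i])
}

#' Alpha peak, total power and mean frequency
#'
#' @param spec output of [power_spectrum()].
#' @return list `alpha_peak` (argmax of power in 8-13 Hz, NA when the band
#'   is flat zero), `total_power` (integral over 0.5-128 Hz),
#'   `mean_frequency` (power-weighted mean over 0.5-128 Hz).
#' @export
summary_spectral_features <- function(spec) {
  asel <- which(spec$freq >= 8 & spec$freq <= 13)
  alpha_peak <- if (length(asel) == 0 || all(spec$power[asel] == 0)) {
    NA_real_
  } else {
    spec$freq[asel[which.max(spec$power[asel])]]
  }
  tsel <- which(spec$freq >= 0.5 & spec$freq <= 128)
  tp <- sum(spec$power[tsel]) * spec$df
  mf <- if (tp > 0) {
    sum(spec$freq[tsel] * spec$power[tsel]) / sum(spec$power[tsel])
  } else NA_real_
  list(alpha_peak = alpha_peak, total_power = tp, mean_frequency = mf)
}

# ---- Daubechies-4 discrete wavelet transform (periodized) ------------------

# 8-tap db4 scaling filter (sum = sqrt(2)); the quadrature-mirror high-pass
# is derived from it. Periodic boundary handling keeps the transform
# orthonormal, so detail/approximation energies sum to the signal energy.
db4_h <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
           -0.02798376941685985, -0.1870348117190931, 0.03084138183556076,
           0.03288301166688519, -0.01059740178506903)

dwt_step_per <- function(x, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n <- length(x)
  L <- length(h)
  idx <- outer(2 * seq_len(n %/% 2) - 1, seq_len(L) - 1, "+")
  idx <- ((idx - 1) %% n) + 1
  xm <- matrix(x[idx], nrow = n %/% 2)
  list(approx = as.numeric(xm %*% h), detail = as.numeric(xm %*% g))
}

#' Energies of db4 wavelet detail coefficients D1..D5
#'
#' Periodized pyramid DWT with the 8-tap Daubechies-4 filters; energy at
#' level k is the sum of squared detail coefficients. Orthonormality means
#' the five detail energies plus the final approximation energy equal the
#' signal energy.
#'
#' @param epoch numeric vector (length >= 32).
#' @param levels decomposition depth (default 5).
#' @return numeric vector `D1..D5` of energies; attribute `"approx_energy"`
#'   holds the residual approximation energy.
#' @export
wavelet_energies <- function(epoch, levels = 5) {
  if (length(epoch) < 2^levels) {
    stop("epoch too short for a ", levels, "-level decomposition")
  }
  x <- epoch
  en <- numeric(levels)
  for (k in seq_len(levels)) {
    st <- dwt_step_per(x, db4_h)
    en[k] <- sum(st$detail^2)
    x <- st$approx
  }
  names(en) <- paste0("D", seq_len(levels))
  attr(en, "approx_energy") <- sum(x^2)
  en
}

#' Four statistical moments of an epoch
#'
#' Sample mean and variance plus skewness and kurtosis in the standardized
#' central-moment convention (moment estimators, kurtosis non-excess: a
#' Gaussian scores 3).
#'
#' @param epoch numeric vector (length >= 2).
#' @return list `mean`, `variance`, `skewness`, `kurtosis`; the last two are
#'   `NA` for zero-variance input.
#' @export
statistical_moments <- function(epoch) {
  m <- mean(epoch)
  v <- stats::var(epoch)
  if (v == 0) {
    return(list(mean = m, variance = 0, skewness = NA_real_,
                kurtosis = NA_real_))
  }
  list(mean = m, variance = v,
       skewness = e1071::skewness(epoch, type = 1),
       kurtosis = e1071::kurtosis(epoch, type = 1) + 3)
}

#' Hjorth parameters
#'
#' Activity (variance), mobility (`sqrt(var(dx)/var(x))`) and complexity
#' (`mobility(dx)/mobility(x)`), with the derivative approximated by first
#' differences.
#'
#' @param epoch numeric vector (length >= 3).
#' @return list `activity`, `mobility`, `complexity` (`NA` where a variance
#'   in the chain is zero).
#' @export
hjorth_parameters <- function(epoch) {
  v0 <- stats::var(epoch)
  if (v0 == 0) {
    return(list(activity = 0, mobility = NA_real_, complexity = NA_real_))
  }
  d1 <- diff(epoch)
  v1 <- stats::var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0) {
    return(list(activity = v0, mobility = mob, complexity = NA_real_))
  }
  d2 <- diff(d1)
  v2 <- stats::var(d2)
  list(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Decorrelation time
#'
#' The lag, in seconds, at which the sample autocorrelation of the
#' (mean-removed) epoch first falls to or below `1/e`. If the criterion is
#' never met within lags `< n/2` the cap is returned with attribute
#' `"capped" = TRUE`.
#'
#' @param epoch numeric vector (length >= 32).
#' @param rate sampling rate in Hz.
#' @return seconds, `NA` for zero-variance input.
#' @export
decorrelation_time <- function(epoch, rate) {
  n <- length(epoch)
  if (n < 32) stop("epoch too short for decorrelation time")
  x <- epoch - mean(epoch)
  if (all(x == 0)) return(NA_real_)
  max_lag <- floor(n / 2) - 1
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  hit <- which(ac[-1] <= exp(-1))[1]           # ac[1] is lag 0
  if (is.na(hit)) {
    out <- max_lag / rate
    attr(out, "capped") <- TRUE
    return(out)
  }
  hit / rate
}

# ---- the 59-feature registry -----------------------------------------------

#' The default 59-feature univariate registry
#'
#' Ordered feature battery computed per 5-s epoch per channel:
#' 8 relative band powers, the 28 pairwise band ratios, 7 spectral-edge
#' entries (edge frequency and power at the 50/75/90th percentiles plus the
#' 95th-percentile edge frequency), alpha peak frequency, total power, mean
#' frequency, 5 wavelet detail energies (db4, D1-D5), the four statistical
#' moments, the three Hjorth parameters, and the decorrelation time —
#' 59 entries in total. The registry is an ordinary data.frame and can be
#' subset or replaced for experimentation.
#'
#' @return data.frame with columns `name`, `kind`, `param1`, `param2`.
#' @export
feature_registry <- function() {
  b <- eeg_bands()
  rows <- list()
  add <- function(name, kind, p1 = NA, p2 = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, kind = kind, param1 = p1, param2 = p2,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(b))) {
    add(paste0("relpow_", b$name[i]), "relpow", b$low[i], b$high[i])
  }
  for (i in 1:(nrow(b) - 1)) for (j in (i + 1):nrow(b)) {
    add(paste0("ratio_", b$name[i], "_", b$name[j]), "ratio", i, j)
  }
  for (p in c(0.5, 0.75, 0.9)) {
    add(sprintf("sef%d", round(p * 100)), "edge_freq", p)
    add(sprintf("sep%d", round(p * 100)), "edge_power", p)
  }
  add("sef95", "edge_freq", 0.95)
  add("alpha_peak", "alpha_peak")
  add("total_power", "total_power")
  add("mean_frequency", "mean_frequency")
  for (k in 1:5) add(paste0("wavelet_D", k), "wavelet", k)
  add("moment_mean", "moment", 1); add("moment_variance", "moment", 2)
  add("moment_skewness", "moment", 3); add("moment_kurtosis", "moment", 4)
  add("hjorth_activity", "hjorth", 1); add("hjorth_mobility", "hjorth", 2)
  add("hjorth_complexity", "hjorth", 3)
  add("decorrelation_time", "decorr")
  reg <- do.call(rbind, rows)
  stopifnot(nrow(reg) == 59, !anyDuplicated(reg$name))
  reg
}

compute_feature_vector <- function(epoch, rate, registry) {
  spec <- power_spectrum(epoch, rate)
  b <- eeg_bands()
  relp <- vapply(seq_len(nrow(b)), function(i) {
    v <- relative_band_power(spec, c(b$low[i], b$high[i]))
    if (is.na(v)) 0 else v
  }, 0)
  edges <- new.env()
  edge_at <- function(p) {
    key <- as.character(p)
    if (is.null(edges[[key]])) edges[[key]] <- spectral_edge(spec, p)
    edges[[key]]
  }
  ssf <- summary_spectral_features(spec)
  wav <- wavelet_energies(epoch)
  mom <- statistical_moments(epoch)
  hj <- hjorth_parameters(epoch)
  out <- numeric(nrow(registry))
  for (r in seq_len(nrow(registry))) {
    k <- registry$kind[r]; p1 <- registry$param1[r]; p2 <- registry$param2[r]
    out[r] <- switch(k,
      relpow = relative_band_power(spec, c(p1, p2)),
      ratio = band_ratio(relp[p1], relp[p2]),
      edge_freq = edge_at(p1)$edge_frequency,
      edge_power = edge_at(p1)$edge_power,
      alpha_peak = ssf$alpha_peak,
      total_power = ssf$total_power,
      mean_frequency = ssf$mean_frequency,
      wavelet = wav[p1],
      moment = unlist(mom, use.names = FALSE)[p1],
      hjorth = unlist(hj, use.names = FALSE)[p1],
      decorr = as.numeric(decorrelation_time(epoch, rate)),
      stop("unknown feature kind: ", k)
    )
  }
  out
}

#' Extract the feature matrix from an epoch array
#'
#' One row per epoch, `n_channels x n_features` columns in registry order
#' (channel-major: all features of channel 1, then channel 2, ...). Epochs
#' producing any non-finite feature value are flagged invalid in
#' `valid_mask` (values kept as computed, NA where undefined).
#'
#' @param epochs an `epoch_array` from [segment_epochs()].
#' @param registry feature registry (default [feature_registry()]); must
#'   have 59 rows unless `allow_any_size = TRUE`.
#' @param allow_any_size permit non-standard registries.
#' @return object of class `feature_matrix`: list with `values` (matrix),
#'   `feature_names`, `channel_labels`, `epoch_start_times`, `valid_mask`,
#'   `window_length`.
#' @export
extract_features <- function(epochs, registry = feature_registry(),
                             allow_any_size = FALSE) {
  if (nrow(registry) != 59 && !allow_any_size) {
    stop("registry must hold exactly 59 features ",
         "(set allow_any_size = TRUE to override)")
  }
  n_ep <- dim(epochs$epochs)[1]
  n_ch <- dim(epochs$epochs)[2]
  nf <- nrow(registry)
  vals <- matrix(NA_real_, nrow = n_ep, ncol = n_ch * nf)
  for (i in seq_len(n_ep)) {
    for (ch in seq_len(n_ch)) {
      vals[i, ((ch - 1) * nf + 1):(ch * nf)] <-
        compute_feature_vector(epochs$epochs[i, ch, ], epochs$sampling_rate,
                               registry)
    }
  }
  fn <- as.vector(vapply(epochs$channel_labels, function(cl) {
    paste0(cl, ".", registry$name)
  }, character(nf)))
  feature_matrix(vals, fn, epochs$channel_labels,
                 epochs$epoch_start_times,
                 valid_mask = epochs$valid_mask & apply(is.finite(vals), 1, all),
                 window_length = epochs$window_length)
}

#' Construct a feature matrix container
#'
#' @param values epoch x feature numeric matrix.
#' @param feature_names,channel_labels character vectors.
#' @param epoch_start_times seconds, one per row.
#' @param valid_mask logical per row.
#' @param window_length epoch length in seconds.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_names, channel_labels,
                           epoch_start_times, valid_mask = NULL,
                           window_length = 5) {
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, nrow(values))
  stopifnot(length(feature_names) == ncol(values),
            length(epoch_start_times) == nrow(values))
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 channel_labels = channel_labels,
                 epoch_start_times = epoch_start_times,
                 valid_mask = valid_mask,
                 window_length = window_length),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d channels), %d valid\n",
              nrow(x$values), ncol(x$values), length(x$channel_labels),
              sum(x$valid_mask)))
  invisible(x)
}
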