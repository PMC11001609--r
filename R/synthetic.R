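#' Specification for a synthetic drifting-EEG patient
#'
#' Defines the study-style conditions the generator emulates: long
#' interictal recordings punctuated by at least four lead seizures spaced by
#' the independence gap (4.5 h by default), each preceded by a preictal
#' period with an altered spectral signature, optionally drifting abruptly
#' or gradually across seizures.
#'
#' @param n_channels number of EEG channels (default 19, 10-20 system).
#' @param rate sampling rate in Hz (default 256).
#' @param n_seizures number of lead seizures (>= 4, default 4).
#' @param gap_hours interictal gap between consecutive seizures (default
#'   4.5; smaller values give a compressed timeline for desk-scale runs).
#' @param true_sop minutes of genuinely altered preictal activity
#'   (default 30).
#' @param sph minutes between the end of the altered window and onset
#'   (default 10).
#' @param effect_bands character, names from [eeg_bands()] whose relative
#'   power the preictal state boosts (default "alpha").
#' @param effect_size dimensionless amplitude of the preictal oscillatory
#'   component relative to the background RMS (raw tier) or the class mean
#'   shift in pooled-SD units (feature tier); default 2.
#' @param drift "none", "abrupt" (concept inversion from seizure
#'   `drift_at`'s batch onward), or "gradual" (smooth interpolation of the
#'   same change across the timeline). A concept inversion flips the sign
#'   of the preictal signature and, mirroring a change of hidden context
#'   (medication, vigilance), also offsets the pre-drift background on the
#'   signature features by `baseline_shift`.
#' @param baseline_shift pooled-SD offset of the pre-drift background on
#'   the signature features (feature tier); defaults to `effect_size`, so
#'   an abrupt drift swaps the two class distributions in place — a genuine
#'   label-inverting concept change.
#' @param drift_at seizure index at which abrupt drift begins (its batch
#'   start), default 3.
#' @param drift_time optional absolute time (s) for the abrupt change,
#'   overriding `drift_at`.
#' @param ar AR(1) coefficient of the background noise (default 0.5).
#' @param ictal_minutes seizure duration (default 3).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 19, rate = 256, n_seizures = 4,
                           gap_hours = 4.5, true_sop = 30, sph = 10,
                           effect_bands = "alpha", effect_size = 2,
                           drift = c("none", "abrupt", "gradual"),
                           drift_at = 3, drift_time = NULL,
                           baseline_shift = effect_size,
                           ar = 0.5, ictal_minutes = 3, seed = 1) {
  drift <- match.arg(drift)
  if (n_seizures < 4) stop("at least four lead seizures are required")
  if (gap_hours <= (true_sop + sph) / 60) {
    stop("gap_hours must exceed the preictal + horizon span")
  }
  structure(list(n_channels = n_channels, rate = rate,
                 n_seizures = n_seizures, gap_hours = gap_hours,
                 true_sop = true_sop, sph = sph,
                 effect_bands = effect_bands, effect_size = effect_size,
                 drift = drift, drift_at = drift_at, drift_time = drift_time,
                 baseline_shift = baseline_shift,
                 ar = ar, ictal_minutes = ictal_minutes, seed = seed),
            class = "synthetic_spec")
}

spec_timeline <- function(spec) {
  gap_s <- spec$gap_hours * 3600
  ict_s <- spec$ictal_minutes * 60
  onsets <- gap_s + (seq_len(spec$n_seizures) - 1) * (gap_s + ict_s)
  offsets <- onsets + ict_s
  duration <- offsets[length(offsets)] + 600
  list(onsets = onsets, offsets = offsets, duration = duration)
}

# sign of the preictal signature at absolute time t (drift schedule)
drift_sign <- function(spec, t, onsets) {
  switch(spec$drift,
    none = 1,
    abrupt = {
      change <- if (!is.null(spec$drift_time)) spec$drift_time else {
        # batch start of seizure `drift_at`: end of previous postictal
        if (spec$drift_at <= 1) 0 else onsets[spec$drift_at - 1] +
          spec$ictal_minutes * 60 + 1
      }
      ifelse(t >= change, 1, -1)
    },
    gradual = {
      total <- onsets[length(onsets)]
      cos(pi * (1 - t / total))     # -1 at start, +1 at the last seizure
    }
  )
}

#' Generate a synthetic multichannel EEG recording
#'
#' Background activity is AR(1)-coloured noise per channel (an approximately
#' 1/f-shaped spectrum). During each preictal window
#' `[onset - (sph+true_sop)*60, onset - sph*60)` a band-limited oscillation
#' in the configured effect bands is added with amplitude
#' `effect_size x` a fraction of the background RMS, modulated by the drift
#' schedule's sign. Ictal segments carry a high-amplitude 4 Hz rhythm.
#' Fully reproducible from the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `recording` ([recording()]) and `annotations`
#'   ([seizure_annotations()]).
#' @export
generate_recording <- function(spec) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  tl <- spec_timeline(spec)
  n <- round(tl$duration * spec$rate)
  tgrid <- (seq_len(n) - 1) / spec$rate
  b <- eeg_bands()
  eb <- b[b$name %in% spec$effect_bands, , drop = FALSE]
  if (nrow(eb) == 0) stop("unknown effect band(s)")
  sig <- matrix(0, nrow = spec$n_channels, ncol = n)
  pre_lo <- tl$onsets - (spec$sph + spec$true_sop) * 60
  pre_hi <- tl$onsets - spec$sph * 60
  for (ch in seq_len(spec$n_channels)) {
    x <- as.numeric(stats::arima.sim(list(ar = spec$ar), n = n,
                                     sd = 10 * sqrt(1 - spec$ar^2)))
    for (k in seq_along(tl$onsets)) {
      idx <- which(tgrid >= pre_lo[k] & tgrid < pre_hi[k])
      if (length(idx) == 0) next
      s <- drift_sign(spec, tgrid[idx[1]], tl$onsets)
      for (r in seq_len(nrow(eb))) {
        f <- stats::runif(1, eb$low[r], min(eb$high[r], spec$rate / 2 * 0.9))
        amp <- spec$effect_size * 3 * abs(s)
        osc <- amp * sin(2 * pi * f * tgrid[idx] + stats::runif(1, 0, 2 * pi))
        # a negative drift sign swaps the signature band to delta
        if (s < 0) {
          f2 <- stats::runif(1, 1, 3)
          osc <- amp * sin(2 * pi * f2 * tgrid[idx] + stats::runif(1, 0, 2 * pi))
        }
        x[idx] <- x[idx] + osc
      }
      ict <- which(tgrid >= tl$onsets[k] & tgrid < tl$offsets[k])
      x[ict] <- x[ict] + 40 * sin(2 * pi * 4 * tgrid[ict])
    }
    sig[ch, ] <- x
  }
  ann <- seizure_annotations(tl$onsets, tl$offsets,
                             independence_gap = spec$gap_hours)
  list(recording = recording(sig, spec$rate,
                             paste0("EEG", seq_len(spec$n_channels))),
       annotations = ann)
}

#' Generate a synthetic per-epoch feature stream
#'
#' The fast generation tier: draws 59-dimensional per-channel feature rows
#' directly from interictal and preictal multivariate Gaussians. Preictal
#' rows shift a fixed subset of feature dimensions (those indexed by the
#' effect bands' relative-power entries plus their ratios) by
#' `effect_size` pooled standard deviations, with the drift schedule
#' scaling/sign-flipping the shift over time. Epoch step defaults to 5 s.
#'
#' @param spec a [synthetic_spec()].
#' @param epoch_length seconds per feature row (default 5).
#' @return list with `features` (a `feature_matrix`) and `annotations`.
#' @export
generate_feature_stream <- function(spec, epoch_length = 5) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  tl <- spec_timeline(spec)
  times <- seq(0, tl$duration - epoch_length, by = epoch_length)
  reg <- feature_registry()
  nf <- nrow(reg)
  n_ch <- spec$n_channels
  p <- nf * n_ch
  # signature: the effect bands' relative-power features and their ratios
  eff_per_ch <- which(reg$kind == "relpow" &
                        sub("relpow_", "", reg$name) %in% spec$effect_bands)
  rn <- paste0("ratio_.*(", paste(spec$effect_bands, collapse = "|"), ")")
  eff_per_ch <- union(eff_per_ch, grep(rn, reg$name))
  eff_vec <- numeric(p)
  for (ch in seq_len(n_ch)) {
    eff_vec[(ch - 1) * nf + eff_per_ch] <- 1
  }
  n <- length(times)
  vals <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  # mild AR(1) correlation along time within each feature
  if (spec$ar > 0) {
    for (j in seq_len(p)) {
      vals[, j] <- as.numeric(stats::filter(vals[, j], spec$ar,
                                            method = "recursive")) *
        sqrt(1 - spec$ar^2)
    }
  }
  # per-row concept state: s = +1 current concept, -1 pre-drift
  s_row <- drift_sign(spec, times, tl$onsets)
  if (length(s_row) == 1) s_row <- rep(s_row, n)
  # pre-drift background offset on the signature features (both classes)
  baseline <- spec$baseline_shift * (1 - s_row) / 2
  vals <- vals + outer(baseline, eff_vec)
  pre_lo <- tl$onsets - (spec$sph + spec$true_sop) * 60
  pre_hi <- tl$onsets - spec$sph * 60
  for (k in seq_along(tl$onsets)) {
    idx <- which(times >= pre_lo[k] & times < pre_hi[k])
    if (length(idx) == 0) next
    vals[idx, ] <- vals[idx, , drop = FALSE] +
      outer(s_row[idx] * spec$effect_size, eff_vec)
  }
  fn <- as.vector(vapply(seq_len(n_ch), function(ch) {
    paste0("EEG", ch, ".", reg$name)
  }, character(nf)))
  ann <- seizure_annotations(tl$onsets, tl$offsets,
                             independence_gap = spec$gap_hours)
  list(features = feature_matrix(vals, fn, paste0("EEG", seq_len(n_ch)),
                                 times, window_length = epoch_length),
       annotations = ann)
}
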