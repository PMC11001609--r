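#' Labelling configuration
#'
#' Bundles the timing parameters that turn an annotated feature stream into
#' labelled training data: the seizure occurrence period (SOP, the labelled
#' preictal duration), the seizure prediction horizon (SPH, the warning
#' gap), the postictal exclusion and the lead-seizure independence gap.
#'
#' @param sop minutes, preictal duration (grid 10-50 in 5-min steps by
#'   default).
#' @param sph minutes, prediction horizon (default 10).
#' @param postictal_exclusion minutes discarded after seizure offset
#'   (default 30).
#' @param independence_gap hours between lead seizures (default 4.5).
#' @return list of class `labeling_config`.
#' @export
labeling_config <- function(sop = 30, sph = 10, postictal_exclusion = 30,
                            independence_gap = 4.5) {
  stopifnot(sop > 0, sph > 0, postictal_exclusion >= 0)
  structure(list(sop = sop, sph = sph,
                 postictal_exclusion = postictal_exclusion,
                 independence_gap = independence_gap),
            class = "labeling_config")
}

#' Assign epochs to per-seizure labelled batches
#'
#' One batch per lead seizure. Within a batch, preictal rows are the epochs
#' whose start time lies in `[onset - (sph+sop)*60, onset - sph*60)`;
#' interictal rows run from the end of the previous seizure's postictal
#' exclusion up to the preictal start. Epochs inside the SPH, the seizure
#' itself, or a postictal exclusion are dropped from training data (counted
#' in `n_dropped`). If a preictal window would overlap the previous
#' seizure's postictal exclusion, the preictal is truncated with a warning.
#'
#' @param features a `feature_matrix`.
#' @param annotations a `seizure_annotations` table.
#' @param cfg a [labeling_config()].
#' @return list of `seizure_batch` objects, each a list with `seizure_id`,
#'   `onset`, `rows` (row indices into `features$values`), `labels`
#'   (0 = interictal, 1 = preictal), `times`, `n_dropped`.
#' @export
label_samples <- function(features, annotations, cfg = labeling_config()) {
  t0 <- features$epoch_start_times
  lead_idx <- which(annotations$lead)
  batches <- vector("list", length(lead_idx))
  for (k in seq_along(lead_idx)) {
    i <- lead_idx[k]
    onset <- annotations$onset[i]
    pre_lo <- onset - (cfg$sph + cfg$sop) * 60
    pre_hi <- onset - cfg$sph * 60
    span_lo <- if (i == 1) -Inf else {
      annotations$offset[i - 1] + cfg$postictal_exclusion * 60
    }
    if (span_lo > pre_lo) {
      warning(sprintf(
        "seizure %d: preictal truncated by previous postictal exclusion (%.0f s lost)",
        i, span_lo - pre_lo))
      pre_lo2 <- max(pre_lo, span_lo)
    } else pre_lo2 <- pre_lo
    in_span <- t0 >= span_lo & t0 < onset & features$valid_mask
    is_pre <- t0 >= pre_lo2 & t0 < pre_hi & in_span
    is_inter <- t0 < pre_lo2 & in_span
    # everything else in the span (SPH rows, truncated preictal remnant) drops
    keep <- which(is_pre | is_inter)
    n_drop <- sum(in_span) - length(keep)
    batches[[k]] <- structure(list(
      seizure_id = i, onset = onset,
      rows = keep,
      labels = as.integer(is_pre[keep]),
      times = t0[keep],
      interictal_span = c(max(span_lo, min(t0)), pre_lo2),
      n_dropped = n_drop
    ), class = "seizure_batch")
  }
  batches
}

#' Fit / apply a z-scoring standardiser
#'
#' Per-feature mean and standard deviation (sample sd, `n-1` denominator)
#' learned on training rows only and applied unchanged to validation/test
#' rows. Zero-variance features are mapped to 0 and flagged.
#'
#' @param x numeric training matrix (rows = epochs).
#' @return object of class `standardiser` with `mean`, `sd`, `degenerate`.
#' @export
fit_standardiser <- function(x) {
  if (nrow(x) < 2) stop("need at least 2 training rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  structure(list(mean = mu, sd = sdv, degenerate = sdv == 0),
            class = "standardiser")
}

#' @rdname fit_standardiser
#' @param std a fitted `standardiser`.
#' @export
apply_standardiser <- function(std, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- sweep(x, 2, std$mean, "-")
  sdv <- ifelse(std$degenerate, 1, std$sd)
  z <- sweep(z, 2, sdv, "/")
  z[, std$degenerate] <- 0
  z
}

#' @rdname fit_standardiser
#' @export
invert_standardiser <- function(std, z) {
  x <- sweep(z, 2, ifelse(std$degenerate, 1, std$sd), "*")
  sweep(x, 2, std$mean, "+")
}

#' Systematic random undersampling of the majority class
#'
#' Reduces the majority class to the minority size by taking every
#' `stride`-th sample in time order starting from a seed-drawn offset, so
#' the retained rows cover the majority timeline uniformly. The minority
#' class is untouched. Deterministic given `seed`.
#'
#' @param labels integer 0/1 vector.
#' @param seed integer RNG seed.
#' @return integer indices of the retained rows (both classes), sorted.
#' @export
balance_undersample <- function(labels, seed = 1) {
  cls <- table(factor(labels, levels = c(0, 1)))
  if (any(cls == 0)) {
    stop("both classes required; missing class ",
         names(cls)[cls == 0][1])
  }
  minority <- if (cls["0"] <= cls["1"]) 0L else 1L
  majority <- 1L - minority
  maj_idx <- which(labels == majority)
  n_min <- as.integer(min(cls))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  # systematic: fixed fractional stride over the time-ordered majority,
  # random phase
  stride <- length(maj_idx) / n_min
  phase <- stats::runif(1, 0, stride)
  pick <- unique(pmin(length(maj_idx), ceiling(phase + stride * (0:(n_min - 1)))))
  sort(c(which(labels == minority), maj_idx[pick]))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Inverse-frequency class weights
#'
#' `w_c` proportional to `1/count_c`, normalised so that
#' `sum_c w_c * count_c` equals the total sample count.
#'
#' @param labels integer 0/1 vector with both classes present.
#' @return named numeric vector of weights (`"0"`, `"1"`).
#' @export
class_weights <- function(labels) {
  cls <- table(factor(labels, levels = c(0, 1)))
  if (any(cls == 0)) stop("both classes required for class weights")
  n <- sum(cls)
  w <- n / (length(cls) * as.numeric(cls))
  names(w) <- names(cls)
  w
}

#' Add-One-Forget-One retraining schedule
#'
#' After each new seizure the model is retrained on the three seizures
#' immediately preceding the next (test) seizure: seizure `t+3` is tested
#' with seizures `t, t+1, t+2` as training, for `t = 1 ...`. Patients with
#' fewer than four lead seizures are excluded.
#'
#' @param seizure_ids chronologically ordered ids of the lead seizures.
#' @param chronological if TRUE, keep all past seizures instead of the
#'   most recent three (the alternative retraining variant); default FALSE.
#' @return list of `train_plan`s: each a list with `iteration`,
#'   `train_seizure_ids`, `test_seizure_id`.
#' @export
add_one_forget_one <- function(seizure_ids, chronological = FALSE) {
  n <- length(seizure_ids)
  if (n < 4) {
    stop("patient excluded: at least four lead seizures are required (got ",
         n, ")")
  }
  lapply(seq_len(n - 3), function(t) {
    train <- if (chronological) seizure_ids[seq_len(t + 2)]
             else seizure_ids[t:(t + 2)]
    structure(list(iteration = t,
                   train_seizure_ids = train,
                   test_seizure_id = seizure_ids[t + 3]),
              class = "train_plan")
  })
}
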