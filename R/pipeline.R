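#' Run configuration for the per-patient pipeline
#'
#' @param approach "control", "blw", "sbr" or "dwe".
#' @param labeling a [labeling_config()] (its `sop` is overridden by the
#'   grid search).
#' @param grid a [hyper_grid()].
#' @param fp_threshold Firing Power alarm threshold (default 0.5, fixed —
#'   deliberately excluded from the grid search).
#' @param surrogate_runs number of surrogate repetitions (default 30).
#' @param alpha significance level of the surrogate t-test (default 0.05).
#' @param seed integer seed for every stochastic step.
#' @param chronological use the keep-all-seizures retraining variant
#'   instead of Add-One-Forget-One (default FALSE).
#' @return list of class `run_config`.
#' @export
run_config <- function(approach = c("control", "blw", "sbr", "dwe"),
                       labeling = labeling_config(), grid = hyper_grid(),
                       fp_threshold = 0.5, surrogate_runs = 30,
                       alpha = 0.05, seed = 1, chronological = FALSE) {
  approach <- match.arg(approach)
  structure(list(approach = approach, labeling = labeling, grid = grid,
                 fp_threshold = fp_threshold,
                 surrogate_runs = surrogate_runs, alpha = alpha,
                 seed = seed, chronological = chronological),
            class = "run_config")
}

train_approach <- function(cfg, values, batches, plan, best, seed) {
  # assemble the plan's training rows in time order
  tb <- batches[vapply(batches, function(b) b$seizure_id, 0) %in%
                  plan$train_seizure_ids]
  rows <- unlist(lapply(tb, function(b) b$rows))
  labels <- unlist(lapply(tb, function(b) b$labels))
  times <- unlist(lapply(tb, function(b) b$times))
  bid <- unlist(lapply(tb, function(b) rep(b$seizure_id, length(b$rows))))
  ord <- order(times)
  rows <- rows[ord]; labels <- labels[ord]; times <- times[ord]
  bid <- bid[ord]
  if (cfg$approach == "control") {
    keep <- balance_undersample(labels, seed = seed)
    rows <- rows[keep]; labels <- labels[keep]; times <- times[keep]
  }
  std <- fit_standardiser(values[rows, , drop = FALSE])
  x <- apply_standardiser(std, values[rows, , drop = FALSE])
  sel <- select_features(x, labels, min(best$k, ncol(x)))
  xs <- x[, sel, drop = FALSE]
  anchor <- max(vapply(tb, function(b) b$onset, 0))
  model <- switch(cfg$approach,
    control = list(kind = "svm",
                   model = train_svm(xs, labels, cost = best$cost)),
    blw = {
      r <- blw_select(xs, labels, times, anchor, cost = best$cost)
      list(kind = "svm", model = r$model, detail = r)
    },
    sbr = {
      r <- sbr_select(xs, labels, bid, cost = best$cost)
      list(kind = "svm", model = r$model, detail = r)
    },
    dwe = {
      base <- dwe_build(xs, labels, times, cost = best$cost)
      cw <- which(times >= anchor - 2 * 3600 & times < anchor)
      if (length(cw) == 0) cw <- seq_along(times)
      wts <- dwe_weigh(base, xs[cw, , drop = FALSE], labels[cw])
      list(kind = "ensemble", models = base, weights = wts)
    })
  c(model, list(standardiser = std, selected = sel,
                train_time_range = range(times)))
}

classify_stream <- function(trained, values) {
  x <- apply_standardiser(trained$standardiser, values)
  xs <- x[, trained$selected, drop = FALSE]
  if (trained$kind == "ensemble") {
    dwe_predict(trained$models, trained$weights, xs)
  } else {
    predict(trained$model, xs)
  }
}

#' Run the full iterative pipeline for one patient
#'
#' Implements the per-patient loop: Add-One-Forget-One scheduling over the
#' lead seizures, leave-one-seizure-out hyperparameter grid search per
#' iteration (cost, number of features, SOP), final training via the
#' configured approach (control = plain SVM with systematic undersampling;
#' blw/sbr/dwe = the drift adapters with inverse-frequency class weights),
#' classification of the unseen test seizure's continuous stream, Firing
#' Power smoothing, alarm generation with refractory periods, event-level
#' scoring, and — across all iterations — surrogate statistical validation.
#'
#' @param features a `feature_matrix` for the patient.
#' @param annotations `seizure_annotations`.
#' @param cfg a [run_config()].
#' @return list of class `performance_report`: `ss`, `fpr_h`,
#'   `surrogate_mean`, `p_value`, `validated`, `iterations` (per-iteration
#'   details incl. selected hyperparameters), `n_test_seizures`.
#' @export
run_patient <- function(features, annotations, cfg = run_config()) {
  lead_ids <- which(annotations$lead)
  plans <- add_one_forget_one(lead_ids, chronological = cfg$chronological)
  epl <- features$window_length
  iterations <- list()
  all_alarm_times <- numeric(0)
  onsets <- numeric(0)
  intervals <- list()
  inter_hours <- 0
  for (plan in plans) {
    gs <- grid_search(features, annotations, plan, cfg$grid,
                      balance = if (cfg$approach == "control")
                        "undersample" else "weights",
                      cfg = cfg$labeling, seed = cfg$seed)
    best <- gs$best
    cfg_s <- cfg$labeling; cfg_s$sop <- best$sop
    batches <- label_samples(features, annotations, cfg_s)
    trained <- train_approach(cfg, features$values, batches, plan, best,
                              cfg$seed)
    test_b <- batches[[which(vapply(batches, function(b) b$seizure_id, 0) ==
                               plan$test_seizure_id)]]
    # the test stream: every epoch of the test seizure's span up to onset
    stream_lo <- if (length(test_b$times) > 0) min(test_b$times) else NA
    stream_idx <- which(features$epoch_start_times >= stream_lo &
                          features$epoch_start_times < test_b$onset)
    stream_times <- features$epoch_start_times[stream_idx]
    if (min(stream_times) <= trained$train_time_range[2]) {
      stop("chronology violation: test stream overlaps training data")
    }
    pred <- classify_stream(trained, features$values[stream_idx, , drop = FALSE])
    tau <- max(1, round(best$sop * 60 / epl))
    fp <- firing_power(pred, tau, epoch_times = stream_times)
    al <- raise_alarms(fp, threshold = cfg$fp_threshold,
                       refractory = best$sop * 60)
    iv <- c(min(stream_times),
            test_b$onset - (cfg$labeling$sph + best$sop) * 60)
    it_hours <- max(0, iv[2] - iv[1]) / 3600
    sc <- score_alarms(al, test_b$onset, best$sop, cfg$labeling$sph,
                       interictal_hours = it_hours)
    iterations[[plan$iteration]] <- list(
      iteration = plan$iteration, best = best,
      test_seizure_id = plan$test_seizure_id,
      n_alarms = length(al$alarm_times), score = sc,
      sop = best$sop, cost = best$cost, k = best$k,
      selected_features = trained$selected,
      train_time_range = trained$train_time_range,
      test_time_range = range(stream_times),
      grid_table = gs$table,
      detail = trained$detail %||% NULL)
    all_alarm_times <- c(all_alarm_times, al$alarm_times)
    onsets <- c(onsets, test_b$onset)
    intervals[[length(intervals) + 1]] <- iv
    inter_hours <- inter_hours + it_hours
  }
  sop_bar <- stats::median(vapply(iterations, function(i) i$sop, 0))
  combined <- structure(list(alarm_times = sort(all_alarm_times),
                             refractory = sop_bar * 60,
                             threshold = cfg$fp_threshold),
                        class = "alarm_series")
  total <- score_alarms(combined, sort(onsets), sop_bar, cfg$labeling$sph,
                        interictal_hours = inter_hours)
  sv <- surrogate_validate(combined, intervals, sop_bar, cfg$labeling$sph,
                           real_ss = as.numeric(total$ss),
                           n_runs = cfg$surrogate_runs, alpha = cfg$alpha,
                           seed = cfg$seed)
  structure(list(ss = as.numeric(total$ss), fpr_h = total$fpr_h,
                 surrogate_mean = sv$surrogate_mean,
                 surrogate_ss = sv$surrogate_ss,
                 t_statistic = sv$t_statistic, p_value = sv$p_value,
                 validated = sv$validated,
                 n_test_seizures = length(onsets),
                 approach = cfg$approach,
                 iterations = iterations),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> %s: SS %.2f, FPR/h %.2f, surrogate %.2f, %s\n",
              x$approach, x$ss, x$fpr_h, x$surrogate_mean,
              if (x$validated) "validated" else "not validated"))
  invisible(x)
}

#' Aggregate per-patient reports into cohort tables
#'
#' Mean +- SD of seizure sensitivity and FPR/h per approach, the percentage
#' of statistically validated patients, and (when `strata` tags are given)
#' the same aggregates per stratum.
#'
#' @param reports list of `performance_report`s (possibly mixed
#'   approaches).
#' @param strata optional character vector of stratum tags, one per report.
#' @return data.frame with one row per approach (x stratum).
#' @export
run_cohort <- function(reports, strata = NULL) {
  if (length(reports) == 0) stop("empty cohort")
  df <- data.frame(
    approach = vapply(reports, function(r) r$approach, ""),
    ss = vapply(reports, function(r) r$ss, 0),
    fpr_h = vapply(reports, function(r) r$fpr_h, 0),
    validated = vapply(reports, function(r) r$validated, TRUE),
    stratum = if (is.null(strata)) "overall" else strata
  )
  agg <- function(d) {
    data.frame(n_patients = nrow(d),
               ss_mean = mean(d$ss), ss_sd = stats::sd(d$ss),
               fpr_h_mean = mean(d$fpr_h), fpr_h_sd = stats::sd(d$fpr_h),
               pct_validated = 100 * mean(d$validated))
  }
  out <- do.call(rbind, lapply(split(df, list(df$approach, df$stratum),
                                     drop = TRUE), agg))
  out <- cbind(do.call(rbind, strsplit(rownames(out), ".", fixed = TRUE)),
               out)
  colnames(out)[1:2] <- c("approach", "stratum")
  rownames(out) <- NULL
  out
}

#' Relative frequencies of the selected hyperparameters
#'
#' Tallies the grid-search selections (SOP, cost, number of features, and
#' feature/channel identities) across iterations and patients; each
#' category's frequencies sum to 1.
#'
#' @param reports list of `performance_report`s.
#' @param feature_names optional full feature-name vector to resolve
#'   selected feature indices into names/channels.
#' @return named list of frequency tables (`sop`, `cost`, `k`, `feature`,
#'   `channel`).
#' @export
report_hyperparameter_frequencies <- function(reports, feature_names = NULL) {
  its <- unlist(lapply(reports, function(r) r$iterations), recursive = FALSE)
  if (length(its) == 0) stop("no completed iterations")
  freq <- function(v) {
    tb <- table(v)
    tb / sum(tb)
  }
  out <- list(
    sop = freq(vapply(its, function(i) i$sop, 0)),
    cost = freq(vapply(its, function(i) i$cost, 0)),
    k = freq(vapply(its, function(i) i$k, 0))
  )
  selected <- unlist(lapply(its, function(i) i$selected_features))
  if (!is.null(feature_names)) {
    fn <- feature_names[selected]
    out$feature <- freq(sub("^[^.]+\\.", "", fn))
    out$channel <- freq(sub("\\..*$", "", fn))
  } else {
    out$feature <- freq(selected)
  }
  out
}
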