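#' Leave-one-out error estimate for an SVM
#'
#' Two modes. `"xi_alpha"` computes the xi-alpha estimate of the
#' leave-one-out error: the fraction of training points with
#' `alpha_i * R^2 + xi_i >= 1`, where `alpha_i` are the dual coefficients,
#' `xi_i = max(0, 1 - y_i f(x_i))` the slacks, and `R^2` the maximum kernel
#' self-similarity over the training points. This form returns 0 on
#' wide-margin separable data and upper-bounds the exact leave-one-out
#' error in practice (the conservative textbook bound carries an extra
#' factor 2 on the `alpha` term but is then never 0, even for trivially
#' separable data). `"exact"` retrains `n` times and returns the true
#' leave-one-out error (a point whose removal leaves a single class is
#' predicted as that class).
#'
#' @param model a `ds_svm` from [train_svm()].
#' @param x,labels the training data the model was fitted on.
#' @param mode "xi_alpha" or "exact".
#' @return error fraction in `[0, 1]`.
#' @export
loo_estimate <- function(model, x, labels, mode = c("xi_alpha", "exact")) {
  mode <- match.arg(mode)
  if (!inherits(model, "ds_svm")) stop("untrained or foreign model")
  n <- nrow(x)
  if (mode == "xi_alpha") {
    y <- ifelse(labels == 1, 1, -1)
    f <- svm_decision(model, x)
    xi <- pmax(0, 1 - y * f)
    alpha <- numeric(n)
    alpha[model$fit$index] <- abs(model$fit$coefs[, 1])
    r2 <- if (model$kernel == "linear") max(rowSums(x^2)) else 1
    mean(alpha * r2 + xi >= 1)
  } else {
    if (n < 2) stop("exact LOO undefined for n < 2")
    errs <- vapply(seq_len(n), function(i) {
      yi <- labels[-i]
      if (length(unique(yi)) < 2) {
        return(as.numeric(unique(yi) != labels[i]))
      }
      w <- model$fit$class.weights
      m <- train_svm(x[-i, , drop = FALSE], yi, cost = model$cost,
                     kernel = model$kernel, weights = w)
      as.numeric(predict(m, x[i, , drop = FALSE]) != labels[i])
    }, 0)
    mean(errs)
  }
}

#' Backwards-Landmark Window training-window selection
#'
#' Grows candidate training windows backwards in time from the most recent
#' training seizure's onset in 1-hour steps, trains an SVM per candidate,
#' and computes its leave-one-out estimate over the candidate's rows. The
#' search stops early when the best estimate has not improved across
#' `early_stop` consecutive enlargements. The window minimising the
#' estimate wins (smallest window on ties). Candidates whose rows contain a
#' single class are skipped. All preictal rows of seizures whose onset lies
#' inside the window are always included.
#'
#' @param x standardised, feature-selected matrix for the plan's training
#'   span.
#' @param labels 0/1 per row.
#' @param times epoch start times in seconds, aligned with `x`.
#' @param anchor seconds: onset of the most recent training seizure.
#' @param step_hours window enlargement step (default 1).
#' @param early_stop patience in steps without improvement (default 12).
#' @param cost,weights SVM settings.
#' @param loo_mode passed to [loo_estimate()].
#' @return list of class `blw_result`: `window_hours`, `model`,
#'   `row_index` (rows inside the selected window), `candidates`
#'   (data.frame window_hours / loo / n_rows).
#' @export
blw_select <- function(x, labels, times, anchor, step_hours = 1,
                       early_stop = 12, cost = 1, weights = NULL,
                       loo_mode = "xi_alpha") {
  span_h <- (anchor - min(times)) / 3600
  if (span_h < step_hours) stop("training data must span at least one step")
  max_w <- ceiling(span_h)
  cand <- data.frame(window_hours = numeric(0), loo = numeric(0),
                     n_rows = integer(0))
  models <- list(); rowsets <- list()
  best <- Inf; best_wh <- 0
  for (wh in seq(step_hours, max_w, by = step_hours)) {
    # patience: stop before exploring windows more than `early_stop` steps
    # beyond the current best
    if (wh - best_wh >= early_stop * step_hours) break
    sel <- which(times >= anchor - wh * 3600 & times < anchor)
    est <- NA_real_
    if (length(sel) >= 4 && length(unique(labels[sel])) == 2) {
      w <- if (is.null(weights)) class_weights(labels[sel]) else weights
      m <- train_svm(x[sel, , drop = FALSE], labels[sel], cost = cost,
                     weights = w)
      est <- loo_estimate(m, x[sel, , drop = FALSE], labels[sel],
                          mode = loo_mode)
      models[[as.character(wh)]] <- m
      rowsets[[as.character(wh)]] <- sel
    }
    cand <- rbind(cand, data.frame(window_hours = wh, loo = est,
                                   n_rows = length(sel)))
    if (!is.na(est) && est < best - 1e-12) {
      best <- est; best_wh <- wh
    }
  }
  ok <- which(!is.na(cand$loo))
  if (length(ok) == 0) {
    stop("no trainable candidate window (single class everywhere); ",
         "widen the window or include preictal rows")
  }
  pick <- ok[order(cand$loo[ok], cand$window_hours[ok])][1]
  wh <- cand$window_hours[pick]
  structure(list(window_hours = wh,
                 model = models[[as.character(wh)]],
                 row_index = rowsets[[as.character(wh)]],
                 candidates = cand),
            class = "blw_result")
}

#' Angle between two weight vectors
#'
#' `acos` of the cosine similarity (clamped to `[-1, 1]`), in degrees.
#' Symmetric and scale-invariant for positive scalings.
#'
#' @param w1,w2 numeric vectors of equal length, both non-zero.
#' @return angle in degrees, in `[0, 180]`.
#' @export
sbr_angle <- function(w1, w2) {
  if (length(w1) != length(w2)) stop("dimension mismatch")
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  if (n1 == 0 || n2 == 0) stop("angle undefined for a zero vector")
  u <- w1 / n1; v <- w2 / n2
  # atan2 form is accurate near 0 and 180 degrees, unlike plain acos
  2 * atan2(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2))) * 180 / pi
}

fit_logistic_weights <- function(x, labels, lambda = 1e-2) {
  fit <- tryCatch(
    glmnet::glmnet(x, factor(labels, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = lambda, standardize = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.numeric(fit$beta[, 1])                      # intercept excluded
}

#' Seizure-batch Regression training-set selection
#'
#' Fits an L2-regularised logistic regression on every chronological
#' combination of the plan's training seizures and compares its weight
#' vector (intercept excluded) against a reference regression trained on
#' the most recent seizure only, via the [sbr_angle()]. The combination
#' with the smallest angle wins; combinations whose angle is within
#' `angle_tol` degrees of the minimum are treated as tied and the largest
#' (then most recent) subset is preferred. The reference singleton itself
#' is excluded from the candidate enumeration (its angle is identically
#' zero). The final SVM is trained on the selected subset's rows.
#'
#' @param x standardised, feature-selected matrix.
#' @param labels 0/1 per row.
#' @param batch_ids per-row id of the training seizure the row belongs to.
#' @param cost SVM cost for the final model.
#' @param lambda ridge penalty for the logistic regressions.
#' @param angle_tol degrees within which angles count as tied (default 15).
#' @return list of class `sbr_result`: `subset` (selected seizure ids),
#'   `model`, `row_index`, `table` (subset / angle / n_rows).
#' @export
sbr_select <- function(x, labels, batch_ids, cost = 1, lambda = 1e-2,
                       angle_tol = 15) {
  ids <- sort(unique(batch_ids))
  if (length(ids) < 2) stop("need at least two training seizures")
  last <- ids[length(ids)]
  ref_rows <- which(batch_ids == last)
  w_ref <- fit_logistic_weights(x[ref_rows, , drop = FALSE],
                                labels[ref_rows], lambda)
  if (is.null(w_ref) || all(w_ref == 0)) {
    stop("reference regression failed on the most recent seizure")
  }
  subsets <- unlist(lapply(seq_along(ids), function(m) {
    utils::combn(ids, m, simplify = FALSE)
  }), recursive = FALSE)
  subsets <- Filter(function(s) !(length(s) == 1 && s == last), subsets)
  tab <- data.frame(subset = vapply(subsets, paste, "", collapse = "+"),
                    size = lengths(subsets),
                    recency = vapply(subsets, max, 0),
                    angle = NA_real_, n_rows = NA_integer_)
  for (i in seq_along(subsets)) {
    rows <- which(batch_ids %in% subsets[[i]])
    tab$n_rows[i] <- length(rows)
    if (length(unique(labels[rows])) < 2) next
    w <- fit_logistic_weights(x[rows, , drop = FALSE], labels[rows], lambda)
    if (is.null(w) || all(w == 0)) {
      warning("regression failed for subset ", tab$subset[i], "; skipped")
      next
    }
    tab$angle[i] <- sbr_angle(w, w_ref)
  }
  ok <- which(!is.na(tab$angle))
  if (length(ok) == 0) stop("every candidate combination failed")
  amin <- min(tab$angle[ok])
  tied <- ok[tab$angle[ok] <= amin + angle_tol]
  pick <- tied[order(-tab$size[tied], -tab$recency[tied])][1]
  rows <- which(batch_ids %in% subsets[[pick]])
  w <- class_weights(labels[rows])
  model <- train_svm(x[rows, , drop = FALSE], labels[rows], cost = cost,
                     weights = w)
  structure(list(subset = subsets[[pick]], model = model, row_index = rows,
                 table = tab), class = "sbr_result")
}

#' Build the Dynamic Weighted Ensemble base models
#'
#' Partitions the training span's interictal rows into non-overlapping
#' 1-hour segments and trains one SVM per segment on that segment's
#' interictal rows plus the shared pool of all preictal rows (guaranteeing
#' two classes). Segments with fewer than `min_rows` interictal rows are
#' skipped.
#'
#' @param x standardised, feature-selected matrix.
#' @param labels 0/1 per row.
#' @param times epoch start times (s).
#' @param period_hours segment length (default 1).
#' @param cost SVM cost.
#' @param min_rows minimum interictal rows per segment (default 12).
#' @return list of base models, each with `model`, `segment` (start/end s).
#' @export
dwe_build <- function(x, labels, times, period_hours = 1, cost = 1,
                      min_rows = 12) {
  inter <- which(labels == 0); pre <- which(labels == 1)
  if (length(pre) == 0) stop("no preictal rows available")
  span <- range(times[inter])
  if (diff(span) < 2 * period_hours * 3600 - 1) {
    stop("training data must span at least two segments")
  }
  edges <- seq(span[1], span[2] + 1, by = period_hours * 3600)
  models <- list()
  for (s in seq_len(length(edges) - 1)) {
    seg <- inter[times[inter] >= edges[s] & times[inter] < edges[s + 1]]
    if (length(seg) < min_rows) next
    rows <- c(seg, pre)
    w <- class_weights(labels[rows])
    m <- train_svm(x[rows, , drop = FALSE], labels[rows], cost = cost,
                   weights = w)
    models[[length(models) + 1]] <- list(model = m,
                                         segment = edges[s + 0:1])
  }
  if (length(models) == 0) stop("no viable 1-hour segment")
  models
}

#' Weight the ensemble by recent-concept accuracy
#'
#' Each base model is weighted by its accuracy on the concept window (the
#' last two hours before the most recent training seizure's onset),
#' normalised to sum to 1. If every accuracy is zero, uniform weights are
#' returned with a warning.
#'
#' @param models list from [dwe_build()].
#' @param x_concept,labels_concept the concept-window rows and labels.
#' @return numeric weight vector summing to 1.
#' @export
dwe_weigh <- function(models, x_concept, labels_concept) {
  if (length(labels_concept) == 0) stop("empty concept window")
  acc <- vapply(models, function(bm) {
    mean(predict(bm$model, x_concept) == labels_concept)
  }, 0)
  if (sum(acc) == 0) {
    warning("all base accuracies are zero; falling back to uniform weights")
    return(rep(1 / length(models), length(models)))
  }
  acc / sum(acc)
}

#' Weighted-vote prediction of the ensemble
#'
#' Label 1 iff the weighted sum of base predictions is `>= 0.5` (ties go to
#' the preictal class). Under uniform weights this is the majority vote.
#'
#' @param models list from [dwe_build()].
#' @param weights probability vector from [dwe_weigh()].
#' @param x rows to classify.
#' @return integer 0/1 vector.
#' @export
dwe_predict <- function(models, weights, x) {
  if (length(models) != length(weights)) stop("model/weight length mismatch")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  votes <- vapply(models, function(bm) predict(bm$model, x),
                  integer(if (is.null(dim(x))) 1 else nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  as.integer(as.numeric(votes %*% weights) >= 0.5 - 1e-12)
}
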