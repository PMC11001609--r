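#' Univariate filter feature selection (one-way ANOVA F)
#'
#' Ranks columns by the two-group one-way ANOVA F statistic (equivalently
#' the squared two-sample t statistic) and returns the top `k` column
#' indices. Deterministic; ties broken by column index. Constant columns
#' score 0.
#'
#' @param x numeric matrix (rows = samples).
#' @param labels 0/1 vector, both classes present.
#' @param k number of columns to keep.
#' @return integer vector of length `k`, ordered by decreasing F.
#' @export
select_features <- function(x, labels, k) {
  if (k <= 0) stop("k must be positive")
  if (k > ncol(x)) stop("k exceeds the number of columns")
  g0 <- labels == 0; g1 <- labels == 1
  n0 <- sum(g0); n1 <- sum(g1)
  if (n0 == 0 || n1 == 0) stop("both classes required")
  m0 <- colMeans(x[g0, , drop = FALSE])
  m1 <- colMeans(x[g1, , drop = FALSE])
  m <- colMeans(x)
  ss_between <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
  ss_within <- colSums(sweep(x[g0, , drop = FALSE], 2, m0)^2) +
               colSums(sweep(x[g1, , drop = FALSE], 2, m1)^2)
  f <- ifelse(ss_within > 0, ss_between / 1 / (ss_within / (n0 + n1 - 2)), 0)
  order(-f, seq_along(f))[seq_len(k)]
}

#' Train a support vector machine
#'
#' Thin wrapper around `e1071::svm` (libsvm) with the conventions used
#' throughout the pipeline: no internal scaling (standardisation is done
#' explicitly upstream), linear kernel by default, optional inverse-frequency
#' class weights. Training is deterministic given the data.
#'
#' @param x standardised numeric matrix.
#' @param labels 0/1 vector.
#' @param cost SVM cost parameter C.
#' @param kernel "linear" (default) or "radial".
#' @param weights optional named class-weight vector from [class_weights()].
#' @return fitted model of class `ds_svm` (wrapping the `e1071::svm` fit).
#' @export
train_svm <- function(x, labels, cost = 1, kernel = "linear",
                      weights = NULL) {
  y <- factor(labels, levels = c(0, 1))
  if (any(table(y) == 0) && is.null(weights)) {
    stop("single-class training data without class weights")
  }
  fit <- e1071::svm(x, y, kernel = kernel, cost = cost, scale = FALSE,
                    class.weights = weights)
  structure(list(fit = fit, cost = cost, kernel = kernel, n = nrow(x)),
            class = "ds_svm")
}

#' @export
predict.ds_svm <- function(object, newdata, decision_values = FALSE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  p <- stats::predict(object$fit, newdata, decision.values = decision_values)
  out <- as.integer(as.character(p))
  if (decision_values) {
    attr(out, "decision_values") <- svm_decision(object, newdata)
  }
  out
}

# signed decision values oriented so that positive means class 1 (preictal)
svm_decision <- function(model, x) {
  dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
             "decision.values")
  v <- dv[, 1]
  # libsvm orients the decision function toward the first training label;
  # flip so that positive always means the preictal class
  pos_first <- colnames(dv)[1]
  if (!startsWith(pos_first, "1")) v <- -v
  v
}

#' Sample-level sensitivity and specificity
#'
#' `Sss = TP/(TP+FN)` over preictal (label 1) samples, `Ssp = TN/(TN+FP)`
#' over interictal (label 0) samples.
#'
#' @param pred,truth 0/1 vectors of equal length.
#' @return list `sss`, `ssp` (NA with attribute `"undefined"` when a class
#'   is absent from `truth`).
#' @export
sample_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  sss <- if (n1 == 0) structure(NA_real_, undefined = TRUE)
         else sum(pred == 1 & truth == 1) / n1
  ssp <- if (n0 == 0) structure(NA_real_, undefined = TRUE)
         else sum(pred == 0 & truth == 0) / n0
  list(sss = sss, ssp = ssp)
}

#' Hyperparameter grid
#'
#' @param cost_grid SVM costs (default `2^c(-10,-8,-6,-4,-2,0,2)`).
#' @param n_features_grid candidate numbers of selected features
#'   (default `c(10, 20, 30, 40)`).
#' @param sop_grid candidate SOP durations in minutes
#'   (default `seq(10, 50, by = 5)`).
#' @return list of class `hyper_grid`.
#' @export
hyper_grid <- function(cost_grid = 2^c(-10, -8, -6, -4, -2, 0, 2),
                       n_features_grid = c(10, 20, 30, 40),
                       sop_grid = seq(10, 50, by = 5)) {
  stopifnot(length(cost_grid) > 0, length(n_features_grid) > 0,
            length(sop_grid) > 0)
  structure(list(cost_grid = cost_grid,
                 n_features_grid = n_features_grid,
                 sop_grid = sop_grid), class = "hyper_grid")
}

#' Leave-one-seizure-out hyperparameter grid search
#'
#' For every `(cost, k, sop)` combination, labels the plan's three training
#' seizures under that SOP, then cycles each training seizure as validation
#' fold: standardiser and feature selection are fitted on the other two
#' seizures (balanced per `balance`), an SVM is trained, and the geometric
#' mean `sqrt(Sss * Ssp)` is computed on the held-out seizure. The score is
#' the fold mean; the maximising combination wins, ties resolved toward
#' smaller SOP, then smaller cost, then fewer features. The full score table
#' is returned for hyperparameter-frequency reporting.
#'
#' @param features a `feature_matrix` for the patient.
#' @param annotations `seizure_annotations`.
#' @param plan a `train_plan` from [add_one_forget_one()].
#' @param grid a [hyper_grid()].
#' @param balance "weights" (inverse-frequency class weights, drift
#'   approaches) or "undersample" (systematic undersampling, control).
#' @param cfg base [labeling_config()] supplying SPH and exclusions.
#' @param seed integer, controls undersampling.
#' @return list of class `grid_search_result`: `best` (cost, k, sop, score),
#'   `table` (all combinations), `selected_features` (indices fitted on all
#'   three training seizures under the best combination), `standardiser`.
#' @export
grid_search <- function(features, annotations, plan, grid = hyper_grid(),
                        balance = c("weights", "undersample"),
                        cfg = labeling_config(), seed = 1) {
  balance <- match.arg(balance)
  combos <- expand.grid(cost = grid$cost_grid, k = grid$n_features_grid,
                        sop = grid$sop_grid, KEEP.OUT.ATTRS = FALSE)
  combos$score <- NA_real_
  for (sop in grid$sop_grid) {
    cfg_s <- cfg; cfg_s$sop <- sop
    batches <- label_samples(features, annotations, cfg_s)
    tb <- batches[vapply(batches, function(b) b$seizure_id, 0) %in%
                    plan$train_seizure_ids]
    if (length(tb) != 3) next
    rows_sop <- which(combos$sop == sop)
    folds <- lapply(1:3, function(v) {
      tr <- do.call(rbind, lapply(tb[-v], function(b) {
        cbind(b$rows, b$labels)
      }))
      list(train_rows = tr[, 1], train_labels = tr[, 2],
           val_rows = tb[[v]]$rows, val_labels = tb[[v]]$labels)
    })
    for (ri in rows_sop) {
      cost <- combos$cost[ri]; k <- combos$k[ri]
      sc <- vapply(folds, function(fd) {
        score_fold(features$values, fd, cost, k, balance, seed)
      }, 0)
      sc <- sc[!is.na(sc)]
      combos$score[ri] <- if (length(sc) == 0) NA else mean(sc)
    }
  }
  valid <- which(!is.na(combos$score))
  if (length(valid) == 0) stop("no grid combination was evaluable")
  # max score; ties -> smaller sop, then smaller cost, then smaller k
  ord <- valid[order(-combos$score[valid], combos$sop[valid],
                     combos$cost[valid], combos$k[valid])]
  best <- combos[ord[1], ]
  structure(list(best = best, table = combos), class = "grid_search_result")
}

score_fold <- function(values, fd, cost, k, balance, seed) {
  trl <- fd$train_labels
  if (length(unique(trl)) < 2 || length(unique(fd$val_labels)) < 2) {
    return(NA_real_)
  }
  tri <- fd$train_rows
  if (balance == "undersample") {
    keep <- balance_undersample(trl, seed = seed)
    tri <- tri[keep]; trl <- trl[keep]
  }
  std <- fit_standardiser(values[tri, , drop = FALSE])
  xtr <- apply_standardiser(std, values[tri, , drop = FALSE])
  sel <- select_features(xtr, trl, min(k, ncol(xtr)))
  w <- if (balance == "weights") class_weights(trl) else NULL
  m <- train_svm(xtr[, sel, drop = FALSE], trl, cost = cost, weights = w)
  xv <- apply_standardiser(std, values[fd$val_rows, , drop = FALSE])
  pr <- predict(m, xv[, sel, drop = FALSE])
  sm <- sample_metrics(pr, fd$val_labels)
  sqrt(sm$sss * sm$ssp)
}
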