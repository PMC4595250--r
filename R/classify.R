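#' SVM model configuration
#'
#' Settings of the RBF-kernel support vector machine used by the diagnostic.
#' Hyperparameters are chosen by jackknife (leave-one-out) accuracy over a
#' grid; ties are broken toward the smallest penalty `C`, then the smallest
#' kernel width `gamma`. Default grids are powers of two with stride 2,
#' the usual coarse libsvm search.
#'
#' @param C_grid Positive penalty values to search.
#' @param gamma_grid Positive RBF kernel widths to search.
#' @param class_weighting `"none"` or `"balanced"` (weights inversely
#'   proportional to class frequencies).
#' @param scale_features Standardize each feature column before fitting
#'   (recommended: after area normalization intensities are on a small
#'   absolute scale and column standardization puts squared distances in
#'   the range the default gamma grid covers).
#' @return A list of class `model_config`.
#' @export
model_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                         gamma_grid = 2^seq(-15, 3, by = 2),
                         class_weighting = c("none", "balanced"),
                         scale_features = TRUE) {
  class_weighting <- match.arg(class_weighting)
  stopifnot(length(C_grid) >= 1, all(C_grid > 0),
            length(gamma_grid) >= 1, all(gamma_grid > 0))
  structure(list(kernel = "RBF", C_grid = C_grid, gamma_grid = gamma_grid,
                 class_weighting = class_weighting,
                 scale_features = scale_features),
            class = "model_config")
}

#' Build a binary classification task from a cohort
#'
#' Rows are the spectra of the two groups; features are the full normalized
#' intensity vectors (one column per grid point); patient ids are retained
#' so leave-one-patient-out folds can be formed.
#'
#' @param cohort A preprocessed [sers_cohort()] containing both groups.
#' @param positive,negative Distinct group labels; `positive` is the class
#'   whose recovery sensitivity measures.
#' @return A list of class `sers_task`: `x` (matrix), `y` (factor with
#'   levels `negative`, `positive`), `patient_id`, `positive`, `negative`.
#' @export
build_task <- function(cohort, positive, negative) {
  stopifnot(inherits(cohort, "sers_cohort"))
  if (positive == negative) stop("config error: positive == negative")
  for (g in c(positive, negative))
    if (!g %in% cohort$meta$group) stop("group missing from cohort: ", g)
  idx <- cohort$meta$group %in% c(positive, negative)
  structure(list(x = cohort$intensity[idx, , drop = FALSE],
                 y = factor(cohort$meta$group[idx],
                            levels = c(negative, positive)),
                 patient_id = cohort$meta$patient_id[idx],
                 positive = positive, negative = negative),
            class = "sers_task")
}

svm_fit <- function(x, y, C, gamma, config) {
  cw <- if (config$class_weighting == "balanced") {
    tab <- table(y)
    w <- length(y) / (length(tab) * tab)
    stats::setNames(as.numeric(w), names(tab))
  } else NULL
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = config$scale_features,
             class.weights = cw)
}

# leave-one-out accuracy via libsvm's internal n-fold cross validation
# (with k = n every fold is a single row, so the result is deterministic)
loo_accuracy <- function(x, y, C, gamma, config) {
  cw <- if (config$class_weighting == "balanced") {
    tab <- table(y)
    stats::setNames(as.numeric(length(y) / (length(tab) * tab)), names(tab))
  } else NULL
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = config$scale_features,
                    class.weights = cw, cross = length(y))
  fit$tot.accuracy / 100
}

#' Jackknife hyperparameter optimization
#'
#' Exhaustive grid search: for every `(C, gamma)` pair the leave-one-spectrum
#' -out accuracy on the supplied (training) data is computed and the argmax
#' returned; ties are broken toward the smallest `C`, then smallest `gamma`.
#'
#' @param task A [build_task()] result (or a compatible list with `x`, `y`).
#' @param config A [model_config()].
#' @return A list `C`, `gamma`, `inner_accuracy`, plus the full `grid`
#'   data frame of leave-one-out accuracies.
#' @export
jackknife_optimize <- function(task, config = model_config()) {
  y <- task$y
  if (nlevels(droplevels(y)) < 2 || any(table(droplevels(y)) < 2))
    stop("jackknife_optimize needs at least 2 rows per class")
  grid <- expand.grid(C = sort(config$C_grid),
                      gamma = sort(config$gamma_grid))
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i)
    loo_accuracy(task$x, y, grid$C[i], grid$gamma[i], config),
    numeric(1))
  # ties: smallest C then smallest gamma -> order by (C, gamma), keep first max
  o <- order(grid$C, grid$gamma)
  grid <- grid[o, ]
  best <- which.max(grid$accuracy)
  list(C = grid$C[best], gamma = grid$gamma[best],
       inner_accuracy = grid$accuracy[best], grid = grid)
}

#' Cross-validate a binary SVM task
#'
#' Leave-one-spectrum-out (`"LOSO"`): each fold holds out one spectrum.
#' Leave-one-patient-out (`"LOPO"`): each fold holds out all spectra of one
#' patient, so no spectrum of the held-out patient can inform the model
#' (identity-leakage guard, asserted per fold). With `optimize = "nested"`
#' hyperparameters are re-selected by [jackknife_optimize()] on each fold's
#' training portion; `optimize = "once"` selects them once on the full task
#' before cross-validating (the cheaper, historically common protocol).
#' Predictions are pooled over folds into one confusion matrix.
#'
#' A LOPO fold whose training portion lacks one class (a patient owning all
#' spectra of a class) is skipped with a warning and reported.
#'
#' @param task A [build_task()] result.
#' @param scheme `"LOSO"` or `"LOPO"`.
#' @param config A [model_config()].
#' @param optimize `"nested"` or `"once"`.
#' @return A list of class `sers_cv`: `counts` (see [confusion_counts()]),
#'   `scheme`, `optimize`, `params` (chosen `C`/`gamma`; per-fold list when
#'   nested), `predictions` data frame, `skipped_folds`, `folds` (held-out
#'   row indices per fold).
#' @export
cross_validate <- function(task, scheme = c("LOSO", "LOPO"),
                           config = model_config(),
                           optimize = c("nested", "once")) {
  scheme <- match.arg(scheme)
  optimize <- match.arg(optimize)
  n <- nrow(task$x)
  folds <- if (scheme == "LOSO") as.list(seq_len(n))
           else split(seq_len(n), task$patient_id)
  shared <- if (optimize == "once") jackknife_optimize(task, config)
  preds <- truth <- character(0)
  fold_id <- integer(0)
  row_id <- integer(0)
  skipped <- character(0)
  params <- list()
  for (k in seq_along(folds)) {
    test <- folds[[k]]
    train <- setdiff(seq_len(n), test)
    # leakage guard: train and test patient sets must be disjoint under LOPO
    if (scheme == "LOPO" &&
        length(intersect(task$patient_id[train], task$patient_id[test])))
      stop("internal error: patient leakage across LOPO fold")
    ytr <- droplevels(task$y[train])
    if (nlevels(ytr) < 2) {
      warning("fold ", names(folds)[k] %||% k,
              " skipped: training portion has a single class")
      skipped <- c(skipped, names(folds)[k] %||% as.character(k))
      next
    }
    par <- if (optimize == "nested") {
      jackknife_optimize(list(x = task$x[train, , drop = FALSE],
                              y = task$y[train]), config)
    } else shared
    fit <- svm_fit(task$x[train, , drop = FALSE], task$y[train],
                   par$C, par$gamma, config)
    p <- stats::predict(fit, task$x[test, , drop = FALSE])
    preds <- c(preds, as.character(p))
    truth <- c(truth, as.character(task$y[test]))
    fold_id <- c(fold_id, rep(k, length(test)))
    row_id <- c(row_id, test)
    params[[k]] <- list(C = par$C, gamma = par$gamma)
  }
  if (!length(preds)) stop("all folds degenerate; nothing predicted")
  counts <- confusion_counts(
    tp = sum(truth == task$positive & preds == task$positive),
    fn = sum(truth == task$positive & preds != task$positive),
    tn = sum(truth == task$negative & preds == task$negative),
    fp = sum(truth == task$negative & preds != task$negative),
    positive = task$positive, negative = task$negative)
  structure(list(counts = counts, scheme = scheme, optimize = optimize,
                 params = if (optimize == "once")
                   list(C = shared$C, gamma = shared$gamma) else params,
                 predictions = data.frame(row = row_id, fold = fold_id,
                                          truth = truth, predicted = preds,
                                          stringsAsFactors = FALSE),
                 skipped_folds = skipped, folds = folds),
            class = "sers_cv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion counts for one binary task
#'
#' @param tp,fn,tn,fp Non-negative integer counts (true/false positives and
#'   negatives).
#' @param positive,negative The class labels the counts refer to.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, tn, fp, positive = "positive",
                             negative = "negative") {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 positive = positive, negative = negative),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %s (+) vs %s (-): tp=%d fn=%d tn=%d fp=%d\n",
              x$positive, x$negative, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Diagnostic metrics from confusion counts
#'
#' Specificity `SP = tn/(tn+fp)`, sensitivity `SE = tp/(tp+fn)`, accuracy
#' `ACC = (tp+tn)/n`, and the Matthews correlation coefficient
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention `MCC = 0` when any marginal (hence the denominator) is zero.
#'
#' @param counts A [confusion_counts()].
#' @return A list of class `metric_report`: `SP`, `SE`, `ACC`, `MCC`,
#'   `positive`, `negative`, `n`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); fn <- as.numeric(counts$fn)
  tn <- as.numeric(counts$tn); fp <- as.numeric(counts$fp)
  n <- tp + fn + tn + fp
  if (n == 0) stop("all-zero confusion counts")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  structure(list(
    SP = tn / (tn + fp),
    SE = tp / (tp + fn),
    ACC = (tp + tn) / n,
    MCC = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den),
    positive = counts$positive, negative = counts$negative, n = n),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s (+) vs %s (-), n = %d\n", x$positive, x$negative, x$n))
  cat(sprintf("  SP %s  SE %s  ACC %s  MCC %.3f\n",
              format_pct(x$SP), format_pct(x$SE), format_pct(x$ACC), x$MCC))
  invisible(x)
}

format_pct <- function(p) sprintf("%.1f %%", round_half_away(100 * p, 1))

#' Reconstruct confusion counts from published rates
#'
#' Given sensitivity, specificity and the two class sizes, recovers the
#' integer counts: `tp = round(se * n_pos)`, `tn = round(sp * n_neg)`
#' (round half away from zero), with `fn`/`fp` as complements. Useful for
#' checking published metric tables for internal consistency.
#'
#' @param se,sp Rates in `[0, 1]`.
#' @param n_pos,n_neg Class sizes.
#' @param positive,negative Optional labels.
#' @return A [confusion_counts()].
#' @export
counts_from_rates <- function(se, sp, n_pos, n_neg,
                              positive = "positive", negative = "negative") {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1)
  tp <- round_half_away(se * n_pos)
  tn <- round_half_away(sp * n_neg)
  confusion_counts(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn,
                   positive = positive, negative = negative)
}
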