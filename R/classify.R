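#' Binary maculopathy label from a 10-stage retinopathy grade
#'
#' The 10-stage scale collapses to maculopathy present/absent: the four
#' "with maculopathy" stages are positive; every other stage, including
#' No DR and advanced diabetic eye disease (ADED), is negative.
#'
#' @param stage Character vector of stage names (see
#'   [retinopathy_stages()]).
#' @return Logical vector.
#' @export
label_from_stage <- function(stage) {
  stages <- retinopathy_stages()
  bad <- setdiff(unique(stage), stages)
  if (length(bad))
    stop("unknown retinopathy stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  positive <- c("Mild DR with maculopathy", "Moderate DR with maculopathy",
                "Severe DR with maculopathy", "PDR with maculopathy")
  stage %in% positive
}

#' Oversample the minority class by seeded duplication
#'
#' Grows the minority class to exactly `target` rows by duplicating
#' randomly chosen minority rows; the majority class is untouched and
#' the combined rows are shuffled deterministically by `seed`.
#'
#' @param features Numeric matrix or data frame of feature rows.
#' @param labels Logical class labels, one per row.
#' @param target Desired minority class size; defaults to the majority
#'   class size (parity). Must be at least the current minority size.
#' @param seed Integer seed controlling both the duplication draws and
#'   the final shuffle.
#' @return List with `features` and `labels` of the oversampled dataset.
#' @export
oversample_minority <- function(features, labels, target = NULL, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (nrow(features) != length(labels))
    stop("`features` and `labels` lengths differ", call. = FALSE)
  tab <- table(factor(labels, levels = c(FALSE, TRUE)))
  if (any(tab == 0L)) stop("one class is empty", call. = FALSE)
  minority <- names(tab)[which.min(tab)] == "TRUE"
  n_min <- min(tab); n_maj <- max(tab)
  if (is.null(target)) target <- as.integer(n_maj)
  if (target < n_min)
    stop("`target` below the current minority size", call. = FALSE)
  idx_min <- which(labels == minority)
  with_seed(seed, {
    extra <- if (target > n_min)
      sample(idx_min, target - n_min, replace = TRUE) else integer(0)
    keep <- c(seq_along(labels), extra)
    keep <- sample(keep)
  })
  list(features = features[keep, , drop = FALSE], labels = labels[keep])
}

#' Confusion-matrix performance metrics
#'
#' @param tp,fp,tn,fn Confusion counts (positive class = maculopathy
#'   detected).
#' @return Class `"eval_result"`: list with the four counts and
#'   `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#'   `accuracy = (TP+TN)/total` and
#'   `misclassification_error = 1 - accuracy`. Ratios with a zero
#'   denominator are `NA`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, total),
    misclassification_error = 1 - safe_div(tp + tn, total)),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("misclassification error %.4f | accuracy %.4f | specificity %.4f | sensitivity %.4f\n",
              x$misclassification_error, x$accuracy, x$specificity,
              x$sensitivity))
  invisible(x)
}

#' Evaluate a classifier by repeated stratified random splits
#'
#' The Monte-Carlo cross-validation protocol: per repeat, a seeded
#' stratified split keeps `train_frac` of each class for training, the
#' named model is fitted on z-scored features (train-fold statistics)
#' and evaluated on the held-out rows; per-repeat metrics are averaged
#' (a metric undefined in a repeat, e.g. sensitivity when the test fold
#' has no positives, is recorded as missing and skipped, not zeroed).
#' Confusion counts are summed over repeats.
#'
#' Models: `knn1` (1-nearest neighbour, Euclidean distance on the
#' standardised features); `svm_poly` (polynomial-kernel SVM, degree 3,
#' C = 1); `svm_rbf` (radial-basis-kernel SVM, gamma = 1/number of
#' features on the standardised scale, C = 1); `naive_bayes` (Gaussian
#' naive Bayes with the per-class standard deviations floored at a
#' small smoothing value so constant-within-class features keep finite
#' likelihoods).
#'
#' @param features Numeric matrix/data frame of feature rows.
#' @param labels Logical labels (TRUE = maculopathy detected).
#' @param model One of `"knn1"`, `"svm_poly"`, `"svm_rbf"`,
#'   `"naive_bayes"`.
#' @param repeats Number of random splits (default 10).
#' @param train_frac Training fraction per class, in (0, 1)
#'   (default 0.9).
#' @param seed Integer seed; fixed seed gives bit-identical splits and
#'   metrics.
#' @param degree,cost,nb_sd_floor Model hyper-parameters (polynomial
#'   degree, SVM regularisation, naive Bayes SD floor).
#' @return An `"eval_result"` with summed confusion counts and
#'   repeat-averaged metrics; attribute `"per_repeat"` holds the
#'   per-repeat metric rows.
#' @export
evaluate_classifier <- function(features, labels,
                                model = c("knn1", "svm_poly", "svm_rbf",
                                          "naive_bayes"),
                                repeats = 10L, train_frac = 0.9, seed = 1L,
                                degree = 3L, cost = 1, nb_sd_floor = 0.05) {
  model <- match.arg(model)
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (!(train_frac > 0 && train_frac < 1))
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop("need >= 2 examples of each class", call. = FALSE)

  per <- matrix(NA_real_, repeats, 4,
                dimnames = list(NULL, c("sensitivity", "specificity",
                                        "accuracy",
                                        "misclassification_error")))
  counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (r in seq_len(repeats)) {
    split <- with_seed(seed + r - 1L, stratified_split(labels, train_frac))
    pred <- with_seed(seed + r - 1L,
                      fit_predict(model, features[split$train, , drop = FALSE],
                                  labels[split$train],
                                  features[split$test, , drop = FALSE],
                                  degree = degree, cost = cost,
                                  nb_sd_floor = nb_sd_floor))
    truth <- labels[split$test]
    cm <- confusion_metrics(tp = sum(pred & truth), fp = sum(pred & !truth),
                            tn = sum(!pred & !truth), fn = sum(!pred & truth))
    counts <- counts + c(cm$tp, cm$fp, cm$tn, cm$fn)
    per[r, ] <- c(cm$sensitivity, cm$specificity, cm$accuracy,
                  cm$misclassification_error)
  }
  out <- confusion_metrics(counts["tp"], counts["fp"], counts["tn"],
                           counts["fn"])
  for (m in colnames(per)) out[[m]] <- mean(per[, m], na.rm = TRUE)
  attr(out, "per_repeat") <- per
  attr(out, "model") <- model
  out
}

stratified_split <- function(labels, train_frac) {
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(length(idx) * train_frac))
    n_tr <- min(n_tr, length(idx) - 1L)   # keep at least one test row
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train), test = setdiff(seq_along(labels), train))
}

fit_predict <- function(model, xtr, ytr, xte, degree, cost, nb_sd_floor) {
  mu <- colMeans(xtr)
  s <- apply(xtr, 2, sd)
  s[s == 0 | is.na(s)] <- 1
  ztr <- sweep(sweep(xtr, 2, mu), 2, s, "/")
  zte <- sweep(sweep(xte, 2, mu), 2, s, "/")
  ytr_f <- factor(ytr, levels = c(FALSE, TRUE))
  pred <- switch(model,
    knn1 = class::knn(ztr, zte, ytr_f, k = 1),
    svm_poly = predict(e1071::svm(ztr, ytr_f, kernel = "polynomial",
                                  degree = degree, coef0 = 1, cost = cost,
                                  scale = FALSE), zte),
    svm_rbf = predict(e1071::svm(ztr, ytr_f, kernel = "radial",
                                 gamma = 1 / ncol(ztr), cost = cost,
                                 scale = FALSE), zte),
    naive_bayes = {
      fit <- e1071::naiveBayes(ztr, ytr_f)
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], nb_sd_floor)
        tb
      })
      predict(fit, zte)
    })
  as.logical(pred == "TRUE")
}

#' Evaluate all four classifiers
#'
#' Convenience wrapper running [evaluate_classifier()] for each of the
#' four models on the same data and seed.
#'
#' @inheritParams evaluate_classifier
#' @param models Character vector of model tags.
#' @return Named list of `"eval_result"` objects; `print()` renders a
#'   metrics-by-model table.
#' @export
evaluate_all_classifiers <- function(features, labels, repeats = 10L,
                                     train_frac = 0.9, seed = 1L,
                                     models = c("knn1", "svm_poly",
                                                "svm_rbf", "naive_bayes")) {
  res <- lapply(models, function(m)
    evaluate_classifier(features, labels, model = m, repeats = repeats,
                        train_frac = train_frac, seed = seed))
  names(res) <- models
  class(res) <- "eval_result_set"
  res
}

#' @export
print.eval_result_set <- function(x, ...) {
  metrics <- c("misclassification_error", "accuracy", "specificity",
               "sensitivity")
  m <- sapply(x, function(r) unlist(r[metrics]))
  rownames(m) <- c("Misclassification error", "Accuracy", "Specificity",
                   "Sensitivity")
  print(round(m, 4))
  invisible(x)
}

## evaluate an expression under a local RNG seed, restoring the
## caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
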