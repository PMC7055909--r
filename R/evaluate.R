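#' One-vs-rest AUC by the rank statistic
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney rank
#' sum of the positive-class scores; ties contribute 1/2.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param positive Logical vector marking the positive class.
#' @return AUC in [0, 1]; `NA` if either class is empty.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class TPR, FPR and AUC
#'
#' One-vs-rest reduction: for each class, TPR = TP/(TP+FN) and
#' FPR = FP/(FP+TN) from the confusion counts, and AUC from the per-sample
#' class scores by the rank statistic.
#'
#' @param confusion_counts Square count matrix, true classes in rows.
#' @param scores Optional per-sample score matrix (columns named by class).
#' @param truth Optional per-sample true classes (required with `scores`).
#' @return Data frame with one row per class: `class`, `TPR`, `FPR`, `AUC`.
#' @examples
#' per_type_metrics(rbind(c(8, 2), c(3, 7)))
#' @export
per_type_metrics <- function(confusion_counts, scores = NULL, truth = NULL) {
  cm <- as.matrix(confusion_counts)
  stopifnot(nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  total <- sum(cm)
  out <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn == 0)
      return(data.frame(class = classes[i], TPR = NA_real_, FPR = NA_real_,
                        AUC = NA_real_, stringsAsFactors = FALSE))
    auc <- if (!is.null(scores) && !is.null(truth))
      auc_rank(scores[, classes[i]], truth == classes[i])
    else NA_real_
    data.frame(class = classes[i], TPR = tp / (tp + fn),
               FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
               AUC = auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Pooled held-out predictions -> one evaluation entry.
.evaluate_predictions <- function(truth, pred, scores, kind,
                                  accuracy_repeats = NULL) {
  lev <- levels(truth)
  counts <- table(truth = truth, pred = factor(pred, lev))
  counts <- matrix(as.numeric(counts), length(lev), length(lev),
                   dimnames = list(lev, lev))
  confusion <- counts / pmax(rowSums(counts), 1)
  ptm <- per_type_metrics(counts, scores, truth)
  structure(
    list(classifier = kind,
         accuracy = mean(pred == truth),
         accuracy_repeats = accuracy_repeats,
         per_class_accuracy = stats::setNames(diag(confusion), lev),
         counts = counts,
         confusion = confusion,
         metrics = ptm,
         n = length(truth),
         n_correct = sum(pred == truth),
         predictions = data.frame(truth = truth, pred = pred,
                                  stringsAsFactors = FALSE),
         scores = scores),
    class = "vt_eval")
}

#' @export
print.vt_eval <- function(x, digits = 3, ...) {
  cat(sprintf("Classifier evaluation [%s]: accuracy %.1f%% (n = %d)\n",
              toupper(x$classifier), 100 * x$accuracy, x$n))
  cat("Row-normalized confusion matrix:\n")
  print(round(x$confusion, digits))
  print(x$metrics, digits = digits)
  invisible(x)
}

# Stratified fold assignment: within each class, folds are cycled over a
# random permutation.
.stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    if (length(idx) < folds)
      stop("class '", lv, "' has fewer samples than folds", call. = FALSE)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

.feature_matrix <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- intersect(c("H1", "H2", "H3", "H4", "SE", "Jr", "Sr",
                                setdiff(names(features),
                                        c("sample_id", "label", "f0_hz"))),
                              names(features))
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold cross-validation: within each fold the features are
#' z-scored using training-fold statistics, the classifier is fitted on the
#' training folds and the held-out fold is predicted; predictions pooled
#' over all folds yield the confusion matrix, overall and per-type
#' accuracy, and per-type TPR/FPR/AUC.
#'
#' @param features Data frame with feature columns and a `label` column.
#' @param spec A [classifier_spec()] (or a kind string).
#' @param folds Number of folds (default 5).
#' @param seed Integer seed governing the fold assignment and any
#'   classifier randomness.
#' @param feature_cols Feature columns to use (default: the seven standard
#'   features present).
#' @return A `vt_eval` object.
#' @examples
#' feats <- simulate_feature_cohort(30, seed = 1)
#' train_eval_cv(feats, "ld", seed = 1)
#' @export
train_eval_cv <- function(features, spec, folds = 5, seed = 1,
                          feature_cols = NULL) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  x <- .feature_matrix(features, feature_cols)
  y <- droplevels(as.factor(features$label))
  set.seed(seed)
  fold_id <- .stratified_folds(y, folds)

  pred <- factor(rep(NA_character_, length(y)), levels(y))
  scores <- matrix(NA_real_, length(y), nlevels(y),
                   dimnames = list(NULL, levels(y)))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (nlevels(droplevels(y[tr])) < nlevels(y))
      stop("a class is absent from a training fold", call. = FALSE)
    std <- .standardizer(x[tr, , drop = FALSE])
    model <- .fit_vt(spec, std(x[tr, , drop = FALSE]), y[tr])
    p <- .predict_vt(model, std(x[!tr, , drop = FALSE]))
    pred[!tr] <- p$class
    scores[!tr, ] <- p$scores
  }
  .evaluate_predictions(y, pred, scores, spec$kind)
}

#' Train and evaluate a neural network with repeated random splits
#'
#' The network is evaluated by repeated stratified 70/15/15
#' train/validation/test splits: per repeat the network is trained with
#' early stopping on the validation cross-entropy and scored on the test
#' set.  The reported accuracy is the mean over repeats; test-set
#' predictions pooled across repeats give the confusion matrix and
#' per-type metrics.  A repeat whose training fails to produce finite
#' weights is re-seeded once before erroring.
#'
#' @param features Data frame with feature columns and a `label` column.
#' @param spec A [classifier_spec()] of kind `"nn"`.
#' @param repeats Number of randomized splits (default 6).
#' @param split Train/validation/test proportions (default
#'   `c(0.70, 0.15, 0.15)`).
#' @param seed Master seed.
#' @param feature_cols Feature columns to use.
#' @return A `vt_eval` object; `accuracy` is the mean over repeats and
#'   `accuracy_repeats` holds the per-repeat values.
#' @export
train_eval_nn <- function(features, spec = classifier_spec("nn"),
                          repeats = 6, split = c(0.70, 0.15, 0.15),
                          seed = 1, feature_cols = NULL) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(spec$kind == "nn", abs(sum(split) - 1) < 1e-9)
  x <- .feature_matrix(features, feature_cols)
  y <- droplevels(as.factor(features$label))
  if (any(table(y) < 20))
    stop("need at least 20 samples per class for the 70/15/15 design",
         call. = FALSE)

  acc <- numeric(repeats)
  truth_all <- pred_all <- NULL
  scores_all <- NULL
  set.seed(seed)
  for (rep_i in seq_len(repeats)) {
    parts <- .stratified_split3(y, split)
    run_once <- function() {
      std <- .standardizer(x[parts == 1L, , drop = FALSE])
      model <- .fit_nn(spec, std(x[parts == 1L, , drop = FALSE]),
                       y[parts == 1L],
                       x_val = std(x[parts == 2L, , drop = FALSE]),
                       y_val = y[parts == 2L])
      list(model = model, std = std)
    }
    fit <- tryCatch(run_once(), error = function(e) {
      set.seed(seed + 1000L + rep_i)   # one re-seeded retry per repeat
      run_once()
    })
    p <- .predict_vt(fit$model, fit$std(x[parts == 3L, , drop = FALSE]))
    truth_i <- y[parts == 3L]
    acc[rep_i] <- mean(p$class == truth_i)
    truth_all <- c(truth_all, as.character(truth_i))
    pred_all <- c(pred_all, as.character(p$class))
    scores_all <- rbind(scores_all, p$scores)
  }
  out <- .evaluate_predictions(factor(truth_all, levels(y)),
                               factor(pred_all, levels(y)),
                               scores_all, "nn", accuracy_repeats = acc)
  out$accuracy <- mean(acc)    # headline figure: mean over repeats
  out
}

# Stratified assignment into 3 parts with given proportions.
.stratified_split3 <- function(y, split) {
  part <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    n <- length(idx)
    n1 <- round(split[1] * n)
    n2 <- round(split[2] * n)
    part[idx[seq_len(n1)]] <- 1L
    part[idx[n1 + seq_len(n2)]] <- 2L
    part[idx[(n1 + n2 + 1):n]] <- 3L
  }
  part
}

#' Chi-square comparison of classification accuracies
#'
#' Pearson chi-square test of independence on the (group x
#' correct/incorrect) contingency table built from each evaluation's
#' pooled held-out predictions.  Cells with expected counts below 1 are
#' flagged.
#'
#' @param evals Named list of `vt_eval` objects (groups to compare).
#' @param alpha Significance level reported alongside (default 0.05).
#' @return List with the contingency `table`, `statistic`, `df`,
#'   `p_value`, `alpha`, `significant`, and `low_expected` flag.
#' @export
chi_square_compare <- function(evals, alpha = 0.05) {
  stopifnot(length(evals) >= 2)
  tab <- t(vapply(evals, function(e)
    c(correct = e$n_correct, incorrect = e$n - e$n_correct), c(0, 0)))
  if (is.null(rownames(tab)))
    rownames(tab) <- vapply(evals, `[[`, "", "classifier")
  if (any(colSums(tab) == 0))   # e.g. every group fully correct: no signal
    return(list(table = tab, statistic = 0, df = nrow(tab) - 1, p_value = 1,
                alpha = alpha, significant = FALSE, low_expected = TRUE))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab,
       statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = ht$p.value,
       alpha = alpha,
       significant = is.finite(ht$p.value) && ht$p.value < alpha,
       low_expected = any(ht$expected < 1))
}
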