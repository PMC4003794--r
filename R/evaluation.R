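# Evaluation: 2x2 confusion matrix against the angiographic ground truth,
# the standard derived metrics (with both per-class metric families), and
# stratified k-fold cross-validation.

#' Confusion matrix for binary classification
#'
#' Tallies predictions against true labels. Unclassified predictions (`NA`)
#' count as errors against the true class: a false negative when the true
#' class is the positive one, a false positive otherwise.
#'
#' @param truth True class labels.
#' @param predicted Predicted labels (`NA` = unclassified).
#' @param positive The label treated as positive (e.g. `"patient"`).
#' @return An object of class `confusion_matrix` with counts `tp`, `tn`,
#'   `fp`, `fn` and the class names.
#' @export
confusion <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  classes <- sort(unique(truth))
  if (!positive %in% classes) stop("unknown positive class: ", positive)
  if (length(classes) > 2L) stop("confusion() handles binary problems")
  negative <- setdiff(classes, positive)
  if (length(negative) == 0L) negative <- paste0("not_", positive)
  known <- is.na(predicted) | predicted %in% c(positive, negative)
  if (!all(known)) stop("unknown predicted label(s): ",
                        paste(unique(predicted[!known]), collapse = ", "))
  is_pos <- truth == positive
  pred_pos <- !is.na(predicted) & predicted == positive
  pred_neg <- !is.na(predicted) & predicted == negative
  structure(list(
    tp = sum(is_pos & pred_pos),
    fn = sum(is_pos & !pred_pos),          # includes unclassified positives
    fp = sum(!is_pos & pred_pos) + sum(!is_pos & is.na(predicted)),
    tn = sum(!is_pos & pred_neg),
    positive = positive, negative = negative
  ), class = "confusion_matrix")
}

#' Build a confusion matrix from its four counts
#'
#' @param tp,fn,fp,tn Nonnegative integer counts.
#' @param positive,negative Class names.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fn, fp, tn, positive = "patient",
                             negative = "healthy") {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 positive = positive, negative = negative),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  # rows = classifier result, columns = actual (angiography) result
  tab <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
                dimnames = list(
                  classifier = c(x$negative, x$positive),
                  actual = c(x$negative, x$positive)))
  print(tab)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity (= positive-class recall), specificity,
#' precision and F-measure with the positive class as reference, plus the
#' full per-class precision/recall/F table for both classes. Any ratio with a
#' zero denominator is returned as `NA` rather than raising an error.
#'
#' @param cm A `confusion_matrix`.
#' @return A list of class `metric_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f_measure`, `total` and
#'   `per_class` (data frame with one row per class).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop("empty confusion matrix")
  prec_pos <- ratio(cm$tp, cm$tp + cm$fp)
  rec_pos <- ratio(cm$tp, cm$tp + cm$fn)
  prec_neg <- ratio(cm$tn, cm$tn + cm$fn)
  rec_neg <- ratio(cm$tn, cm$tn + cm$fp)
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
  }
  per_class <- data.frame(
    class = c(cm$positive, cm$negative),
    precision = c(prec_pos, prec_neg),
    recall = c(rec_pos, rec_neg),
    f_measure = c(f1(prec_pos, rec_pos), f1(prec_neg, rec_neg)),
    stringsAsFactors = FALSE
  )
  structure(list(
    accuracy = (cm$tp + cm$tn) / total,
    sensitivity = rec_pos,
    specificity = rec_neg,
    precision = prec_pos,
    f_measure = f1(prec_pos, rec_pos),
    total = total,
    per_class = per_class
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f%%", 100 * v))
  cat(sprintf("accuracy %s  sensitivity %s  specificity %s  precision %s  F %s  (n = %d)\n",
              pct(x$accuracy), pct(x$sensitivity), pct(x$specificity),
              pct(x$precision), pct(x$f_measure), x$total))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %s: precision %s  recall %s  F %s\n", pc$class[i],
                pct(pc$precision[i]), pct(pc$recall[i]), pct(pc$f_measure[i])))
  }
  invisible(x)
}

# stratified fold assignment: within each class, shuffle and deal round-robin
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop(sprintf("class %s has %d members; need at least k = %d for stratified folds",
                   cl, length(idx), k))
    }
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation
#'
#' Randomly partitions the instances into `k` stratified folds (class
#' proportions preserved, fold sizes differing by at most one per class),
#' trains on each k-1 fold union and evaluates on the held-out fold. When
#' `scale = TRUE` the min-max scaling schema is fitted on the training folds
#' only and applied to the held-out fold (values outside the training range
#' are clipped to \eqn{[0,1]}).
#'
#' @param X Predictor matrix (raw, or already in \eqn{[0,1]} with
#'   `scale = FALSE`).
#' @param labels Class labels.
#' @param cfg A [train_config()].
#' @param k Number of folds (default 10).
#' @param positive Positive class for the metric report.
#' @param scale Fit per-fold min-max scaling on the training folds.
#' @param seed Optional integer seed (fold assignment and training).
#' @return A list of class `cv_result` with `folds` (per-fold data frame:
#'   metrics, rule count, mean rule length), `pooled` (confusion matrix over
#'   all held-out predictions), `pooled_metrics`, and `mean` (column means of
#'   the per-fold metrics).
#' @export
cross_validate <- function(X, labels, cfg = train_config(), k = 10L,
                           positive = NULL, scale = TRUE, seed = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(k >= 2L, nrow(X) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  classes <- sort(unique(labels))
  if (is.null(positive)) {
    positive <- if ("patient" %in% classes) "patient" else classes[1]
  }
  folds <- stratified_folds(labels, k)
  rows <- vector("list", k)
  pooled_truth <- character(0)
  pooled_pred <- character(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    if (scale) {
      schema <- attribute_schema(Xtr)
      Xtr <- scale_attributes(Xtr, schema)
      Xte <- scale_attributes(Xte, schema)
    }
    rs <- train(weighted_dataset(Xtr, labels[tr]), cfg)
    pred <- predict(rs, Xte)
    cm <- confusion(labels[!tr], pred, positive)
    mt <- metrics(cm)
    st <- ruleset_stats(rs)
    rows[[f]] <- data.frame(fold = f, n = sum(!tr),
                            accuracy = mt$accuracy,
                            sensitivity = mt$sensitivity,
                            specificity = mt$specificity,
                            precision = mt$precision,
                            f_measure = mt$f_measure,
                            n_rules = st$count,
                            mean_rule_length = st$mean_length)
    pooled_truth <- c(pooled_truth, labels[!tr])
    pooled_pred <- c(pooled_pred, pred)
  }
  per_fold <- do.call(rbind, rows)
  pooled <- confusion(pooled_truth, pooled_pred, positive)
  structure(list(folds = per_fold, pooled = pooled,
                 pooled_metrics = metrics(pooled),
                 mean = colMeans(per_fold[, -(1:2)], na.rm = TRUE),
                 positive = positive),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (positive class: %s)\n",
              nrow(x$folds), x$positive))
  cat("pooled: "); print(x$pooled_metrics)
  cat(sprintf("mean rules per fold: %.1f, mean rule length: %.2f\n",
              x$mean[["n_rules"]], x$mean[["mean_rule_length"]]))
  invisible(x)
}

#' Write a cross-validation report as tab-separated text
#'
#' One row per fold plus a final `mean` row; columns include the five
#' metrics, rule count and mean rule length.
#'
#' @param cv A `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  tab <- cv$folds
  mean_row <- tab[1, ]
  mean_row$fold <- NA
  mean_row$n <- sum(tab$n)
  for (col in names(cv$mean)) mean_row[[col]] <- cv$mean[[col]]
  out <- rbind(cbind(row = paste0("fold", tab$fold), tab),
               cbind(row = "mean", mean_row))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
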