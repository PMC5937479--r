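#' Confusion matrix over classified sounds
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param classes Class label universe (rows = true, columns = predicted).
#' @return Integer `A x A` matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels, classes) {
  t_ <- as.character(true_labels); p_ <- as.character(predicted_labels)
  if (length(t_) != length(p_)) stop("confusion: length mismatch")
  if (!all(c(t_, p_) %in% classes))
    stop("confusion: label outside the declared class set")
  cm <- table(factor(t_, levels = classes), factor(p_, levels = classes))
  structure(unclass(as.matrix(cm)), class = "confusion_matrix")
}

.metric_names <- c("ACC", "PRC", "SNS", "SPC", "F1", "GM", "AUC")

#' One-vs-rest metrics for a positive class
#'
#' Collapses the confusion matrix one-vs-rest and computes accuracy,
#' precision, sensitivity, specificity, F1, the geometric mean of
#' sensitivity and specificity, and the single-point AUC
#' `(SNS + SPC) / 2` (the area under the ROC when only one operating point
#' exists). Metrics with a zero denominator are reported as 0 with a
#' warning.
#'
#' @param cm A `confusion_matrix`.
#' @param positive_class The class treated as positive.
#' @return Named numeric vector `(ACC, PRC, SNS, SPC, F1, GM, AUC)` in
#'   `[0, 1]`.
#' @export
one_vs_rest_metrics <- function(cm, positive_class) {
  classes <- rownames(cm)
  if (!(positive_class %in% classes))
    stop("one_vs_rest_metrics: unknown class ", positive_class)
  i <- match(positive_class, classes)
  tp <- cm[i, i]
  fn <- sum(cm[i, -i])
  fp <- sum(cm[-i, i])
  tn <- sum(cm[-i, -i])
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("one_vs_rest_metrics: zero denominator for ", what,
              " (reported as 0)", call. = FALSE)
      return(0)
    }
    num / den
  }
  acc <- safe_div(tp + tn, tp + tn + fp + fn, "ACC")
  prc <- safe_div(tp, tp + fp, "PRC")
  sns <- safe_div(tp, tp + fn, "SNS")
  spc <- safe_div(tn, tn + fp, "SPC")
  f1 <- if (prc + sns == 0) 0 else 2 * prc * sns / (prc + sns)
  gm <- sqrt(sns * spc)
  auc <- (sns + spc) / 2
  stats::setNames(c(acc, prc, sns, spc, f1, gm, auc), .metric_names)
}

#' Per-class and macro-averaged metrics of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return List with `per_class` (class x metric matrix) and `macro`
#'   (unweighted mean over classes).
#' @export
metrics_table <- function(cm) {
  classes <- rownames(cm)
  per <- t(vapply(classes, function(k)
    suppressWarnings(one_vs_rest_metrics(cm, k)), numeric(7)))
  list(per_class = per, macro = macro_average(per))
}

#' Macro-average per-class metric vectors
#'
#' Unweighted arithmetic mean of each metric over classes.
#'
#' @param per_class_metrics Matrix (class x metric) or list of named metric
#'   vectors.
#' @return Named metric vector.
#' @export
macro_average <- function(per_class_metrics) {
  m <- if (is.list(per_class_metrics)) do.call(rbind, per_class_metrics) else
    per_class_metrics
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(per_class_metrics)))
  colMeans(m)
}

#' Assign sounds to train / validation / test splits
#'
#' `instance_selection` uses the manifest's `is_pattern` flag: pattern
#' sounds train; the rest split ~50/50 into validation and test by a seeded
#' shuffle stratified by class. `cv4` assigns four seeded stratified folds
#' (column `fold`).
#'
#' @param manifest Data frame with at least `class` and (for instance
#'   selection) logical `is_pattern`.
#' @param mode `"instance_selection"` or `"cv4"`.
#' @param seed Integer seed.
#' @return The manifest with an added `split` column (`train` /
#'   `validation` / `test`) or, for `cv4`, an integer `fold` column.
#' @export
split_dataset <- function(manifest, mode = c("instance_selection", "cv4"),
                          seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(manifest), "class" %in% names(manifest))
  set.seed(seed %% .Machine$integer.max)
  if (mode == "instance_selection") {
    if (!"is_pattern" %in% names(manifest))
      stop("split_dataset: instance selection needs an is_pattern column")
    if (!all(unique(manifest$class) %in% manifest$class[manifest$is_pattern]))
      stop("split_dataset: some class has no pattern (training) sound")
    split <- rep(NA_character_, nrow(manifest))
    split[manifest$is_pattern] <- "train"
    for (k in unique(manifest$class)) {
      rows <- which(!manifest$is_pattern & manifest$class == k)
      rows <- sample(rows)
      n_val <- floor(length(rows) / 2)
      split[rows[seq_len(n_val)]] <- "validation"
      if (n_val < length(rows)) split[rows[(n_val + 1):length(rows)]] <- "test"
    }
    manifest$split <- split
  } else {
    fold <- integer(nrow(manifest))
    for (k in unique(manifest$class)) {
      rows <- sample(which(manifest$class == k))
      fold[rows] <- rep_len(1:4, length(rows))
    }
    if (any(vapply(unique(manifest$class), function(k)
      length(unique(fold[manifest$class == k])), integer(1)) < 2))
      warning("split_dataset: a class occupies fewer than 2 folds")
    manifest$fold <- fold
  }
  manifest
}

#' Bootstrap confidence intervals of the macro metrics
#'
#' Resamples the classified test sounds with replacement (`n_boot` times),
#' recomputes the macro metric vector per resample, and reports percentile
#' confidence intervals at level `gamma` (the 2.5 / 97.5 percentiles for
#' the default 95%). Because the classifiers emit hard labels, resampling
#' the test set is equivalent to resampling its (true, predicted) pairs, so
#' the classifier runs once.
#'
#' @param true_labels,predicted_labels Labels of the classified test sounds.
#' @param classes Class universe.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param gamma Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Object of class `bootstrap_result`: `samples` (n_boot x 7 macro
#'   metric matrix), `point` (macro metrics of the full test set), `ci`
#'   (2 x 7 matrix of lower/upper bounds), `gamma`, `n_boot`.
#' @export
bootstrap_metrics <- function(true_labels, predicted_labels, classes,
                              n_boot = 1000, gamma = 0.95, seed = 1) {
  t_ <- as.character(true_labels); p_ <- as.character(predicted_labels)
  n <- length(t_)
  if (n < 2) stop("bootstrap_metrics: need >= 2 test sounds")
  set.seed(seed %% .Machine$integer.max)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  samples <- t(apply(idx, 2, function(i)
    metrics_table(confusion(t_[i], p_[i], classes))$macro))
  colnames(samples) <- .metric_names
  probs <- c((1 - gamma) / 2, 1 - (1 - gamma) / 2)
  ci <- apply(samples, 2, stats::quantile, probs = probs, names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(list(samples = samples,
                 point = metrics_table(confusion(t_, p_, classes))$macro,
                 ci = ci, gamma = gamma, n_boot = n_boot),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result: %d resamples, %.0f%% CI>\n",
              x$n_boot, 100 * x$gamma))
  out <- rbind(point = x$point, x$ci)
  print(round(out, 4))
  invisible(x)
}

#' Probability that one method outperforms another
#'
#' Paired bootstrap: the same resampled index sets are applied to both
#' methods' (true, predicted) pairs; for each metric the outperformance
#' probability is the fraction of resamples on which method 1's macro
#' metric strictly exceeds method 2's.
#'
#' @param true_labels True sound labels.
#' @param pred1,pred2 Predicted labels of the two methods on the same
#'   sounds.
#' @param classes Class universe.
#' @param n_boot Number of paired resamples.
#' @param seed Integer seed.
#' @return List with `o` (named outperformance probability per metric),
#'   `delta_mean` (mean paired difference) and `delta` (resample x metric
#'   difference matrix).
#' @export
prob_outperform <- function(true_labels, pred1, pred2, classes,
                            n_boot = 1000, seed = 1) {
  t_ <- as.character(true_labels)
  p1 <- as.character(pred1); p2 <- as.character(pred2)
  stopifnot(length(p1) == length(t_), length(p2) == length(t_))
  n <- length(t_)
  set.seed(seed %% .Machine$integer.max)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  delta <- t(apply(idx, 2, function(i)
    metrics_table(confusion(t_[i], p1[i], classes))$macro -
      metrics_table(confusion(t_[i], p2[i], classes))$macro))
  colnames(delta) <- .metric_names
  list(o = colMeans(delta > 0), delta_mean = colMeans(delta), delta = delta)
}
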