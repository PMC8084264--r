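#' Stratified cross-validation folds
#'
#' Partitions the instance indices of a case table into `k` disjoint folds.
#' With stratification (the default), each class's instances are shuffled
#' (seeded) and dealt round-robin across folds, so every class is spread as
#' evenly as integer arithmetic allows; classes with fewer than `k`
#' instances land in consecutive folds in shuffle order. Without
#' stratification all indices are shuffled and dealt round-robin. With 30
#' diagnoses among 100 cases, unstratified folds routinely lose whole
#' classes from the training complement, so stratification is the default.
#'
#' @param table a [case_table()].
#' @param k number of folds (>= 2, <= number of instances).
#' @param seed integer seed for the shuffles; `NULL` uses the current RNG.
#' @param stratified logical.
#' @return a list of `k` integer index vectors: disjoint, covering all
#'   instances.
#' @export
stratified_folds <- function(table, k = 10L, seed = NULL, stratified = TRUE) {
  n <- n_cases(table)
  k <- as.integer(k)
  if (k < 2L) stop("config error: k must be at least 2")
  if (k > n) stop("config error: k (", k, ") exceeds the instance count (", n, ")")
  with_seed(seed, {
    folds <- vector("list", k)
    assign_rr <- function(idx, start) {
      for (j in seq_along(idx)) {
        f <- ((start + j - 2L) %% k) + 1L
        folds[[f]] <<- c(folds[[f]], idx[j])
      }
      start + length(idx)
    }
    if (stratified) {
      cls <- table$data[[table$class_attribute]]
      ptr <- 1L
      for (lv in levels(cls)) {
        idx <- which(cls == lv)
        if (length(idx) > 1L) idx <- sample(idx)
        ptr <- assign_rr(idx, ptr)
      }
    } else {
      assign_rr(sample(seq_len(n)), 1L)
    }
    lapply(folds, sort)
  })
}

#' Cross-validate a tree on a case table
#'
#' Runs k-fold cross-validation: for each fold, a tree is induced on the
#' complement and the held-out fold is classified; predictions are pooled
#' over folds into one confusion matrix from which overall accuracy and
#' Cohen's kappa are computed (kappa on the pooled matrix, not averaged per
#' fold, matching the usual Weka reporting). Per-fold accuracies are also
#' reported. If a training complement lacks some class entirely the run
#' proceeds -- that class can only be predicted wrongly -- and the report
#' records a warning.
#'
#' @param table a [case_table()].
#' @param control a [c45_control()].
#' @param k number of folds (default 10).
#' @param seed seed for fold assignment.
#' @param stratified stratify folds by diagnosis (default `TRUE`).
#' @return an `evaluation_report`: `fold_accuracies`, `overall_accuracy`,
#'   `kappa`, `confusion`, `params_used`, `warnings`.
#' @export
cross_validate <- function(table, control = c45_control(), k = 10L,
                           seed = NULL, stratified = TRUE) {
  folds <- stratified_folds(table, k = k, seed = seed, stratified = stratified)
  cls <- table$data[[table$class_attribute]]
  lv <- levels(cls)
  truth_all <- character(); pred_all <- character()
  fold_acc <- numeric(length(folds))
  warns <- character()
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n_cases(table)), test_idx)
    train_tab <- subset_table(table, train_idx)
    missing_cls <- lv[!(lv %in% unique(as.character(cls[train_idx])))]
    if (length(missing_cls)) {
      warns <- c(warns, paste0("fold ", f, ": class(es) absent from training: ",
                               paste(missing_cls, collapse = ", ")))
    }
    fit <- c45(train_tab, control = control)
    pred <- as.character(predict(fit, subset_table(table, test_idx)))
    truth <- as.character(cls[test_idx])
    fold_acc[f] <- mean(pred == truth)
    truth_all <- c(truth_all, truth)
    pred_all <- c(pred_all, pred)
  }
  cm <- confusion_matrix(truth_all, pred_all, labels = lv)
  structure(
    list(fold_accuracies = fold_acc,
         overall_accuracy = sum(diag(cm)) / sum(cm),
         kappa = cohen_kappa(cm),
         confusion = cm,
         params_used = list(induction = control,
                            k_folds = length(folds), seed = seed,
                            stratified = stratified),
         warnings = warns),
    class = "evaluation_report"
  )
}

#' Evaluate a tree on a held-out split
#'
#' Stratified train/test split (default 80/20): the tree is induced on the
#' training portion and scored on the holdout.
#'
#' @param table a [case_table()].
#' @param control a [c45_control()].
#' @param train_fraction fraction of instances used for training.
#' @param seed seed for the split.
#' @return an `evaluation_report` with a single entry in `fold_accuracies`.
#' @export
holdout_evaluate <- function(table, control = c45_control(),
                             train_fraction = 0.8, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- n_cases(table)
  cls <- table$data[[table$class_attribute]]
  test_idx <- with_seed(seed, {
    idx <- integer()
    for (lv in levels(cls)) {
      members <- which(cls == lv)
      n_test <- round(length(members) * (1 - train_fraction))
      if (n_test > 0L && length(members) > 1L) {
        idx <- c(idx, sample(members, n_test))
      }
    }
    sort(idx)
  })
  if (length(test_idx) == 0L || length(test_idx) == n) {
    stop("config error: degenerate holdout split")
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  fit <- c45(subset_table(table, train_idx), control = control)
  pred <- as.character(predict(fit, subset_table(table, test_idx)))
  truth <- as.character(cls[test_idx])
  cm <- confusion_matrix(truth, pred, labels = levels(cls))
  missing_cls <- levels(cls)[!(levels(cls) %in%
                                 unique(as.character(cls[train_idx])))]
  structure(
    list(fold_accuracies = mean(pred == truth),
         overall_accuracy = sum(diag(cm)) / sum(cm),
         kappa = cohen_kappa(cm),
         confusion = cm,
         params_used = list(induction = control,
                            train_fraction = train_fraction, seed = seed),
         warnings = if (length(missing_cls))
           paste0("class(es) absent from training: ",
                  paste(missing_cls, collapse = ", ")) else character()),
    class = "evaluation_report"
  )
}

subset_table <- function(table, idx) {
  out <- table
  out$data <- table$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Confusion matrix
#'
#' `counts[i, j]` = number of cases whose true class is `i` and predicted
#' class is `j`. Rows index truth, columns prediction, both over the full
#' label set.
#'
#' @param truth,predicted equal-length class label vectors.
#' @param labels label set fixing row/column order; default: sorted union of
#'   observed labels.
#' @return a square integer matrix.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length")
  }
  labels <- labels %||% sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad)) stop("labels outside the class domain: ",
                        paste(bad, collapse = ", "))
  tab <- table(factor(truth, levels = labels),
               factor(predicted, levels = labels))
  m <- matrix(as.integer(tab), nrow = length(labels),
              dimnames = list(truth = labels, predicted = labels))
  m
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` on a
#' confusion matrix, with observed agreement `p_o = trace/total` and chance
#' agreement `p_e = sum_i row_i * col_i / total^2`. When `p_e = 1` (a
#' degenerate one-class matrix) kappa is defined as 1 if agreement is also
#' perfect and 0 otherwise.
#'
#' @param confusion a square count matrix with positive total, as from
#'   [confusion_matrix()].
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (length(m) == 0L || nrow(m) != ncol(m)) {
    stop("`confusion` must be a non-empty square matrix")
  }
  total <- sum(m)
  if (total <= 0) stop("`confusion` must have a positive total")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - pe) < 1e-12) return(if (abs(po - 1) < 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  overall accuracy: %.2f%%\n", 100 * x$overall_accuracy))
  cat(sprintf("  Cohen's kappa:    %.4f\n", x$kappa))
  if (length(x$fold_accuracies) > 1L) {
    cat("  per-fold accuracy:\n")
    for (i in seq_along(x$fold_accuracies)) {
      cat(sprintf("    fold %2d: %.2f%%\n", i, 100 * x$fold_accuracies[i]))
    }
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    -", w, "\n")
  }
  invisible(x)
}

#' Export an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @return a JSON string.
#' @export
evaluation_report_json <- function(report) {
  out <- list(
    fold_accuracies = report$fold_accuracies,
    overall_accuracy = report$overall_accuracy,
    kappa = report$kappa,
    confusion = list(labels = rownames(report$confusion),
                     counts = unname(apply(report$confusion, 1L, as.list,
                                           simplify = FALSE))),
    warnings = report$warnings
  )
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}
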