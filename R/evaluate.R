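#' Partition samples into k cross-validation folds
#'
#' Stratified by default: each class's samples are dealt across folds so
#' every fold keeps close-to-proportional class composition (with very
#' unbalanced classes — such as a 17-sample class against k up to 9 —
#' unstratified folds can miss a class entirely). Remainder samples go to the
#' currently smallest folds, so fold sizes never differ by more than one.
#'
#' @param sample_ids sample identifiers.
#' @param labels class label per sample.
#' @param k number of folds (`k <=` number of samples).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param stratified logical (default `TRUE`).
#' @return list of k integer vectors of sample indices (the test folds),
#'   disjoint with union all samples.
#' @export
kfold_partition <- function(sample_ids, labels, k, seed = 1L,
                            stratified = TRUE) {
  n <- length(sample_ids)
  if (k > n) stop_fmt("k = %d exceeds the number of samples (%d)", k, n)
  labels <- as.character(labels)
  with_seed(seed, {
    folds <- vector("list", k)
    sizes <- integer(k)
    assign_round <- function(idx) {
      # deal idx one at a time to the currently smallest fold (ties: lowest
      # fold index), keeping overall sizes within one of each other
      for (i in idx) {
        f <- which.min(sizes)
        folds[[f]] <<- c(folds[[f]], i)
        sizes[[f]] <<- sizes[[f]] + 1L
      }
    }
    if (stratified) {
      small <- names(which(table(labels) < k))
      if (length(small))
        warning(sprintf(
          "class(es) smaller than k (%s): those samples are spread at random",
          paste(small, collapse = ", ")), call. = FALSE)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        assign_round(idx[sample.int(length(idx))])
      }
    } else {
      assign_round(sample.int(n))
    }
    folds
  })
}

#' Repeated k-fold cross-validation of the network classifier
#'
#' For every combination of `k` in `k_values` and seed in `1..n_seeds`
#' (offset by `seed_base`), the samples are partitioned into k folds; each
#' fold is held out once while the classifier is fitted on the remaining
#' folds and used to predict the held-out samples, so training never sees
#' test samples. Per-run accuracy is the pooled fraction of correct
#' predictions over the run's k test folds. Run accuracies are averaged with
#' equal weight.
#'
#' @param disc a `"discretized_matrix"`.
#' @param subset character vector of gene ids to use (non-empty).
#' @param k_values fold counts (default `5:9`).
#' @param n_seeds repeats per k (default 50).
#' @param max_parents,smoothing classifier configuration; `max_parents > 0`
#'   runs the AIC structure search inside every training fold.
#' @param stratified passed to [kfold_partition()].
#' @param seed_base offset added to the repeat index to form the fold seed.
#' @param x optional [expression_matrix] enabling the strict leakage-safe
#'   mode: when given, the mixture discretization of the subset genes is
#'   refitted on each training fold alone and its boundaries applied to the
#'   held-out samples, instead of reusing the full-data discretization in
#'   `disc`.
#' @param k_candidates mixture candidates for the strict refits.
#' @return an object of class `"cv_report"`: data frame `runs` (k, seed,
#'   accuracy), `mean_accuracy`, `sd_accuracy`, pooled `confusion` matrix,
#'   and per-class `sensitivity` / `specificity`.
#' @export
cross_validate <- function(disc, subset, k_values = 5:9, n_seeds = 50L,
                           max_parents = 0L, smoothing = 0.5,
                           stratified = TRUE, seed_base = 0L, x = NULL,
                           k_candidates = 1:4) {
  stopifnot(inherits(disc, "discretized_matrix"))
  if (!length(subset)) stop_fmt("empty gene subset")
  if (!is.null(x)) stopifnot(inherits(x, "expression_matrix"))
  n_class <- length(disc$class_set)
  conf <- matrix(0L, n_class, n_class,
                 dimnames = list(true = disc$class_set,
                                 predicted = disc$class_set))
  runs <- vector("list", length(k_values) * n_seeds)
  r <- 0L
  truth <- as.character(disc$labels)
  for (k in k_values) {
    for (s in seq_len(n_seeds)) {
      folds <- kfold_partition(disc$sample_ids, disc$labels, k,
                               seed = seed_base + s, stratified = stratified)
      pred <- character(length(truth))
      for (fold in folds) {
        tr_idx <- setdiff(seq_along(truth), fold)
        if (is.null(x)) {
          train <- subset_samples(disc, tr_idx)
          test_codes <- disc$codes[subset, fold, drop = FALSE]
        } else {
          # strict mode: refit discretization on the training fold only
          xtr <- expression_matrix(
            x$values[subset, tr_idx, drop = FALSE],
            labels = as.character(x$labels[tr_idx]),
            class_set = x$class_set)
          train <- discretize_matrix(xtr, k_candidates = k_candidates)
          test_codes <- do.call(rbind, lapply(subset, function(g)
            apply_boundaries(x$values[g, fold],
                             train$boundaries_per_gene[[g]])))
          dimnames(test_codes) <- list(subset, x$sample_ids[fold])
        }
        fit <- if (max_parents > 0L) {
          learn_structure(train, genes = subset, max_parents = max_parents,
                          smoothing = smoothing)
        } else {
          bayesnet_fit(train, genes = subset, smoothing = smoothing,
                       arity = train$ranges_per_gene[subset])
        }
        pred[fold] <- predict(fit, test_codes)$class
      }
      conf <- conf + confusion_matrix(truth, pred, disc$class_set)
      r <- r + 1L
      runs[[r]] <- data.frame(k = k, seed = seed_base + s,
                              accuracy = mean(pred == truth))
    }
  }
  runs <- do.call(rbind, runs)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  tn <- sum(conf) - tp - fn - fp
  structure(list(runs = runs,
                 mean_accuracy = mean(runs$accuracy),
                 sd_accuracy = stats::sd(runs$accuracy),
                 confusion = conf,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp)),
            class = "cv_report")
}

# restrict a discretized matrix to a set of sample indices; arities and
# boundaries are kept from the full fit so codes stay comparable
subset_samples <- function(disc, idx) {
  structure(list(codes = disc$codes[, idx, drop = FALSE],
                 gene_ids = disc$gene_ids,
                 sample_ids = disc$sample_ids[idx],
                 labels = disc$labels[idx],
                 class_set = disc$class_set,
                 ranges_per_gene = disc$ranges_per_gene,
                 boundaries_per_gene = disc$boundaries_per_gene),
            class = "discretized_matrix")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cross-validation: %d runs (k in {%s}), mean accuracy %.4f (sd %.4f)\n",
              nrow(x$runs), paste(unique(x$runs$k), collapse = ","),
              x$mean_accuracy, x$sd_accuracy))
  cat("pooled confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' Confusion matrix
#'
#' Entry (i, j) counts samples of true class i predicted as class j; the
#' diagonal sum over the total is the accuracy.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param class_set ordered class labels.
#' @return integer matrix with `true` rows and `predicted` columns.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_set) {
  if (!length(true_labels)) stop_fmt("empty input")
  if (length(true_labels) != length(predicted_labels))
    stop_fmt("label vectors differ in length")
  tr <- factor(as.character(true_labels), levels = class_set)
  pr <- factor(as.character(predicted_labels), levels = class_set)
  if (anyNA(tr) || anyNA(pr)) stop_fmt("label outside class_set")
  m <- unclass(table(tr, pr))
  dimnames(m) <- list(true = class_set, predicted = class_set)
  m
}

#' Empirical ROC curve with AUC, standard error and confidence interval
#'
#' Operating points are computed over all score thresholds with tied scores
#' grouped; the AUC by the trapezoid rule equals the Mann-Whitney
#' probability `P(score_pos > score_neg) + P(tie)/2`. The standard error is
#' the Hanley-McNeil formula and the 95% confidence interval is
#' `auc +/- 1.96 se`, clipped to `[0, 1]`.
#'
#' @param scores numeric score per sample (larger = more positive).
#' @param binary_labels logical, or a two-level vector with `positive` named.
#' @param positive the label counted as positive (default `TRUE`).
#' @return an object of class `"roc_curve"`: data frame `points` (fpr, tpr),
#'   `auc`, `se`, `ci` (length-2).
#' @export
roc_curve <- function(scores, binary_labels, positive = TRUE) {
  pos <- binary_labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_fmt("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores: cut only where the score strictly drops
  last_of_group <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(p)[last_of_group]
  fp <- cumsum(!p)[last_of_group]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, se = se, ci = ci, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f, SE %.4f, 95%% CI %.4f-%.4f (%d pos / %d neg)\n",
              x$auc, x$se, x$ci[1L], x$ci[2L], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 main = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                x$auc, x$ci[1L], x$ci[2L]), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
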