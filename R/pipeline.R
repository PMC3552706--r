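#' Control parameters for [marker_fit()]
#'
#' Collects every stage's tunables with their defaults: discretization
#' (mixture component candidates), ranking pre-selection size, wrapper search
#' strategy, classifier structure/smoothing, and the final cross-validation
#' protocol. One master seed derives all per-stage seeds via [derive_seeds()]
#' so each stage is independently reproducible.
#'
#' @param k_candidates mixture component candidates (default 1:4).
#' @param top_k ranking pre-selection size (default 250).
#' @param strategy,direction,run_all,stale_limit wrapper search settings
#'   (defaults: best-first, forward, single combination, stale limit 5).
#' @param search_k,search_repeats CV folds/repeats inside the search goodness
#'   function (defaults 5, 3).
#' @param max_parents gene-parent cap for the final structure search
#'   (default 1).
#' @param smoothing CPT pseudo-count (default 0.5).
#' @param k_values,n_seeds final-report CV protocol (defaults `5:9`, 50).
#' @param stratified stratified folds (default TRUE).
#' @param seed master seed (default 1).
#' @return a list of class `"marker_control"`.
#' @export
marker_control <- function(k_candidates = 1:4, top_k = 250L,
                           strategy = c("best_first", "greedy"),
                           direction = c("forward", "backward"),
                           run_all = FALSE, stale_limit = 5L,
                           search_k = 5L, search_repeats = 3L,
                           max_parents = 1L, smoothing = 0.5,
                           k_values = 5:9, n_seeds = 50L, stratified = TRUE,
                           seed = 1L) {
  structure(list(k_candidates = k_candidates, top_k = as.integer(top_k),
                 strategy = match.arg(strategy),
                 direction = match.arg(direction), run_all = run_all,
                 stale_limit = stale_limit, search_k = as.integer(search_k),
                 search_repeats = as.integer(search_repeats),
                 max_parents = as.integer(max_parents),
                 smoothing = smoothing, k_values = as.integer(k_values),
                 n_seeds = as.integer(n_seeds), stratified = stratified,
                 seed = as.integer(seed)),
            class = "marker_control")
}

#' Fit the full biomarker-discovery model
#'
#' The end-to-end procedure: (1) discretize every gene by Gaussian-mixture
#' EM; (2) rank genes by the LorenzGini ratio and keep the top `top_k`;
#' (3) wrapper-search that pool for the subset maximizing cross-validated
#' classifier accuracy; (4) fit the final Bayesian-network classifier on the
#' selected markers with AIC structure search; (5) evaluate it by repeated
#' stratified k-fold cross-validation.
#'
#' @param x an [expression_matrix], or a numeric genes-by-samples matrix (in
#'   which case `labels` must be given).
#' @param labels class label per sample (ignored when `x` is already an
#'   [expression_matrix]).
#' @param control a [marker_control()].
#' @return an object of class `"marker_fit"`: `markers` (selected gene ids),
#'   `model` (the fitted `"bayesnet"`), `cv` (a `"cv_report"`), `ranking`
#'   (the LorenzGini table), `disc`, `control`, `seeds` (the derived stage
#'   seeds), `search` (per-search results).
#' @export
marker_fit <- function(x, labels = NULL, control = marker_control()) {
  if (!inherits(x, "expression_matrix")) {
    if (is.null(labels)) stop_fmt("labels required when x is a plain matrix")
    x <- expression_matrix(as.matrix(x), labels = labels)
  }
  seeds <- derive_seeds(control$seed, 3L)  # 1 discretize, 2 search, 3 eval
  res <- select_markers(
    x, top_k = control$top_k, strategy = control$strategy,
    direction = control$direction, run_all = control$run_all,
    stale_limit = control$stale_limit,
    search_config = eval_config(k = control$search_k,
                                repeats = control$search_repeats,
                                max_parents = 0L,
                                smoothing = control$smoothing,
                                seed = seeds[2L],
                                stratified = control$stratified),
    final_max_parents = control$max_parents,
    k_values = control$k_values, n_seeds = control$n_seeds,
    k_candidates = control$k_candidates, seed = seeds[1L])
  structure(list(markers = res$markers, model = res$model, cv = res$cv,
                 ranking = res$ranking, disc = res$disc, control = control,
                 seeds = seeds, search = res$search,
                 class_set = x$class_set),
            class = "marker_fit")
}

#' @export
print.marker_fit <- function(x, ...) {
  cat(sprintf("marker_fit: %d marker gene(s) of %d ranked\n",
              length(x$markers), nrow(x$ranking)))
  cat("markers:", paste(x$markers, collapse = ", "), "\n")
  cat(sprintf("cross-validated accuracy %.4f (sd %.4f, %d runs)\n",
              x$cv$mean_accuracy, x$cv$sd_accuracy, nrow(x$cv$runs)))
  invisible(x)
}

#' @export
summary.marker_fit <- function(object, ...) {
  x <- object
  cat("Selected markers and their ranking scores:\n")
  print(x$ranking[x$ranking$gene_id %in% x$markers,
                  c("gene_id", "lorenzgini", "delta_gini", "split")])
  cat("\nFinal model:\n")
  print(x$model)
  cat("\nCross-validation (final protocol):\n")
  print(x$cv)
  by_k <- stats::aggregate(accuracy ~ k, x$cv$runs, mean)
  cat("\nmean accuracy by k:\n")
  print(by_k)
  invisible(x)
}

#' @export
coef.marker_fit <- function(object, ...) {
  r <- object$ranking[object$ranking$gene_id %in% object$markers, ]
  stats::setNames(r$lorenzgini, r$gene_id)
}

#' Predict classes for new continuous expression data
#'
#' New samples are discretized with the boundaries stored at training time,
#' then classified by the fitted network.
#'
#' @param object a `"marker_fit"`.
#' @param newdata an [expression_matrix] or numeric genes-by-samples matrix
#'   containing at least the marker genes.
#' @param ... ignored.
#' @return list with `class` and `posterior` as in [predict.bayesnet()].
#' @export
predict.marker_fit <- function(object, newdata, ...) {
  vals <- if (inherits(newdata, "expression_matrix")) newdata$values
          else as.matrix(newdata)
  missing <- setdiff(object$markers, rownames(vals))
  if (length(missing))
    stop_fmt("marker gene(s) absent from newdata: %s",
             paste(missing, collapse = ", "))
  codes <- t(vapply(object$markers, function(g)
    apply_boundaries(vals[g, ], object$disc$boundaries_per_gene[[g]]),
    integer(ncol(vals))))
  dimnames(codes) <- list(object$markers, colnames(vals))
  predict(object$model, codes)
}

#' @export
plot.marker_fit <- function(x, ...) {
  graphics::boxplot(accuracy ~ k, data = x$cv$runs,
                    xlab = "number of folds k",
                    ylab = "cross-validated accuracy",
                    main = sprintf("%d markers, mean accuracy %.3f",
                                   length(x$markers), x$cv$mean_accuracy),
                    ...)
  invisible(x)
}
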