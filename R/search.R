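#' Evaluation configuration for the wrapper search
#'
#' The goodness of a candidate subset is its mean cross-validated accuracy
#' under one fixed, internally seeded configuration, so goodness is a
#' deterministic function of the subset and can be cached. The default
#' (k = 5, 3 repeats, naive class-to-gene structure) keeps the search loop
#' tractable; the heavier repeated protocol is reserved for final reporting.
#'
#' @param k folds used inside the search (default 5).
#' @param repeats CV repeats inside the search (default 3).
#' @param max_parents gene-parent cap for the classifier inside the search
#'   (default 0 = class-parent-only backbone).
#' @param smoothing CPT pseudo-count.
#' @param seed fixed internal seed making goodness deterministic.
#' @param stratified stratify folds.
#' @return a list of class `"eval_config"`.
#' @export
eval_config <- function(k = 5L, repeats = 3L, max_parents = 0L,
                        smoothing = 0.5, seed = 1L, stratified = TRUE) {
  structure(list(k = k, repeats = repeats, max_parents = max_parents,
                 smoothing = smoothing, seed = seed, stratified = stratified),
            class = "eval_config")
}

new_goodness_cache <- function() new.env(parent = emptyenv())

subset_key <- function(subset) {
  paste0("k:", paste(sort(subset), collapse = "\r"))
}

#' Goodness of a gene subset
#'
#' Mean k-fold cross-validated accuracy of the network classifier restricted
#' to the subset, under the fixed configuration in `config`. Values are
#' cached by subset (order-independent), so repeated queries cost nothing.
#'
#' @param subset non-empty character vector of gene ids.
#' @param disc a `"discretized_matrix"`.
#' @param config an [eval_config()].
#' @param cache environment from `new_goodness_cache()`; pass the same cache
#'   across calls to share evaluations.
#' @return accuracy in `[0, 1]`.
#' @export
goodness <- function(subset, disc, config = eval_config(),
                     cache = new_goodness_cache()) {
  if (!length(subset)) stop_fmt("empty subset")
  key <- subset_key(subset)
  if (!is.null(cache[[key]])) return(cache[[key]])
  rep <- cross_validate(disc, subset, k_values = config$k,
                        n_seeds = config$repeats,
                        max_parents = config$max_parents,
                        smoothing = config$smoothing,
                        stratified = config$stratified,
                        seed_base = config$seed * 1000L)
  cache[[key]] <- rep$mean_accuracy
  cache[[key]]
}

# tie-break among equal-goodness subsets: smaller first, then earlier in the
# pool's ranking order (lexicographic over ranked positions)
subset_rank_key <- function(subset, pool) {
  sort(match(subset, pool))
}

prefer_subset <- function(a, b, pool) {
  # TRUE if a is preferred over b at equal goodness
  if (length(a) != length(b)) return(length(a) < length(b))
  ka <- subset_rank_key(a, pool); kb <- subset_rank_key(b, pool)
  cmp <- ka - kb
  nz <- which(cmp != 0)
  if (!length(nz)) FALSE else cmp[nz[1L]] < 0
}

children_of <- function(subset, pool, direction) {
  if (direction == "forward") {
    lapply(setdiff(pool, subset), function(g) c(subset, g))
  } else {
    if (length(subset) <= 1L) list()
    else lapply(seq_along(subset), function(i) subset[-i])
  }
}

#' Greedy wrapper search
#'
#' From the empty set (forward) or the full pool (backward), all child
#' subsets reachable by adding/removing one gene are scored; the best child
#' replaces the parent while it strictly improves goodness, and the search
#' stops when no child improves. Ties among children are broken by the pool's
#' ranking order.
#'
#' @param pool ranked character vector of candidate gene ids (best first).
#' @param direction `"forward"` or `"backward"`.
#' @param disc a `"discretized_matrix"`.
#' @param config an [eval_config()].
#' @param cache shared goodness cache (optional).
#' @param trace optional environment collecting every scored subset.
#' @return list with `subset`, `goodness`, `n_evaluated`.
#' @export
greedy_search <- function(pool, direction = c("forward", "backward"), disc,
                          config = eval_config(),
                          cache = new_goodness_cache(), trace = NULL) {
  direction <- match.arg(direction)
  if (!length(pool)) stop_fmt("empty pool")
  score <- function(s) {
    g <- goodness(s, disc, config, cache)
    if (!is.null(trace)) trace$log <- rbind(trace$log,
      data.frame(subset = subset_key(s), goodness = g))
    g
  }
  current <- if (direction == "forward") character(0) else pool
  cur_good <- if (length(current)) score(current) else -Inf
  repeat {
    kids <- children_of(current, pool, direction)
    if (!length(kids)) break
    kid_good <- vapply(kids, score, numeric(1))
    best <- which(kid_good == max(kid_good))
    # ranking-order tie-break: children are generated in pool order (forward)
    # / removal order (backward); take the preferred one
    b <- best[1L]
    for (j in best[-1L]) if (prefer_subset(kids[[j]], kids[[b]], pool)) b <- j
    if (kid_good[[b]] > cur_good) {
      current <- kids[[b]]
      cur_good <- kid_good[[b]]
    } else break
  }
  list(subset = current, goodness = cur_good,
       n_evaluated = length(ls(cache)))
}

#' Best-first wrapper search with backtracking
#'
#' Maintains an open list of scored-but-unexpanded subsets and always expands
#' the one with the highest goodness, so the search can backtrack to an
#' earlier branch when the current path stops improving. A limit is placed on
#' the number of consecutive non-improving expansions (default 5); the
#' all-time best subset is returned. With an unlimited stale budget and a
#' non-empty open list the search visits every reachable subset and is
#' equivalent to exhaustive enumeration.
#'
#' @inheritParams greedy_search
#' @param stale_limit consecutive non-improving expansions tolerated
#'   (default 5; `Inf` = exhaustive).
#' @return list with `subset`, `goodness`, `n_evaluated`.
#' @export
best_first_search <- function(pool, direction = c("forward", "backward"),
                              disc, config = eval_config(), stale_limit = 5L,
                              cache = new_goodness_cache(), trace = NULL) {
  direction <- match.arg(direction)
  if (!length(pool)) stop_fmt("empty pool")
  if (stale_limit < 1L) stop_fmt("stale_limit must be >= 1")
  score <- function(s) {
    g <- goodness(s, disc, config, cache)
    if (!is.null(trace)) trace$log <- rbind(trace$log,
      data.frame(subset = subset_key(s), goodness = g))
    g
  }
  start <- if (direction == "forward") character(0) else pool
  open <- list(list(subset = start,
                    goodness = if (length(start)) score(start) else -Inf))
  seen <- new.env(parent = emptyenv())
  seen[[subset_key(start)]] <- TRUE
  best <- open[[1L]]
  stale <- 0L
  while (length(open) && stale < stale_limit) {
    # pop the best unexpanded subset (ties: preferred subset)
    gd <- vapply(open, `[[`, numeric(1), "goodness")
    cand <- which(gd == max(gd))
    b <- cand[1L]
    for (j in cand[-1L])
      if (prefer_subset(open[[j]]$subset, open[[b]]$subset, pool)) b <- j
    node <- open[[b]]
    open[[b]] <- NULL
    improved <- FALSE
    for (kid in children_of(node$subset, pool, direction)) {
      key <- subset_key(kid)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      g <- score(kid)
      open[[length(open) + 1L]] <- list(subset = kid, goodness = g)
      if (g > best$goodness ||
          (g == best$goodness && prefer_subset(kid, best$subset, pool))) {
        if (g > best$goodness) improved <- TRUE
        best <- list(subset = kid, goodness = g)
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  list(subset = best$subset, goodness = best$goodness,
       n_evaluated = length(ls(cache)))
}

#' Select a marker subset from an expression matrix
#'
#' The wrapper step end-to-end: discretize, rank by LorenzGini, keep the top
#' `top_k`, run the configured subset search(es) over that pool, and return
#' the best subset with a final fitted network and a full cross-validation
#' report. The default runs best-first forward; set `run_all = TRUE` to run
#' both strategies in both directions and keep the overall best (backward
#' runs start from the full pool and are expensive for large `top_k`).
#'
#' @param x an [expression_matrix].
#' @param top_k ranking pre-selection size (default 250).
#' @param strategy `"best_first"` or `"greedy"`.
#' @param direction `"forward"` or `"backward"`.
#' @param run_all run all four strategy/direction combinations.
#' @param stale_limit best-first non-improving budget (default 5).
#' @param search_config an [eval_config()] for the goodness function.
#' @param final_max_parents gene-parent cap for the final model's structure
#'   search (default 1).
#' @param k_values,n_seeds final-report CV protocol (defaults `5:9`, 50).
#' @param k_candidates,seed discretization controls.
#' @return list with `markers`, `model` (a `"bayesnet"`), `cv` (a
#'   `"cv_report"`), `ranking`, `disc`, `search` (per-search results).
#' @export
select_markers <- function(x, top_k = 250L,
                           strategy = c("best_first", "greedy"),
                           direction = c("forward", "backward"),
                           run_all = FALSE, stale_limit = 5L,
                           search_config = eval_config(),
                           final_max_parents = 1L,
                           k_values = 5:9, n_seeds = 50L,
                           k_candidates = 1:4, seed = 1L) {
  strategy <- match.arg(strategy)
  direction <- match.arg(direction)
  disc <- discretize_matrix(x, k_candidates = k_candidates, seed = seed)
  ranking <- rank_genes(disc, top_k = top_k)
  pool <- ranking$gene_id
  cache <- new_goodness_cache()
  combos <- if (run_all) {
    expand.grid(strategy = c("best_first", "greedy"),
                direction = c("forward", "backward"),
                stringsAsFactors = FALSE)
  } else {
    data.frame(strategy = strategy, direction = direction,
               stringsAsFactors = FALSE)
  }
  searches <- lapply(seq_len(nrow(combos)), function(i) {
    res <- if (combos$strategy[i] == "greedy") {
      greedy_search(pool, combos$direction[i], disc, search_config, cache)
    } else {
      best_first_search(pool, combos$direction[i], disc, search_config,
                        stale_limit, cache)
    }
    c(res, combos[i, ])
  })
  best <- searches[[1L]]
  for (s in searches[-1L]) {
    if (s$goodness > best$goodness ||
        (s$goodness == best$goodness &&
           prefer_subset(s$subset, best$subset, pool))) best <- s
  }
  markers <- best$subset
  model <- learn_structure(disc, genes = markers,
                           max_parents = final_max_parents,
                           smoothing = search_config$smoothing)
  cv <- cross_validate(disc, markers, k_values = k_values, n_seeds = n_seeds,
                       max_parents = search_config$max_parents,
                       smoothing = search_config$smoothing)
  list(markers = markers, model = model, cv = cv, ranking = ranking,
       disc = disc, search = searches)
}
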