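#' Fit a discrete Bayesian-network classifier given its structure
#'
#' The network is a classifier backbone: the class node is a root and a
#' parent of every gene node; each gene may additionally have up to two gene
#' parents (given by `parents`). Conditional probability tables are estimated
#' with pseudo-count smoothing:
#' `P(v | parent combo) = (count + s) / (row total + s * arity)`;
#' class priors the same way from the label counts.
#'
#' @param disc a `"discretized_matrix"` restricted (or restrictable) to the
#'   marker genes.
#' @param genes character vector of gene ids to include as nodes.
#' @param parents named list mapping gene id to a character vector of gene
#'   parents (class parent is implicit). Missing entries mean no gene parent
#'   (naive structure).
#' @param smoothing pseudo-count (default 0.5).
#' @param arity optional named integer vector of value counts per gene;
#'   defaults to `disc$ranges_per_gene`.
#' @return an object of class `"bayesnet"` with per-gene CPT arrays, class
#'   priors, parent sets, arities, the smoothing used, and the fit's
#'   log-likelihood / AIC on the training data.
#' @export
bayesnet_fit <- function(disc, genes = disc$gene_ids, parents = list(),
                         smoothing = 0.5, arity = NULL) {
  stopifnot(inherits(disc, "discretized_matrix"))
  missing <- setdiff(genes, disc$gene_ids)
  if (length(missing))
    stop_fmt("genes absent from data: %s", paste(missing, collapse = ", "))
  bad <- setdiff(unlist(parents), genes)
  if (length(bad))
    stop_fmt("parent genes not in node set: %s", paste(bad, collapse = ", "))
  check_acyclic(genes, parents)
  if (is.null(arity)) arity <- disc$ranges_per_gene[genes]
  arity <- arity[genes]
  n_class <- length(disc$class_set)
  y <- as.integer(disc$labels)                       # 1..n_class
  codes <- disc$codes[genes, , drop = FALSE]

  class_counts <- tabulate(y, n_class)
  priors <- (class_counts + smoothing) /
    (sum(class_counts) + smoothing * n_class)
  names(priors) <- disc$class_set

  cpts <- lapply(genes, function(g) {
    pa <- parents[[g]]
    dims <- c(arity[[g]], n_class, if (length(pa)) arity[pa])
    idx_list <- c(list(factor(codes[g, ], levels = 0:(arity[[g]] - 1L)),
                       factor(y, levels = seq_len(n_class))),
                  lapply(pa, function(p)
                    factor(codes[p, ], levels = 0:(arity[[p]] - 1L))))
    counts <- array(unclass(table(idx_list)), dim = dims)
    tot <- apply(counts, seq_along(dims)[-1L], sum)
    sm <- counts + smoothing
    denom <- array(rep(tot + smoothing * arity[[g]], each = dims[1L]),
                   dim = dims)
    p <- sm / denom
    if (smoothing == 0) {
      # unobserved parent combos: leave a uniform row rather than 0/0
      zero <- denom == 0
      p[zero] <- 1 / dims[1L]
    }
    p
  })
  names(cpts) <- genes

  model <- structure(list(genes = genes, class_set = disc$class_set,
                          parents = parents[intersect(names(parents), genes)],
                          arity = arity, cpts = cpts, class_priors = priors,
                          smoothing = smoothing,
                          boundaries = disc$boundaries_per_gene[
                            intersect(genes, names(disc$boundaries_per_gene))],
                          format_version = 1L),
                     class = "bayesnet")
  ll <- bn_log_likelihood(model, disc)
  model$loglik <- ll
  model$n_parameters <- bn_n_parameters(model)
  model$aic <- -ll + model$n_parameters
  model
}

check_acyclic <- function(genes, parents) {
  # class node is a root; only gene-gene edges can form a cycle
  state <- stats::setNames(rep(0L, length(genes)), genes)  # 0 new 1 open 2 done
  visit <- function(g) {
    if (state[[g]] == 1L) stop_fmt("parent structure contains a cycle at '%s'", g)
    if (state[[g]] == 2L) return(invisible())
    state[[g]] <<- 1L
    for (p in parents[[g]]) visit(p)
    state[[g]] <<- 2L
  }
  for (g in genes) visit(g)
  invisible(TRUE)
}

bn_n_parameters <- function(model) {
  n_class <- length(model$class_set)
  gene_par <- sum(vapply(model$genes, function(g) {
    pa <- model$parents[[g]]
    (model$arity[[g]] - 1) * n_class *
      if (length(pa)) prod(model$arity[pa]) else 1
  }, numeric(1)))
  gene_par + (n_class - 1)
}

# CPT lookup P(gene = code | class, gene-parents' codes) for all samples.
cpt_prob <- function(model, g, codes, y) {
  pa <- model$parents[[g]]
  cpt <- model$cpts[[g]]
  idx <- cbind(codes[g, ] + 1L, y,
               if (length(pa))
                 matrix(t(codes[pa, , drop = FALSE]) + 1L,
                        ncol = length(pa)))
  cpt[idx]
}

bn_log_likelihood <- function(model, disc) {
  codes <- disc$codes[model$genes, , drop = FALSE]
  y <- as.integer(factor(as.character(disc$labels),
                         levels = model$class_set))
  ll <- sum(log(model$class_priors[y]))
  for (g in model$genes) ll <- ll + sum(log(cpt_prob(model, g, codes, y)))
  ll
}

#' Log-likelihood and AIC of a fitted network
#'
#' AIC here is the negated log-likelihood plus the number of free parameters
#' (`sum over nodes of (arity - 1) * prod(parent arities)`, the class node
#' contributing `n_classes - 1`); lower is better. With zero smoothing an
#' unobserved event yields `-Inf` log-likelihood, which is reported, not an
#' error.
#'
#' @param object,model a `"bayesnet"`.
#' @param disc data to score; defaults to the stored training-fit values.
#' @param ... ignored.
#' @return `logLik` returns a numeric with attributes `df` and `nobs`; `AIC`
#'   the score (a plain number).
#' @export
logLik.bayesnet <- function(object, disc = NULL, ...) {
  ll <- if (is.null(disc)) object$loglik else bn_log_likelihood(object, disc)
  structure(ll, df = object$n_parameters, class = "logLik")
}

#' @rdname logLik.bayesnet
#' @export
aic_score <- function(model, disc = NULL) {
  ll <- if (is.null(disc)) model$loglik else bn_log_likelihood(model, disc)
  -ll + model$n_parameters
}

#' Joint probability of one instance and one class
#'
#' The product of every gene's CPT entry given its parents' values (the class
#' included) times the class prior.
#'
#' @param model a `"bayesnet"`.
#' @param instance named integer vector of 0-based codes, one per gene node.
#' @param class a class label.
#' @return the joint probability.
#' @export
joint_probability <- function(model, instance, class) {
  ci <- match(class, model$class_set)
  if (is.na(ci)) stop_fmt("unknown class '%s'", class)
  for (g in model$genes) {
    v <- instance[[g]]
    if (is.null(v) || is.na(v) || v < 0L || v >= model$arity[[g]])
      stop_fmt("value for gene '%s' missing or out of range [0, %d]",
               g, model$arity[[g]] - 1L)
  }
  codes <- matrix(as.integer(instance[model$genes]), ncol = 1,
                  dimnames = list(model$genes, NULL))
  p <- model$class_priors[[ci]]
  for (g in model$genes) p <- p * cpt_prob(model, g, codes, ci)
  unname(p)
}

#' Classify instances with a fitted network
#'
#' The posterior over classes is proportional to the per-class joint
#' probability; the argmax is returned, ties broken by `class_set` order.
#'
#' @param object a `"bayesnet"`.
#' @param newdata either a `"discretized_matrix"`, an integer code matrix
#'   (genes x samples, 0-based), or a single named instance vector.
#' @param ... ignored.
#' @return a list with `class` (predicted label per sample) and `posterior`
#'   (samples x classes matrix).
#' @export
predict.bayesnet <- function(object, newdata, ...) {
  model <- object
  if (inherits(newdata, "discretized_matrix")) {
    codes <- newdata$codes[model$genes, , drop = FALSE]
  } else if (is.matrix(newdata)) {
    codes <- newdata[model$genes, , drop = FALSE]
  } else {
    codes <- matrix(as.integer(newdata[model$genes]), ncol = 1,
                    dimnames = list(model$genes, NULL))
  }
  ns <- ncol(codes)
  n_class <- length(model$class_set)
  logjoint <- matrix(rep(log(model$class_priors), each = ns), ns, n_class,
                     dimnames = list(colnames(codes), model$class_set))
  for (ci in seq_len(n_class)) {
    for (g in model$genes) {
      logjoint[, ci] <- logjoint[, ci] +
        log(cpt_prob(model, g, codes, rep(ci, ns)))
    }
  }
  mx <- apply(logjoint, 1L, max)
  if (any(!is.finite(mx)))
    stop_fmt("all class joints are zero for some instance (smoothing 0?)")
  post <- exp(logjoint - mx)
  post <- post / rowSums(post)
  pred <- model$class_set[max.col(post, ties.method = "first")]
  list(class = pred, posterior = post)
}

#' @export
print.bayesnet <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("Bayesian-network classifier: %d gene nodes, %d classes, %d gene-gene edges\n",
              length(x$genes), length(x$class_set), n_edges))
  cat(sprintf("free parameters %d, training log-likelihood %.3f, AIC %.3f\n",
              x$n_parameters, x$loglik, x$aic))
  invisible(x)
}

#' Learn the network structure by greedy AIC search
#'
#' The class node is always a parent of every gene node. Gene nodes are
#' processed in the given ordering; for each node, candidate parents are the
#' earlier-ordered genes (which keeps the graph acyclic by construction), and
#' single edges are added greedily, each kept only if it strictly lowers the
#' AIC, until `max_parents` gene parents are reached or no addition improves.
#' `max_parents = 2` is the second-parent search variant; `max_parents = 0`
#' returns the naive structure.
#'
#' @param disc a `"discretized_matrix"`.
#' @param genes gene ordering to process (default: data order; typically the
#'   ranking order).
#' @param max_parents maximum gene parents per gene node (0, 1 or 2).
#' @param smoothing pseudo-count for CPT estimation.
#' @return the fitted `"bayesnet"` with the selected structure.
#' @export
learn_structure <- function(disc, genes = disc$gene_ids, max_parents = 1L,
                            smoothing = 0.5) {
  stopifnot(max_parents %in% 0:2)
  parents <- stats::setNames(vector("list", length(genes)), genes)
  fit <- bayesnet_fit(disc, genes, parents = list(), smoothing = smoothing)
  if (max_parents == 0L || length(genes) < 2L) return(fit)
  best_aic <- fit$aic
  for (i in seq_along(genes)[-1L]) {
    g <- genes[[i]]
    repeat {
      if (length(parents[[g]]) >= max_parents) break
      cands <- setdiff(genes[seq_len(i - 1L)], parents[[g]])
      if (!length(cands)) break
      trial_aic <- vapply(cands, function(p) {
        pa <- parents
        pa[[g]] <- c(pa[[g]], p)
        bayesnet_fit(disc, genes, parents = pa, smoothing = smoothing)$aic
      }, numeric(1))
      j <- which.min(trial_aic)
      if (trial_aic[[j]] < best_aic) {
        parents[[g]] <- c(parents[[g]], cands[[j]])
        best_aic <- trial_aic[[j]]
      } else break
    }
  }
  bayesnet_fit(disc, genes,
               parents = Filter(length, parents), smoothing = smoothing)
}
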