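#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Plain expectation-maximization for a k-component univariate normal mixture.
#' Initialization is deterministic: component means at the k mid-quantiles of
#' the data, a common variance equal to the sample variance, uniform weights.
#' A variance floor of `1e-6` times the sample variance keeps components from
#' collapsing onto single points. The log-likelihood is non-decreasing across
#' iterations; iteration stops when its relative change falls below `tol`.
#'
#' @param values numeric vector, length at least `2k`.
#' @param k number of components (`k = 1` is handled in closed form).
#' @param seed integer seed (the default initialization is deterministic, but
#'   the seed is part of the contract so alternative initializations stay
#'   reproducible).
#' @param max_iter,tol iteration cap and relative log-likelihood tolerance.
#' @return an object of class `"mixture_fit"`: weights, means and variances in
#'   ascending-mean order, `loglik`, `bic`, `converged`, `n_iter`, and the
#'   per-iteration `loglik_trace`.
#' @export
em_fit <- function(values, k, seed = 1L, max_iter = 500L, tol = 1e-6) {
  values <- as.numeric(values)
  n <- length(values)
  if (k < 1L) stop_fmt("k must be >= 1")
  if (n < 2L * k) stop_fmt("need at least 2k = %d values, got %d", 2L * k, n)
  sv <- stats::var(values) * (n - 1) / n   # ML variance
  if (k == 1L) {
    mu <- mean(values)
    ll <- sum(stats::dnorm(values, mu, sqrt(max(sv, 1e-300)), log = TRUE))
    return(structure(list(k = 1L, weights = 1, means = mu, variances = sv,
                          converged = TRUE, n_iter = 0L, loglik = ll,
                          loglik_trace = ll, bic = -2 * ll + 2 * log(n)),
                     class = "mixture_fit"))
  }
  if (sv == 0)
    stop_fmt("all values identical; a %d-component mixture is degenerate (use k = 1)", k)
  floor_var <- 1e-6 * sv
  mu <- as.numeric(stats::quantile(values, (seq_len(k) - 0.5) / k,
                                   names = FALSE, type = 7))
  var_ <- rep(sv, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  trace <- numeric(max_iter)
  converged <- FALSE
  iter <- 0L
  logdens <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    # E-step in log space for numerical safety
    for (j in seq_len(k)) {
      logdens[, j] <- log(w[j]) - 0.5 * log(2 * pi * var_[j]) -
        (values - mu[j])^2 / (2 * var_[j])
    }
    mx <- logdens[, 1L]
    for (j in seq_len(k)[-1L]) mx <- pmax(mx, logdens[, j])
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    trace[iter] <- ll
    resp <- exp(logdens - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    nk <- colSums(resp)
    nk[nk < 1e-300] <- 1e-300
    w <- nk / n
    mu <- colSums(resp * values) / nk
    var_ <- vapply(seq_len(k), function(j)
      sum(resp[, j] * (values - mu[j])^2), numeric(1)) / nk
    var_ <- pmax(var_, floor_var)
  }
  trace <- trace[seq_len(iter)]
  ord <- order(mu)
  p <- 3 * k - 1  # free parameters: k means, k variances, k-1 weights
  structure(list(k = k, weights = w[ord], means = mu[ord],
                 variances = var_[ord], converged = converged, n_iter = iter,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 bic = -2 * trace[length(trace)] + p * log(n)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture, k = %d (%s, %d iterations)\n", x$k,
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(data.frame(weight = x$weights, mean = x$means,
                   variance = x$variances))
  cat(sprintf("log-likelihood %.4f, BIC %.4f\n", x$loglik, x$bic))
  invisible(x)
}

#' Select the mixture order by BIC
#'
#' Fits [em_fit()] for each candidate component count and returns the fit with
#' the smallest BIC. Candidates whose fit errors (for example `k > 1` on a
#' constant vector) are skipped; an error is raised only when every candidate
#' fails.
#'
#' @param values numeric vector.
#' @param k_candidates integer vector of component counts to try.
#' @param seed,max_iter,tol passed to [em_fit()].
#' @return the BIC-minimizing `"mixture_fit"`.
#' @export
choose_components <- function(values, k_candidates = 1:4, seed = 1L,
                              max_iter = 500L, tol = 1e-6) {
  if (!length(k_candidates)) stop_fmt("k_candidates must be non-empty")
  fits <- list()
  errs <- character(0)
  for (k in sort(unique(as.integer(k_candidates)))) {
    f <- tryCatch(em_fit(values, k, seed = seed, max_iter = max_iter,
                         tol = tol),
                  error = function(e) e)
    if (inherits(f, "error")) errs <- c(errs, conditionMessage(f))
    else fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits))
    stop_fmt("every candidate failed: %s", paste(errs, collapse = "; "))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
}

# Boundary between two adjacent (ascending-mean) components: the point where
# their weighted densities cross. Solved on the log scale between the means;
# if no sign change exists there (heavily overlapping components), the
# precision-weighted midpoint is used.
component_boundary <- function(w1, m1, v1, w2, m2, v2) {
  f <- function(x) {
    (log(w1) + stats::dnorm(x, m1, sqrt(v1), log = TRUE)) -
      (log(w2) + stats::dnorm(x, m2, sqrt(v2), log = TRUE))
  }
  if (m2 - m1 < .Machine$double.eps) return((m1 + m2) / 2)
  lo <- m1; hi <- m2
  if (f(lo) > 0 && f(hi) < 0) {
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  } else {
    (m1 / v1 + m2 / v2) / (1 / v1 + 1 / v2)
  }
}

# Discretize one gene's values: fit a mixture, convert it to cut points at the
# posterior crossings, assign codes by interval, drop empty ranges.
discretize_gene <- function(values, k_candidates, seed, max_iter, tol) {
  if (stats::var(values) == 0) {
    return(list(codes = rep(0L, length(values)), m = 1L,
                boundaries = numeric(0)))
  }
  fit <- choose_components(values, k_candidates, seed = seed,
                           max_iter = max_iter, tol = tol)
  if (fit$k == 1L) {
    return(list(codes = rep(0L, length(values)), m = 1L,
                boundaries = numeric(0)))
  }
  b <- vapply(seq_len(fit$k - 1L), function(i)
    component_boundary(fit$weights[i], fit$means[i], fit$variances[i],
                       fit$weights[i + 1L], fit$means[i + 1L],
                       fit$variances[i + 1L]),
    numeric(1))
  b <- sort(b)
  codes <- findInterval(values, b)          # 0-based range index
  used <- sort(unique(codes))
  codes <- match(codes, used) - 1L          # compact dropped ranges
  # keep only boundaries separating surviving ranges
  keep <- used[-1L]
  list(codes = as.integer(codes), m = length(used),
       boundaries = if (length(keep)) b[keep] else numeric(0))
}

#' Discretize an expression matrix gene-by-gene
#'
#' Each gene's continuous values are converted to ordered ranges by fitting a
#' univariate Gaussian mixture (component count chosen by BIC among
#' `k_candidates`) and cutting at the posterior crossing points between
#' adjacent components. Range 0 always holds the lowest expression values, so
#' codes respect value order within a gene. Ranges left empty after cutting
#' are dropped and the indices compacted. A constant gene yields a single
#' range.
#'
#' @param x an [expression_matrix].
#' @param k_candidates candidate component counts (default 1:4).
#' @param seed integer seed.
#' @param max_iter,tol EM controls.
#' @return an object of class `"discretized_matrix"`: integer `codes`
#'   (genes x samples, 0-based per gene), `ranges_per_gene`,
#'   `boundaries_per_gene`, plus the ids, labels and class set carried over.
#' @export
discretize_matrix <- function(x, k_candidates = 1:4, seed = 1L,
                              max_iter = 500L, tol = 1e-6) {
  stopifnot(inherits(x, "expression_matrix"))
  ng <- length(x$gene_ids)
  codes <- matrix(0L, ng, length(x$sample_ids),
                  dimnames = dimnames(x$values))
  m_g <- integer(ng)
  bounds <- vector("list", ng)
  for (g in seq_len(ng)) {
    d <- discretize_gene(x$values[g, ], k_candidates, seed, max_iter, tol)
    codes[g, ] <- d$codes
    m_g[g] <- d$m
    bounds[[g]] <- d$boundaries
  }
  names(bounds) <- x$gene_ids
  names(m_g) <- x$gene_ids
  structure(list(codes = codes, gene_ids = x$gene_ids,
                 sample_ids = x$sample_ids, labels = x$labels,
                 class_set = x$class_set, ranges_per_gene = m_g,
                 boundaries_per_gene = bounds),
            class = "discretized_matrix")
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat(sprintf("discretized_matrix: %d genes x %d samples, %d-%d ranges per gene\n",
              length(x$gene_ids), length(x$sample_ids),
              min(x$ranges_per_gene), max(x$ranges_per_gene)))
  invisible(x)
}

# Apply stored per-gene boundaries to new continuous values (for prediction).
apply_boundaries <- function(values, boundaries) {
  if (!length(boundaries)) rep(0L, length(values))
  else as.integer(findInterval(values, boundaries))
}
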