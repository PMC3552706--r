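# Shared fixtures and independent oracles, all built in code.

# contingency table from a list of per-range count vectors
table_from_rows <- function(rows, classes = paste0("C", seq_along(rows[[1]]))) {
  codes <- rep(seq_along(rows) - 1L, vapply(rows, sum, integer(1)))
  labels <- unlist(lapply(rows, function(r) rep(classes, r)))
  build_contingency(codes, labels, classes)
}

# the three-range, three-class class-order-bias example (d = 100)
table1_fixture <- function() {
  table_from_rows(list(c(4L, 6L, 30L), c(6L, 30L, 4L), c(0L, 4L, 16L)))
}

# the two four-range genes of the range-order-bias example
table2_left <- function() {
  table_from_rows(list(c(3L, 0L, 0L), c(0L, 88L, 0L), c(4L, 0L, 0L),
                       c(0L, 0L, 5L)))
}
table2_right <- function() {
  table_from_rows(list(c(3L, 0L, 0L), c(4L, 0L, 0L), c(0L, 88L, 0L),
                       c(0L, 0L, 5L)))
}

# random non-degenerate contingency table (every row/column non-zero total)
random_table <- function(max_m = 6L, max_n = 5L) {
  repeat {
    m <- sample(2:max_m, 1L)
    n <- sample(2:max_n, 1L)
    counts <- matrix(stats::rpois(m * n, 3), m, n)
    if (all(rowSums(counts) > 0) && all(colSums(counts) > 0)) {
      return(table_from_rows(asplit(counts, 1L)))
    }
  }
}

# build a discretized_matrix directly from 0-based codes (bypassing EM)
make_disc <- function(codes, labels, class_set = unique(as.character(labels)),
                      gene_ids = NULL, arity = NULL) {
  codes <- rbind(codes)
  storage.mode(codes) <- "integer"
  if (is.null(gene_ids)) {
    gene_ids <- rownames(codes)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(codes)))
  }
  if (is.null(arity)) arity <- apply(codes, 1L, max) + 1L
  rownames(codes) <- gene_ids
  colnames(codes) <- paste0("s", seq_len(ncol(codes)))
  structure(list(codes = codes, gene_ids = gene_ids,
                 sample_ids = colnames(codes),
                 labels = factor(as.character(labels), levels = class_set),
                 class_set = class_set,
                 ranges_per_gene = stats::setNames(as.integer(arity), gene_ids),
                 boundaries_per_gene =
                   stats::setNames(vector("list", nrow(codes)), gene_ids)),
            class = "discretized_matrix")
}

# a gene whose code equals the class index: a perfect predictor
perfect_gene_disc <- function(n_per_class = 10L, n_classes = 2L,
                              noise_genes = 0L, seed = 42L) {
  classes <- paste0("c", seq_len(n_classes))
  labels <- rep(classes, each = n_per_class)
  n <- length(labels)
  codes <- matrix(rep(seq_len(n_classes) - 1L, each = n_per_class), 1L, n)
  if (noise_genes > 0L) {
    withr::with_seed(seed, {
      codes <- rbind(codes,
                     matrix(sample(0:1, noise_genes * n, replace = TRUE),
                            noise_genes, n))
    })
  }
  rownames(codes) <- c("perfect",
                       if (noise_genes > 0L) paste0("noise", seq_len(noise_genes)))
  make_disc(codes, labels, classes)
}

# independent oracle: posterior by direct CPT indexing with explicit loops,
# normalized over the enumerated per-class joints
brute_force_posterior <- function(model, instance) {
  joints <- vapply(seq_along(model$class_set), function(ci) {
    p <- model$class_priors[[ci]]
    for (g in model$genes) {
      pa <- model$parents[[g]]
      idx <- c(instance[[g]] + 1L, ci,
               if (length(pa)) unlist(instance[pa]) + 1L)
      p <- p * do.call(`[`, c(list(model$cpts[[g]]), as.list(idx)))
    }
    p
  }, numeric(1))
  joints / sum(joints)
}

# independent oracle: AIC by direct counting/logs, no package internals
brute_force_aic <- function(disc, genes, parents, smoothing) {
  y <- as.character(disc$labels)
  class_set <- disc$class_set
  n_class <- length(class_set)
  arity <- disc$ranges_per_gene[genes]
  n <- length(y)
  # class prior term
  cc <- table(factor(y, levels = class_set))
  pri <- (as.numeric(cc) + smoothing) / (n + smoothing * n_class)
  ll <- sum(as.numeric(cc) * log(pri))
  npar <- n_class - 1
  for (g in genes) {
    pa <- parents[[g]]
    npar <- npar + (arity[[g]] - 1) * n_class *
      (if (length(pa)) prod(arity[pa]) else 1)
    # enumerate parent configurations explicitly
    pa_grid <- expand.grid(c(list(class = class_set),
                             lapply(pa, function(p) 0:(arity[[p]] - 1L))),
                           stringsAsFactors = FALSE)
    for (r in seq_len(nrow(pa_grid))) {
      sel <- y == pa_grid$class[r]
      if (length(pa)) {
        for (j in seq_along(pa)) {
          sel <- sel & disc$codes[pa[j], ] == pa_grid[r, j + 1L]
        }
      }
      tot <- sum(sel)
      for (v in 0:(arity[[g]] - 1L)) {
        cnt <- sum(sel & disc$codes[g, ] == v)
        if (cnt > 0) {
          p <- (cnt + smoothing) / (tot + smoothing * arity[[g]])
          ll <- ll + cnt * log(p)
        }
      }
    }
  }
  -ll + npar
}

# all DAG parent assignments over `genes` with <= max_parents gene parents
enumerate_dags <- function(genes, max_parents = 2L) {
  parent_sets <- function(g) {
    others <- setdiff(genes, g)
    sets <- list(character(0))
    for (k in seq_len(min(max_parents, length(others)))) {
      cmb <- utils::combn(others, k, simplify = FALSE)
      sets <- c(sets, cmb)
    }
    sets
  }
  per_gene <- lapply(genes, parent_sets)
  grids <- expand.grid(lapply(per_gene, seq_along))
  out <- list()
  for (r in seq_len(nrow(grids))) {
    pa <- stats::setNames(lapply(seq_along(genes), function(i)
      per_gene[[i]][[grids[r, i]]]), genes)
    if (is_acyclic(genes, pa)) out[[length(out) + 1L]] <- Filter(length, pa)
  }
  out
}

is_acyclic <- function(genes, parents) {
  ok <- TRUE
  state <- stats::setNames(rep(0L, length(genes)), genes)
  visit <- function(g) {
    if (state[[g]] == 1L) { ok <<- FALSE; return(invisible()) }
    if (state[[g]] == 2L) return(invisible())
    state[[g]] <<- 1L
    for (p in parents[[g]]) visit(p)
    state[[g]] <<- 2L
  }
  for (g in genes) visit(g)
  ok
}

# pair-counting AUC oracle: P(score_pos > score_neg) + P(tie)/2
pair_count_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# fixture where greedy forward is trapped: class is the XOR of two genes
# (learnable only with a gene-gene edge), plus a moderately predictive decoy
xor_trap_disc <- function(n = 60L, decoy_acc = 0.85, seed = 11L) {
  withr::with_seed(seed, {
    g1 <- sample(0:1, n, replace = TRUE)
    g2 <- sample(0:1, n, replace = TRUE)
    cls <- xor(g1, g2) + 0L
    flip <- stats::runif(n) > decoy_acc
    g3 <- ifelse(flip, 1L - cls, cls)
    codes <- rbind(decoy = g3, xa = g1, xb = g2)
    make_disc(codes, paste0("k", cls), c("k0", "k1"))
  })
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a),
                                                      as.character(b))
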