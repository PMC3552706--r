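#' Build a range-by-class contingency table for one gene
#'
#' Rows are discretized expression ranges in ascending value order, columns
#' are the classes in `class_set` order. Ranges with no samples are dropped
#' and indices compacted.
#'
#' @param gene_codes integer vector of 0-based range codes.
#' @param labels class label per sample.
#' @param class_set ordered class labels.
#' @return an object of class `"contingency_table"`: integer `counts`
#'   (m x n), `row_totals`, `col_totals`, grand total `d`, `m`, `n`.
#' @export
build_contingency <- function(gene_codes, labels, class_set) {
  if (!length(gene_codes)) stop_fmt("empty input")
  if (length(gene_codes) != length(labels))
    stop_fmt("codes (%d) and labels (%d) differ in length",
             length(gene_codes), length(labels))
  f_range <- factor(gene_codes, levels = sort(unique(gene_codes)))
  f_class <- factor(as.character(labels), levels = class_set)
  if (anyNA(f_class)) stop_fmt("labels outside class_set")
  counts <- unclass(table(f_range, f_class))
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  contingency_table(counts)
}

contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop_fmt("negative counts")
  if (ncol(counts) < 2L) stop_fmt("need at least 2 classes")
  if (!nrow(counts) || sum(counts) == 0L) stop_fmt("empty table")
  structure(list(counts = counts, row_totals = rowSums(counts),
                 col_totals = colSums(counts), d = sum(counts),
                 m = nrow(counts), n = ncol(counts)),
            class = "contingency_table")
}

#' Gini impurity of a count vector
#'
#' `1 - sum(p_j^2)` where `p_j` are the class proportions within the range;
#' 0 for a pure range, `1 - 1/n` for a uniform one.
#'
#' @param count_vector non-negative counts with at least one positive entry.
#' @return impurity in `[0, 1)`.
#' @export
gini_impurity <- function(count_vector) {
  s <- sum(count_vector)
  if (s <= 0) stop_fmt("all-zero count vector")
  if (any(count_vector < 0)) stop_fmt("negative counts")
  1 - sum((count_vector / s)^2)
}

#' Standard (unweighted) Gini index of a split
#'
#' The size-weighted average of per-range impurities:
#' `sum_i (|R_i|/d) * gini(R_i)`.
#'
#' @param table a `"contingency_table"`.
#' @return the index value.
#' @export
standard_gini_index <- function(table) {
  sum(vapply(seq_len(table$m), function(i)
    (table$row_totals[i] / table$d) * gini_impurity(table$counts[i, ]),
    numeric(1)))
}

#' Class order by ascending total size
#'
#' Lorenz curves are built over classes sorted so that
#' `|C_1| <= |C_2| <= ... <= |C_n|`; ties keep the original class position
#' (stable sort).
#'
#' @param table a `"contingency_table"`.
#' @return integer permutation of the class columns.
#' @export
class_order <- function(table) {
  order(table$col_totals)  # order() is stable: ties keep original position
}

# Trapezoid area under a piecewise-linear curve through ordinates y at
# x = 0, 1/n, ..., 1 (y includes the leading 0).
lorenz_area <- function(y) {
  n <- length(y) - 1L
  sum((y[-1L] + y[-length(y)]) / 2) / n
}

#' Lorenz coefficient of one range
#'
#' The signed, normalized area difference between the range's Lorenz curve and
#' the Equality Polygon. Both curves are piecewise linear through cumulative
#' class shares at x = 0, 1/n, ..., 1, with the classes taken in the
#' dataset-level [class_order()] (ascending column totals). The Equality
#' Polygon uses the dataset's class totals, the range curve its own counts.
#' Ranges whose count vectors are permutations of one another — identical to
#' the plain Gini impurity — receive different coefficients, which is what
#' removes the class-order bias.
#'
#' @param row_counts counts of one range across classes (in `class_set`
#'   order, as stored in the table).
#' @param table the owning `"contingency_table"`.
#' @return signed coefficient `(area_row - area_Eq) / area_Eq`.
#' @export
lorenz_coefficient <- function(row_counts, table) {
  if (sum(row_counts) <= 0) stop_fmt("empty range")
  ord <- class_order(table)
  eq <- c(0, cumsum(table$col_totals[ord]) / table$d)
  rw <- c(0, cumsum(row_counts[ord]) / sum(row_counts))
  a_eq <- lorenz_area(eq)
  (lorenz_area(rw) - a_eq) / a_eq
}

#' Class-order correction weights (alpha)
#'
#' Absolute Lorenz coefficients `|g_i|`, rescaled to sum to the number of
#' ranges `m` so that equal coefficients reduce the weighted index to the
#' standard one. When every coefficient is zero (each range proportional to
#' the class totals) the weights fall back to 1.
#'
#' @param table a `"contingency_table"`.
#' @return non-negative weight vector of length `m`.
#' @export
alpha_weights <- function(table) {
  a <- abs(lorenz_coefficients(table))
  if (sum(a) > 0) table$m * a / sum(a) else rep(1, table$m)
}

lorenz_coefficients <- function(table) {
  vapply(seq_len(table$m), function(i)
    lorenz_coefficient(table$counts[i, ], table), numeric(1))
}

#' Normalized distance between two ranges' class profiles
#'
#' Half the L1 distance between the class-proportion vectors — 0 for
#' identical profiles, 1 for disjoint class support (the L1 diameter of the
#' probability simplex is 2).
#'
#' @param row_a,row_b count vectors, each with at least one positive entry.
#' @return distance in `[0, 1]`.
#' @export
row_distance <- function(row_a, row_b) {
  sa <- sum(row_a); sb <- sum(row_b)
  if (sa <= 0 || sb <= 0) stop_fmt("zero-total range")
  sum(abs(row_a / sa - row_b / sb)) / 2
}

#' Range-order correction weights (delta)
#'
#' For each range, the mean closeness `1 - distance` to its existing
#' neighbours (one neighbour at the boundary ranges, two inside), so
#' `delta(i)` lies in `[0, 1]` and is large when a range's class profile
#' resembles its neighbours' — the "harmonic" value-order pattern the weight
#' is meant to emphasize. A single-range table gets delta = 1.
#'
#' @param table a `"contingency_table"`.
#' @return weight vector of length `m`.
#' @export
delta_weights <- function(table) {
  m <- table$m
  if (m == 1L) return(1)
  vapply(seq_len(m), function(i) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= m]
    mean(vapply(nb, function(j)
      1 - row_distance(table$counts[i, ], table$counts[j, ]), numeric(1)))
  }, numeric(1))
}

#' Weighted Gini index
#'
#' `sum_i alpha_i * delta_i * (|R_i|/d) * gini(R_i)` — the standard index
#' with both order-bias corrections applied multiplicatively. With both
#' weight vectors forced to 1 it equals [standard_gini_index()].
#'
#' @param table a `"contingency_table"`.
#' @param alpha,delta optional weight overrides (defaults computed from the
#'   table).
#' @return the weighted index.
#' @export
weighted_gini_index <- function(table, alpha = alpha_weights(table),
                                delta = delta_weights(table)) {
  sum(vapply(seq_len(table$m), function(i)
    alpha[i] * delta[i] * (table$row_totals[i] / table$d) *
      gini_impurity(table$counts[i, ]), numeric(1)))
}

#' Splitting status of a table
#'
#' `1 - sum_i (|R_i|/d)^2`: 0 when the gene never splits the samples, close
#' to 1 for many equal ranges. Used to normalize the impurity reduction.
#'
#' @param table a `"contingency_table"`.
#' @return value in `[0, 1)`.
#' @export
split_status <- function(table) {
  1 - sum((table$row_totals / table$d)^2)
}

#' Full LorenzGini score of one contingency table
#'
#' Computes every component of the ranking statistic: the dataset impurity
#' `gini(D) = 1 - sum_j (|C_j|/d)^2`, the standard and weighted Gini indexes,
#' the alpha and delta weight vectors with the signed Lorenz coefficients,
#' the splitting status, the impurity reduction
#' `delta_gini = gini(D) - gini_A(D)` (using the weighted index), and the
#' final ratio `lorenzgini = delta_gini / split`. A single-range table
#' (split = 0) scores 0 by convention: an attribute that never splits carries
#' no information.
#'
#' @param table a `"contingency_table"`.
#' @return an object of class `"gene_score"` with fields `gini_D`,
#'   `gini_A_standard`, `gini_A_weighted`, `alpha`, `delta`,
#'   `lorenz_coefficients`, `split`, `delta_gini`, `lorenzgini`.
#' @export
lorenzgini_score <- function(table) {
  gini_D <- 1 - sum((table$col_totals / table$d)^2)
  g <- lorenz_coefficients(table)
  alpha <- alpha_weights(table)
  delta <- delta_weights(table)
  std <- standard_gini_index(table)
  wtd <- weighted_gini_index(table, alpha, delta)
  split <- split_status(table)
  dg <- gini_D - wtd
  structure(list(gini_D = gini_D, gini_A_standard = std,
                 gini_A_weighted = wtd, alpha = alpha, delta = delta,
                 lorenz_coefficients = g, split = split, delta_gini = dg,
                 lorenzgini = if (split > 0) dg / split else 0),
            class = "gene_score")
}

#' @export
print.gene_score <- function(x, ...) {
  cat(sprintf("LorenzGini %.6f  (delta_gini %.6f / split %.6f)\n",
              x$lorenzgini, x$delta_gini, x$split))
  cat(sprintf("gini(D) %.6f, standard index %.6f, weighted index %.6f\n",
              x$gini_D, x$gini_A_standard, x$gini_A_weighted))
  invisible(x)
}

#' Rank all genes by LorenzGini
#'
#' Scores every gene of a discretized matrix and returns the top `top_k` in
#' descending score order. Ties are broken lexicographically by gene id so
#' the ranking is deterministic and invariant to input gene order.
#'
#' @param disc a `"discretized_matrix"`.
#' @param top_k number of genes to keep (default 250, the pre-selection size
#'   used upstream of the wrapper search).
#' @return a data frame (one row per gene, best first) with columns
#'   `gene_id`, `lorenzgini`, `delta_gini`, `split`, `gini_standard`,
#'   `gini_weighted`, `gini_D`, `m_ranges`.
#' @export
rank_genes <- function(disc, top_k = 250L) {
  stopifnot(inherits(disc, "discretized_matrix"), top_k >= 1L)
  scores <- lapply(seq_along(disc$gene_ids), function(g)
    lorenzgini_score(build_contingency(disc$codes[g, ], disc$labels,
                                       disc$class_set)))
  df <- data.frame(
    gene_id = disc$gene_ids,
    lorenzgini = vapply(scores, `[[`, numeric(1), "lorenzgini"),
    delta_gini = vapply(scores, `[[`, numeric(1), "delta_gini"),
    split = vapply(scores, `[[`, numeric(1), "split"),
    gini_standard = vapply(scores, `[[`, numeric(1), "gini_A_standard"),
    gini_weighted = vapply(scores, `[[`, numeric(1), "gini_A_weighted"),
    gini_D = vapply(scores, `[[`, numeric(1), "gini_D"),
    m_ranges = vapply(scores, function(s) length(s$alpha), numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(-df$lorenzgini, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}
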