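test_that("contingency tables are built and compacted correctly", {
  t <- build_contingency(c(0L, 0L, 1L), c("A", "A", "B"), c("A", "B"))
  expect_equal(unname(t$counts), rbind(c(2L, 0L), c(0L, 1L)))
  t1 <- table1_fixture()
  expect_equal(unname(t1$row_totals), c(40, 40, 20))
  expect_equal(unname(t1$col_totals), c(10, 40, 50))
  expect_identical(t1$d, 100L)
  # all codes equal: one row equal to the column totals
  t0 <- build_contingency(rep(0L, 5), c("A", "A", "B", "B", "B"),
                          c("A", "B"))
  expect_identical(t0$m, 1L)
  expect_equal(unname(t0$counts[1, ]), c(2L, 3L))
  # gaps in codes are compacted
  tg <- build_contingency(c(0L, 5L, 5L), c("A", "B", "B"), c("A", "B"))
  expect_identical(tg$m, 2L)
  expect_error(build_contingency(integer(0), character(0), c("A", "B")),
               "empty")
})

test_that("gini impurity matches hand values", {
  expect_equal(gini_impurity(c(4, 6, 30)), 0.405)
  expect_equal(gini_impurity(c(0, 0, 16)), 0)
  expect_equal(gini_impurity(c(10, 10, 10)), 2 / 3)
  expect_error(gini_impurity(c(0, 0, 0)), "zero")
})

test_that("the standard index reproduces the class-order-bias example", {
  t1 <- table1_fixture()
  expect_equal(standard_gini_index(t1), 0.388, tolerance = 1e-12)
  # the two impure rows contribute identically -- the bias being corrected
  c1 <- (t1$row_totals[1] / t1$d) * gini_impurity(t1$counts[1, ])
  c2 <- (t1$row_totals[2] / t1$d) * gini_impurity(t1$counts[2, ])
  expect_identical(unname(c1), unname(c2))
  # single-row table reduces to the row impurity
  t0 <- build_contingency(rep(0L, 6), rep(c("A", "B"), 3), c("A", "B"))
  expect_equal(standard_gini_index(t0), gini_impurity(c(3, 3)))
})

test_that("class order sorts totals ascending with a stable tie-break", {
  expect_identical(class_order(table1_fixture()), 1:3)
  t <- table_from_rows(list(c(30L, 5L, 20L), c(20L, 5L, 20L)))
  expect_identical(class_order(t), c(2L, 3L, 1L))  # totals (50, 10, 40)
  teq <- table_from_rows(list(c(5L, 5L, 5L), c(5L, 5L, 5L)))
  expect_identical(class_order(teq), 1:3)
})

test_that("Lorenz coefficients separate the equally-contributing rows", {
  t1 <- table1_fixture()
  g1 <- lorenz_coefficient(t1$counts[1, ], t1)
  g2 <- lorenz_coefficient(t1$counts[2, ], t1)
  g3 <- lorenz_coefficient(t1$counts[3, ], t1)
  expect_equal(g1, (0.85 - 1.1) / 1.1, tolerance = 1e-12)  # -0.227273
  expect_equal(g2, (1.55 - 1.1) / 1.1, tolerance = 1e-12)  # +0.409091
  expect_equal(g3, (0.7 - 1.1) / 1.1, tolerance = 1e-12)   # -0.363636
  expect_true(g1 != g2)
  # a row proportional to the class totals lies on the Equality Polygon
  tp <- table_from_rows(list(c(1L, 4L, 5L), c(2L, 8L, 10L)))
  expect_equal(lorenz_coefficient(tp$counts[1, ], tp), 0, tolerance = 1e-12)
})

test_that("alpha weights are |g| scaled to sum to m, with uniform fallback", {
  t1 <- table1_fixture()
  a <- alpha_weights(t1)
  g_abs <- c(0.25, 0.45, 0.4) / 1.1
  expect_equal(a, 3 * g_abs / sum(g_abs), tolerance = 1e-12)
  tp <- table_from_rows(list(c(1L, 4L, 5L), c(2L, 8L, 10L)))
  expect_equal(alpha_weights(tp), c(1, 1), tolerance = 1e-12)
  t0 <- build_contingency(rep(0L, 4), rep(c("A", "B"), 2), c("A", "B"))
  expect_equal(alpha_weights(t0), 1)
})

test_that("row distance is the half-L1 between class proportions", {
  expect_equal(row_distance(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(row_distance(c(2, 4, 6), c(1, 2, 3)), 0)
  expect_equal(row_distance(c(3, 0, 0), c(4, 0, 0)), 0)
  expect_error(row_distance(c(0, 0), c(1, 1)), "zero")
})

test_that("delta weights realize the range-order-bias correction", {
  expect_equal(delta_weights(table2_left()), c(0, 0, 0, 0))
  dr <- delta_weights(table2_right())
  expect_equal(dr, c(1, 0.5, 0, 0))
  expect_gt(sum(dr), sum(delta_weights(table2_left())))
  tsame <- table_from_rows(list(c(2L, 2L, 0L), c(4L, 4L, 0L), c(1L, 1L, 0L)))
  expect_equal(delta_weights(tsame), c(1, 1, 1))
  t0 <- build_contingency(rep(0L, 4), rep(c("A", "B"), 2), c("A", "B"))
  expect_equal(delta_weights(t0), 1)
})

test_that("the weighted index reduces to the standard one under uniform
           weights (1000 random tables)", {
  withr::with_seed(101L, {
    for (i in 1:1000) {
      t <- random_table()
      w <- weighted_gini_index(t, alpha = rep(1, t$m), delta = rep(1, t$m))
      expect_equal(w, standard_gini_index(t), tolerance = 1e-12)
    }
  })
})

test_that("both range-order-bias genes have identical printed-formula scores
           (pure rows) while delta differs", {
  expect_equal(standard_gini_index(table2_left()), 0)
  expect_equal(standard_gini_index(table2_right()), 0)
  expect_equal(split_status(table2_left()), split_status(table2_right()))
  expect_equal(weighted_gini_index(table2_left()), 0)
  expect_equal(weighted_gini_index(table2_right()), 0)
})

test_that("splitting status matches its closed forms", {
  expect_equal(split_status(table1_fixture()), 0.64, tolerance = 1e-12)
  t0 <- build_contingency(rep(0L, 4), rep(c("A", "B"), 2), c("A", "B"))
  expect_equal(split_status(t0), 0)
  tm <- table_from_rows(list(c(5L, 5L), c(5L, 5L), c(5L, 5L), c(5L, 5L)))
  expect_equal(split_status(tm), 1 - 1 / 4, tolerance = 1e-12)
})

test_that("the full score composes its verified pieces", {
  t1 <- table1_fixture()
  s <- lorenzgini_score(t1)
  expect_equal(s$gini_D, 0.58, tolerance = 1e-12)
  expect_equal(s$split, 0.64, tolerance = 1e-12)
  expect_equal((s$gini_D - s$gini_A_standard) / s$split, 0.3,
               tolerance = 1e-12)
  # weighted value departs from the standard one when weights are non-uniform
  expect_false(isTRUE(all.equal(s$gini_A_weighted, s$gini_A_standard)))
  t0 <- build_contingency(rep(0L, 4), rep(c("A", "B"), 2), c("A", "B"))
  expect_equal(lorenzgini_score(t0)$lorenzgini, 0)
})

test_that("scores are invariant under joint class/label permutation", {
  withr::with_seed(55L, {
    for (i in 1:50) {
      t <- random_table()
      if (anyDuplicated(t$col_totals)) next  # stable tie-break caveat
      perm <- sample(t$n)
      counts <- t$counts[, perm, drop = FALSE]
      tp <- table_from_rows(asplit(counts, 1L))
      expect_equal(lorenzgini_score(tp)$lorenzgini,
                   lorenzgini_score(t)$lorenzgini, tolerance = 1e-12)
    }
  })
})

test_that("ranking puts a perfectly predictive gene first among noise", {
  withr::with_seed(77L, {
    n <- 60L
    labels <- rep(c("A", "B", "C"), each = 20L)
    codes <- rbind(matrix(sample(0:2, 99 * n, replace = TRUE), 99, n),
                   rep(0:2, each = 20L))
    rownames(codes) <- c(sprintf("noise%02d", 1:99), "signal")
    disc <- make_disc(codes, labels, c("A", "B", "C"))
    ranking <- rank_genes(disc, top_k = 100L)
    expect_identical(ranking$gene_id[1L], "signal")
    # brute-force check: no other gene scores higher
    scores <- vapply(seq_len(100), function(g)
      lorenzgini_score(build_contingency(codes[g, ], labels,
                                         c("A", "B", "C")))$lorenzgini,
      numeric(1))
    expect_equal(max(scores), ranking$lorenzgini[1L])
  })
})

test_that("ranking ties break alphabetically and top_k caps gracefully", {
  codes <- rbind(zeta = c(0L, 0L, 1L, 1L), alpha = c(0L, 0L, 1L, 1L))
  disc <- make_disc(codes, c("A", "A", "B", "B"))
  ranking <- rank_genes(disc, top_k = 10L)
  expect_identical(ranking$gene_id, c("alpha", "zeta"))
  expect_identical(nrow(ranking), 2L)
  expect_identical(ranking$lorenzgini[1L], ranking$lorenzgini[2L])
})

test_that("ranking order is invariant to input gene order", {
  withr::with_seed(31L, {
    codes <- matrix(sample(0:2, 20 * 30, replace = TRUE), 20, 30)
    rownames(codes) <- sprintf("g%02d", 1:20)
    labels <- rep(c("A", "B"), 15)
    r1 <- rank_genes(make_disc(codes, labels), top_k = 20L)
    perm <- sample(20)
    r2 <- rank_genes(make_disc(codes[perm, , drop = FALSE], labels),
                     top_k = 20L)
    expect_identical(r1$gene_id, r2$gene_id)
    expect_equal(r1$lorenzgini, r2$lorenzgini, tolerance = 1e-15)
  })
})
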