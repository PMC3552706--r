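test_that("CPT estimation applies the smoothing formula", {
  # one gene, class parent only; class A counts (9, 1) over values (0, 1)
  codes <- matrix(c(rep(0L, 9), 1L, rep(0L, 5), rep(1L, 5)), 1,
                  dimnames = list("g1", NULL))
  disc <- make_disc(codes, rep(c("A", "B"), each = 10L))
  raw <- bayesnet_fit(disc, smoothing = 0)
  expect_equal(raw$cpts$g1[1, 1], 0.9)                 # P(0 | A)
  sm <- bayesnet_fit(disc, smoothing = 0.5)
  expect_equal(sm$cpts$g1[1, 1], 9.5 / 11, tolerance = 1e-12)
  # every CPT row is a distribution
  expect_equal(colSums(sm$cpts$g1), c(1, 1), tolerance = 1e-9)
  expect_error(bayesnet_fit(disc, genes = "nope"), "absent")
})

test_that("an unobserved parent combination gets a uniform smoothed row", {
  codes <- rbind(g1 = c(0L, 0L, 1L, 1L), g2 = c(0L, 1L, 0L, 1L))
  disc <- make_disc(codes, c("A", "A", "B", "B"))
  fit <- bayesnet_fit(disc, parents = list(g2 = "g1"), smoothing = 0.5)
  # class A never occurs with g1 = 1: P(g2 | A, g1 = 1) must be uniform
  expect_equal(fit$cpts$g2[, 1, 2], c(0.5, 0.5))
})

test_that("AIC equals its closed form for a saturated single node and grows
           with useless parameters", {
  codes <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L), 1, dimnames = list("g1", NULL))
  disc <- make_disc(codes, rep(c("A", "B"), 3L))
  fit <- bayesnet_fit(disc, smoothing = 0)
  # parameters: class prior (1) + (3 - 1) * 2 classes = 5
  expect_identical(fit$n_parameters, 5)
  expect_equal(fit$aic, -fit$loglik + 5)
  # a second gene that duplicates g1 with an added edge costs parameters
  codes2 <- rbind(codes, g2 = codes[1, ])
  disc2 <- make_disc(codes2, rep(c("A", "B"), 3L), gene_ids = c("g1", "g2"))
  naive <- bayesnet_fit(disc2, smoothing = 0)
  edged <- bayesnet_fit(disc2, parents = list(g2 = "g1"), smoothing = 0)
  expect_gt(edged$n_parameters, naive$n_parameters)
  # an edge that leaves every fitted probability unchanged still pays its
  # parameter cost, so the AIC strictly increases
  codes3 <- rbind(g1 = c(0L, 0L, 1L, 1L), g2 = c(0L, 1L, 0L, 1L))
  disc3 <- make_disc(codes3, c("A", "A", "B", "B"))
  plain <- bayesnet_fit(disc3, smoothing = 0)
  extra <- bayesnet_fit(disc3, parents = list(g2 = "g1"), smoothing = 0)
  expect_equal(extra$loglik, plain$loglik, tolerance = 1e-12)
  expect_gt(extra$aic, plain$aic)
})

test_that("AIC agrees with a brute-force oracle over every DAG on 3 genes", {
  withr::with_seed(13L, {
    codes <- rbind(a = sample(0:1, 40, replace = TRUE),
                   b = sample(0:2, 40, replace = TRUE),
                   c = sample(0:1, 40, replace = TRUE))
    disc <- make_disc(codes, rep(c("A", "B"), 20L))
  })
  dags <- enumerate_dags(c("a", "b", "c"), max_parents = 2L)
  expect_gte(length(dags), 20L)
  expect_lte(length(dags), 25L)
  for (pa in dags) {
    fit <- bayesnet_fit(disc, genes = c("a", "b", "c"), parents = pa,
                        smoothing = 0.5)
    expect_equal(fit$aic,
                 brute_force_aic(disc, c("a", "b", "c"), pa, 0.5),
                 tolerance = 1e-9)
  }
})

test_that("cyclic parent structures are rejected", {
  codes <- rbind(g1 = c(0L, 1L, 0L, 1L), g2 = c(0L, 0L, 1L, 1L))
  disc <- make_disc(codes, c("A", "A", "B", "B"))
  expect_error(bayesnet_fit(disc, parents = list(g1 = "g2", g2 = "g1")),
               "cycle")
})

test_that("structure search adds an edge only for dependent genes", {
  withr::with_seed(17L, {
    n <- 2000L
    cls <- sample(c("A", "B"), n, replace = TRUE)
    p <- ifelse(cls == "A", 0.2, 0.8)
    g1 <- rbinom(n, 1L, p)
    # conditionally independent given class
    g2_ind <- rbinom(n, 1L, p)
    disc_ind <- make_disc(rbind(g1 = g1, g2 = g2_ind), cls, c("A", "B"))
    fit_ind <- learn_structure(disc_ind, max_parents = 1L)
    expect_identical(sum(lengths(fit_ind$parents)), 0L)
    # near-deterministic copy: the edge pays for itself
    flip <- runif(n) < 0.01
    g2_cop <- ifelse(flip, 1L - g1, g1)
    disc_cop <- make_disc(rbind(g1 = g1, g2 = g2_cop), cls, c("A", "B"))
    fit_cop <- learn_structure(disc_cop, max_parents = 1L)
    expect_identical(fit_cop$parents$g2, "g1")
  })
})

test_that("max_parents = 0 always returns the naive structure", {
  withr::with_seed(19L, {
    codes <- rbind(g1 = sample(0:1, 50, TRUE), g2 = sample(0:1, 50, TRUE))
    disc <- make_disc(codes, rep(c("A", "B"), 25L))
    fit <- learn_structure(disc, max_parents = 0L)
    expect_identical(sum(lengths(fit$parents)), 0L)
  })
})

test_that("structure search returns acyclic graphs on random datasets", {
  withr::with_seed(23L, {
    for (i in 1:300) {
      ng <- sample(2:4, 1L)
      n <- sample(c(20L, 40L), 1L)
      codes <- matrix(sample(0:1, ng * n, replace = TRUE), ng, n)
      rownames(codes) <- paste0("g", seq_len(ng))
      disc <- make_disc(codes, sample(c("A", "B"), n, replace = TRUE),
                        c("A", "B"))
      fit <- learn_structure(disc, max_parents = 2L)
      expect_true(is_acyclic(fit$genes, fit$parents))
    }
  })
})

test_that("the worked-example joint probability matches the printed factors", {
  m <- generate_worked_example_model()
  inst <- stats::setNames(rep(0L, 9), m$genes)
  j <- joint_probability(m, inst, "normal")
  expect_equal(signif(j, 4), 4.455e-9)
  expect_equal(j, prod(c(0.95, 0.92, 0.03, 0.92, 0.95, 0.03, 0.08, 0.03,
                         0.03)) * 0.09, tolerance = 1e-15)
  # a class with zero prior has zero joint
  m0 <- m
  m0$class_priors[["carcinoid"]] <- 0
  expect_equal(joint_probability(m0, inst, "carcinoid"), 0)
  expect_error(joint_probability(m, stats::setNames(rep(5L, 9), m$genes),
                                 "normal"), "out of range")
})

test_that("prediction follows the largest joint, squamous in the worked
           example", {
  m <- generate_worked_example_model()
  inst <- stats::setNames(rep(0L, 9), m$genes)
  joints <- vapply(m$class_set, function(cl) joint_probability(m, inst, cl),
                   numeric(1))
  expect_identical(names(which.max(joints)), "squamous")
  pred <- predict(m, inst)
  expect_identical(pred$class, "squamous")
  expect_equal(sum(pred$posterior), 1, tolerance = 1e-12)
  expect_equal(unname(pred$posterior[1, ]), unname(joints / sum(joints)),
               tolerance = 1e-12)
})

test_that("equal joints break ties by class order; posteriors stay positive
           with smoothing", {
  codes <- matrix(c(0L, 1L, 0L, 1L), 1, dimnames = list("g1", NULL))
  disc <- make_disc(codes, c("A", "A", "B", "B"))
  fit <- bayesnet_fit(disc, smoothing = 0.5)  # symmetric: joints equal
  pred <- predict(fit, c(g1 = 0L))
  expect_identical(pred$class, "A")
  expect_true(all(pred$posterior > 0))
})

test_that("posteriors equal brute-force joint enumeration on small binary
           networks", {
  withr::with_seed(29L, {
    for (rep in 1:10) {
      ng <- sample(2:4, 1L)
      n <- 60L
      codes <- matrix(sample(0:1, ng * n, replace = TRUE), ng, n)
      rownames(codes) <- paste0("g", seq_len(ng))
      disc <- make_disc(codes, sample(c("A", "B", "C"), n, replace = TRUE),
                        c("A", "B", "C"))
      pa <- if (ng >= 2L) list(g2 = "g1") else list()
      fit <- bayesnet_fit(disc, parents = pa, smoothing = 0.5)
      inst <- stats::setNames(sample(0:1, ng, replace = TRUE),
                              paste0("g", seq_len(ng)))
      expect_equal(unname(predict(fit, inst)$posterior[1, ]),
                   unname(brute_force_posterior(fit, inst)),
                   tolerance = 1e-10)
    }
  })
})
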