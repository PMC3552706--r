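#' Specification for a synthetic expression matrix
#'
#' Defaults emulate the data regime the method targets: thousands of genes
#' for a few hundred samples, strongly unbalanced class sizes (the default
#' 139/21/20/17 shape: one dominant tumour subtype, two small subtypes, a
#' small normal group), a handful of informative genes with class-dependent
#' mean shifts, blocks of correlated (redundant) informative genes, and
#' Gaussian within-class noise.
#'
#' @param n_genes total genes (default 2000).
#' @param class_sizes samples per class (default `c(139, 21, 20, 17)`).
#' @param n_informative genes with class-dependent means (default 20).
#' @param effect between-class mean shift in within-class SD units
#'   (default 2).
#' @param sd within-class standard deviation (default 1).
#' @param n_correlated_blocks number of correlated blocks among the
#'   informative genes (default 2).
#' @param block_size genes per block (default 4).
#' @param block_correlation shared-factor correlation within a block, in
#'   `[0, 1)` (default 0.8).
#' @param log_normal exponentiate the values (off by default).
#' @param seed integer seed.
#' @return a list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 2000L, class_sizes = c(139L, 21L, 20L, 17L),
                           n_informative = 20L, effect = 2, sd = 1,
                           n_correlated_blocks = 2L, block_size = 4L,
                           block_correlation = 0.8, log_normal = FALSE,
                           seed = 1L) {
  if (n_informative > n_genes) stop_fmt("n_informative > n_genes")
  if (any(class_sizes < 1L)) stop_fmt("every class needs >= 1 sample")
  if (block_correlation < 0 || block_correlation >= 1)
    stop_fmt("block_correlation must be in [0, 1)")
  if (n_correlated_blocks * block_size > n_informative)
    stop_fmt("correlated blocks (%d x %d) exceed n_informative (%d)",
             n_correlated_blocks, block_size, n_informative)
  structure(list(n_genes = as.integer(n_genes),
                 class_sizes = as.integer(class_sizes),
                 n_informative = as.integer(n_informative),
                 effect = effect, sd = sd,
                 n_correlated_blocks = as.integer(n_correlated_blocks),
                 block_size = as.integer(block_size),
                 block_correlation = block_correlation,
                 log_normal = log_normal, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' Informative genes get class-specific means: each draws a random
#' permutation of `0..(n_classes-1)` scaled by `effect * sd`, so every class
#' pair is separated by at least one effect unit on that gene. Genes inside a
#' correlated block share one class-mean profile and a per-sample latent
#' factor mixed at the requested correlation, making them redundant
#' high-ranking markers. Noise genes are class-independent Gaussian.
#' Everything is deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (an [expression_matrix]), `informative`
#'   (gene ids), and `class_means` (informative genes x classes).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_class <- length(spec$class_sizes)
  n <- sum(spec$class_sizes)
  classes <- paste0("class", seq_len(n_class))
  labels <- rep(classes, spec$class_sizes)
  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  sample_ids <- sprintf("sample%03d", seq_len(n))
  with_seed(spec$seed, {
    vals <- matrix(stats::rnorm(spec$n_genes * n, 0, spec$sd),
                   spec$n_genes, n, dimnames = list(gene_ids, sample_ids))
    info <- seq_len(spec$n_informative)
    # block membership: first n_correlated_blocks * block_size informative
    # genes form the blocks, the rest are independent informative genes
    block_of <- rep(NA_integer_, spec$n_informative)
    if (spec$n_correlated_blocks > 0L)
      block_of[seq_len(spec$n_correlated_blocks * spec$block_size)] <-
        rep(seq_len(spec$n_correlated_blocks), each = spec$block_size)
    class_means <- matrix(0, spec$n_informative, n_class,
                          dimnames = list(gene_ids[info], classes))
    block_profile <- lapply(seq_len(max(spec$n_correlated_blocks, 1L)),
                            function(b) sample(n_class) - 1L)
    block_factor <- lapply(seq_len(max(spec$n_correlated_blocks, 1L)),
                           function(b) stats::rnorm(n, 0, spec$sd))
    rho <- spec$block_correlation
    for (g in info) {
      b <- block_of[g]
      prof <- if (is.na(b)) sample(n_class) - 1L else block_profile[[b]]
      class_means[g, ] <- spec$effect * spec$sd * prof
      mu <- class_means[g, match(labels, classes)]
      noise <- if (is.na(b)) {
        stats::rnorm(n, 0, spec$sd)
      } else {
        sqrt(rho) * block_factor[[b]] +
          sqrt(1 - rho) * stats::rnorm(n, 0, spec$sd)
      }
      vals[g, ] <- mu + noise
    }
    if (spec$log_normal) vals <- exp(vals)
    list(matrix = expression_matrix(vals, labels = labels,
                                    class_set = classes),
         informative = gene_ids[info],
         class_means = class_means)
  })
}

#' The nine-gene worked-example network
#'
#' A naive-structure network over nine binary marker genes and four classes
#' (normal, adenocarcinoma, squamous, carcinoid) whose conditional
#' probabilities for the all-zero instance given class "normal" are the nine
#' reference factors 0.95, 0.92, 0.03, 0.92, 0.95, 0.03, 0.08, 0.03, 0.03
#' with class prior 0.09, so the all-zero/normal joint probability is
#' 0.4454e-8. Entries not pinned down by those factors are synthetic
#' completions chosen so that CPT rows and priors are proper distributions
#' and the all-zero instance is classified as squamous (its joint is made the
#' largest, with the adenocarcinoma joint exactly zero).
#'
#' @return a `"bayesnet"` with nine binary gene nodes.
#' @export
generate_worked_example_model <- function() {
  genes <- c("JAG1", "MET", "CDH5", "ABCC3", "DSP", "ABCD3", "PECAM1",
             "MAPRE2", "PDF5")
  class_set <- c("normal", "adenocarcinoma", "squamous", "carcinoid")
  normal_f <- c(0.95, 0.92, 0.03, 0.92, 0.95, 0.03, 0.08, 0.03, 0.03)
  priors <- c(normal = 0.09, adenocarcinoma = 0.70, squamous = 0.11,
              carcinoid = 0.10)
  # per-class P(gene = 0 | class): squamous/carcinoid chosen to give joints
  # of 0.3615e-4 and 0.2647e-10 scale; adenocarcinoma zero on the first gene
  sq_f <- rep((0.3615e-4 / priors[["squamous"]])^(1 / 9), 9)
  ca_f <- rep((0.2647e-10 / priors[["carcinoid"]])^(1 / 9), 9)
  ad_f <- c(0, rep(0.5, 8))
  cpts <- lapply(seq_along(genes), function(i) {
    p0 <- c(normal_f[i], ad_f[i], sq_f[i], ca_f[i])
    array(rbind(p0, 1 - p0), dim = c(2L, 4L))
  })
  names(cpts) <- genes
  model <- structure(list(genes = genes, class_set = class_set,
                          parents = list(),
                          arity = stats::setNames(rep(2L, 9), genes),
                          cpts = cpts, class_priors = priors, smoothing = 0,
                          boundaries = list(), format_version = 1L,
                          loglik = NA_real_, aic = NA_real_),
                     class = "bayesnet")
  model$n_parameters <- bn_n_parameters(model)
  model
}
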