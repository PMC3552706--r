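#' Serialize a fitted network to self-describing JSON text
#'
#' The file records a format-version field, the node set, parent sets,
#' arities, every CPT (flattened with its dimensions, written at full decimal
#' precision so a round-trip is bit-exact at >= 15 significant digits), class
#' priors, the smoothing pseudo-count, and any stored discretization
#' boundaries needed to code new continuous samples.
#'
#' @param model a `"bayesnet"`.
#' @param path output file.
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "bayesnet"))
  obj <- list(
    format = "lorenzgini-bayesnet",
    format_version = model$format_version %||% 1L,
    genes = model$genes,
    class_set = model$class_set,
    arity = as.list(model$arity),
    parents = if (length(model$parents)) model$parents else NULL,
    class_priors = as.numeric(model$class_priors),
    smoothing = model$smoothing,
    cpts = lapply(model$cpts, function(a)
      list(dim = dim(a), values = as.numeric(a))),
    boundaries = lapply(model$boundaries, as.numeric),
    loglik = model$loglik,
    n_parameters = model$n_parameters,
    aic = model$aic
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a serialized network
#'
#' @param path file written by [serialize_model()].
#' @return the reconstructed `"bayesnet"`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_fmt("cannot deserialize '%s': %s", path,
                             conditionMessage(e)))
  req <- c("format", "genes", "class_set", "arity", "class_priors", "cpts")
  if (!is.list(obj) || !all(req %in% names(obj)) ||
      !identical(obj$format, "lorenzgini-bayesnet"))
    stop_fmt("'%s' is not a valid model file", path)
  genes <- as.character(obj$genes)
  cpts <- lapply(obj$cpts, function(x)
    array(as.numeric(x$values), dim = as.integer(x$dim)))
  names(cpts) <- genes
  parents <- lapply(obj$parents, as.character)
  boundaries <- lapply(obj$boundaries, as.numeric)
  structure(list(genes = genes,
                 class_set = as.character(obj$class_set),
                 parents = Filter(length, parents),
                 arity = unlist(obj$arity)[genes],
                 cpts = cpts,
                 class_priors = stats::setNames(as.numeric(obj$class_priors),
                                                as.character(obj$class_set)),
                 smoothing = obj$smoothing,
                 boundaries = boundaries,
                 format_version = obj$format_version,
                 loglik = obj$loglik,
                 n_parameters = obj$n_parameters,
                 aic = obj$aic),
            class = "bayesnet")
}
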