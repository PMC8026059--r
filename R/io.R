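# Serialization: model checkpoints, feature-tensor containers, score tables.
# The container format is R's native serialization with an explicit header
# list, so a checkpoint is self-describing (configuration and shapes travel
# with the numbers).

#' Save a model checkpoint
#'
#' Writes a self-describing container holding the network configuration and
#' all parameters; [load_model()] restores a functional `coev_model`.
#'
#' @param model A `coev_model` (or `coev_fit`, whose model is saved).
#' @param path Output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "coev_fit")) model <- model$model
  stopifnot(inherits(model, "coev_model"))
  saveRDS(list(container = "coevnet_model", version = 1L,
               cfg = model$cfg, params = as.list(model$params)),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_model()].
#' @return A `coev_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container, "coevnet_model"))
    stop("not a coevnet model checkpoint")
  model <- build_model(obj$cfg)
  for (nm in names(obj$params)) model$params[[nm]] <- obj$params[[nm]]
  model
}

#' Save feature tensors
#'
#' Stores a named list of `L x L x 441` arrays (as produced by
#' [coev_features()]) with shape metadata.
#'
#' @param tensors Named list of feature arrays.
#' @param path Output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_features <- function(tensors, path) {
  stopifnot(is.list(tensors), length(names(tensors)) == length(tensors))
  saveRDS(list(container = "coevnet_features", version = 1L,
               shapes = lapply(tensors, dim),
               neff = attr(tensors, "neff"),
               tensors = tensors),
          path)
  invisible(path)
}

#' Load feature tensors written by [write_features()]
#'
#' @param path File path.
#' @return Named list of feature arrays (with `neff` attribute if stored).
#' @export
read_features <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container, "coevnet_features"))
    stop("not a coevnet feature container")
  out <- obj$tensors
  attr(out, "neff") <- obj$neff
  out
}

#' Write a pair-score map as TSV
#'
#' One row per unordered pair (i < j) above the minimum separation, ranked
#' by score.
#'
#' @param ps A `coev_pairscore`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(ps, path) {
  stopifnot(inherits(ps, "coev_pairscore"))
  top <- rank_contacts(ps$scores, range = "all", depth = Inf)
  names(top)[names(top) == "probability"] <- "score"
  top$method <- ps$method
  top$apc <- ps$apc_applied
  utils::write.table(top, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
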