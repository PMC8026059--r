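# End-to-end orchestration: simulate -> features -> train -> predict ->
# evaluate, with a reproducibility manifest. Every stage draws its seed
# deterministically from the master seed.

#' Pipeline run configuration
#'
#' @param master_seed Single integer from which every stage seed derives.
#' @param out_dir Output directory (created; artifacts are written here).
#' @param n_train,n_test Number of simulated training / held-out proteins.
#' @param sim A [sim_config()] template; its `seed` is overridden per
#'   protein.
#' @param net A [net_config()] template; its `seed` is overridden by the
#'   master seed.
#' @param features Feature subset used by the model.
#' @param loss `"distance"` or `"binary"`.
#' @param epochs Training epochs.
#' @param plm_maxit PLM iteration cap during corpus building.
#' @param write_artifacts Write alignments/structures/predictions to
#'   `out_dir` (default TRUE).
#' @return List of class `coev_run_config`.
#' @export
run_config <- function(master_seed = 1L, out_dir = tempfile("coevnet_run_"),
                       n_train = 8L, n_test = 3L,
                       sim = sim_config(L = 30L, N = 200L),
                       net = net_config(),
                       features = c("cov", "pre", "plm"),
                       loss = c("distance", "binary"),
                       epochs = 10L, plm_maxit = 100L,
                       write_artifacts = TRUE) {
  loss <- match.arg(loss)
  features <- match.arg(features, c("cov", "pre", "plm"), several.ok = TRUE)
  structure(list(master_seed = as.integer(master_seed), out_dir = out_dir,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 sim = sim, net = net, features = features, loss = loss,
                 epochs = as.integer(epochs), plm_maxit = as.integer(plm_maxit),
                 write_artifacts = isTRUE(write_artifacts)),
            class = "coev_run_config")
}

# serialize a config into a stable hashable list
.config_digest <- function(cfg) {
  rlang::hash(list(cfg$master_seed, cfg$n_train, cfg$n_test,
                   unclass(cfg$sim), unclass(cfg$net), cfg$features,
                   cfg$loss, cfg$epochs, cfg$plm_maxit))
}

# write one simulated protein's artifacts as plain text
.write_sim_artifacts <- function(sim, dir, tag) {
  write_alignment(sim$alignment, file.path(dir, paste0(tag, ".fasta")))
  L <- nrow(sim$structure$coords)
  bio3d::write.pdb(file = file.path(dir, paste0(tag, ".pdb")),
                   xyz = as.vector(t(sim$structure$coords)),
                   resno = seq_len(L), resid = rep("ALA", L),
                   elety = rep("CB", L), chain = rep("A", L))
  utils::write.table(round(structure_distances(sim$structure), 4),
                     file.path(dir, paste0(tag, "_dist.tsv")),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a corpus of toy proteins, extracts the raw feature triplet,
#' trains the distogram network, predicts contacts on held-out proteins, and
#' evaluates them CASP-style. Writes alignments (FASTA), structures (PDB),
#' distance matrices (TSV), predictions (RR), an evaluation table (TSV) and
#' a JSON manifest with the config hash and all derived seeds. Rerunning
#' with the same configuration reproduces all numbers.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress.
#' @return List of class `coev_run`: `fit` (a `coev_fit`), `evaluation`
#'   (tibble over held-out targets), `manifest`, `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "coev_run_config"))
  if (cfg$write_artifacts) dir.create(cfg$out_dir, recursive = TRUE,
                                      showWarnings = FALSE)
  n_total <- cfg$n_train + cfg$n_test
  say <- function(...) if (verbose) cat(sprintf(...), "\n")

  say("simulating %d proteins (L = %d, N = %d)", n_total, cfg$sim$L, cfg$sim$N)
  examples <- vector("list", n_total)
  for (p in seq_len(n_total)) {
    scfg <- cfg$sim
    scfg$seed <- derive_seed(cfg$master_seed, 100L + p)
    sim <- simulate_protein(scfg)
    ex <- make_training_example(sim$structure, sim$alignment,
                                which = cfg$features,
                                plm_maxit = cfg$plm_maxit)
    ex$tag <- sprintf("protein_%03d", p)
    if (cfg$write_artifacts) .write_sim_artifacts(sim, cfg$out_dir, ex$tag)
    examples[[p]] <- ex
  }
  train_set <- examples[seq_len(cfg$n_train)]
  test_set <- examples[cfg$n_train + seq_len(cfg$n_test)]

  ncfg <- cfg$net
  ncfg$features <- cfg$features
  ncfg$fusion_channels_in <- length(cfg$features) * ncfg$channels_hidden
  ncfg$seed <- derive_seed(cfg$master_seed, 77L)
  say("training %s-loss model on %d proteins for %d epochs",
      cfg$loss, cfg$n_train, cfg$epochs)
  model <- build_model(ncfg)
  fit <- train_model(model, train_set, epochs = cfg$epochs, loss = cfg$loss)

  say("evaluating %d held-out proteins", cfg$n_test)
  evals <- lapply(test_set, function(ex) {
    pred <- model_forward(fit$model, ex$features)
    if (cfg$write_artifacts) {
      write_rr(pred, file.path(cfg$out_dir, paste0(ex$tag, ".rr")))
    }
    evaluate_target(pred, ex$labels, target = ex$tag)
  })
  evaluation <- dplyr::bind_rows(evals)

  manifest <- list(
    package = "coevnet",
    version = as.character(utils::packageVersion("coevnet")),
    config_hash = .config_digest(cfg),
    master_seed = cfg$master_seed,
    n_train = cfg$n_train, n_test = cfg$n_test,
    sim = unclass(cfg$sim), net = unclass(cfg$net)[
      setdiff(names(unclass(cfg$net)), NULL)],
    features = cfg$features, loss = cfg$loss, epochs = cfg$epochs,
    final_train_loss = utils::tail(fit$history$loss, 1),
    mean_long_topL5_precision = mean(
      evaluation$precision[evaluation$range == "long" &
                             evaluation$depth == "L/5"])
  )
  if (cfg$write_artifacts) {
    utils::write.table(evaluation, file.path(cfg$out_dir, "evaluation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(fit = fit, evaluation = evaluation, manifest = manifest,
                 out_dir = if (cfg$write_artifacts) cfg$out_dir else NA),
            class = "coev_run")
}
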