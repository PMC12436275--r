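# Run configuration and the command-line entry point. A run configuration is
# a YAML file with top-level keys: seed, scheme, paths, generator, evolution,
# objectives. Unknown keys are rejected so typos fail loudly.

.CONFIG_KEYS <- list(
  top = c("seed", "scheme", "paths", "generator", "evolution", "objectives",
          "epochs", "sample_size", "temperature"),
  paths = c("corpus", "ligand_table", "pretrained", "finetuned",
            "output_dir", "vocabulary"),
  generator = c("embed_dim", "hidden_size", "block_layers", "num_blocks",
                "attention_heads", "key_dim", "max_len", "learning_rate",
                "batch_size"),
  evolution = c("crossover_threshold", "mutation_rate",
                "crover_sync_interval", "selection_fraction", "epochs"),
  objective = c("target_id", "direction", "threshold", "model",
                "toy_element", "cap"))

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key '%s' in %s", bad[1], where))
}

#' Load a run configuration
#'
#' Reads and validates a YAML run configuration, filling defaults (scheme
#' "pareto", learning rate 1e-3, batch 512, crossover threshold 0.5, sync
#' interval 250, selection fraction 0.2). Unknown keys anywhere are an
#' error; referenced input paths must exist.
#'
#' @param path YAML file path.
#' @return named list with elements `seed`, `scheme`, `paths`, `generator`
#'   (argument list for [generatorConfig()], minus vocab size), `evolution`
#'   (an [evolutionConfig()]), `objectives` (list of objective descriptors),
#'   `epochs`, `sample_size`, `temperature`.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  .checkKeys(raw, .CONFIG_KEYS$top, "top level")
  if (is.null(raw$seed)) stop("missing required key 'seed'")
  scheme <- if (is.null(raw$scheme)) "pareto" else raw$scheme
  if (!scheme %in% c("weighted", "pareto"))
    stop("scheme must be 'weighted' or 'pareto'")
  paths <- if (is.null(raw$paths)) list() else raw$paths
  .checkKeys(paths, .CONFIG_KEYS$paths, "paths")
  for (nm in intersect(names(paths), c("corpus", "ligand_table"))) {
    if (!file.exists(paths[[nm]]))
      stop(sprintf("configured path '%s' (%s) does not exist", paths[[nm]], nm))
  }
  gen <- if (is.null(raw$generator)) list() else raw$generator
  .checkKeys(gen, .CONFIG_KEYS$generator, "generator")
  evo <- if (is.null(raw$evolution)) list() else raw$evolution
  .checkKeys(evo, .CONFIG_KEYS$evolution, "evolution")
  evo <- do.call(evolutionConfig, c(evo, list(seed = as.integer(raw$seed))))
  objectives <- raw$objectives
  if (!is.null(objectives)) {
    for (ob in objectives) .checkKeys(ob, .CONFIG_KEYS$objective, "objective")
  }
  list(seed = as.integer(raw$seed), scheme = scheme, paths = paths,
       generator = gen, evolution = evo, objectives = objectives,
       epochs = raw$epochs, sample_size = raw$sample_size,
       temperature = if (is.null(raw$temperature)) 1.0 else raw$temperature)
}

#' @rdname loadRunConfig
#' @param config a configuration list (as returned by [loadRunConfig()] or
#'   hand-built with the same keys).
#' @export
saveRunConfig <- function(config, path) {
  out <- config
  out$evolution <- config$evolution[c("crossover_threshold", "mutation_rate",
                                      "crover_sync_interval",
                                      "selection_fraction", "epochs")]
  yaml::write_yaml(out, path)
  invisible(config)
}

# Materialize ObjectiveSpec objects from config descriptors.
.buildObjectives <- function(descriptors) {
  if (is.null(descriptors) || !length(descriptors))
    stop("configuration declares no objectives")
  lapply(descriptors, function(ob) {
    if (is.null(ob$target_id)) stop("objective missing target_id")
    direction <- if (is.null(ob$direction)) "high_affinity" else ob$direction
    threshold <- if (is.null(ob$threshold)) 0.5 else ob$threshold
    if (!is.null(ob$model)) {
      objectiveSpec(ob$target_id, direction, threshold,
                    loadQsarModel(ob$model))
    } else if (!is.null(ob$toy_element)) {
      toyObjective(ob$target_id, ob$toy_element, direction,
                   cap = if (is.null(ob$cap)) 2L else ob$cap,
                   threshold = threshold)
    } else {
      stop(sprintf("objective %s needs a 'model' path or a 'toy_element'",
                   ob$target_id))
    }
  })
}

.parseArgs <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a))
    if (i == length(argv)) stop(sprintf("flag %s needs a value", a))
    flags[[substring(a, 3L)]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

.usage <- function() {
  paste(
    "usage: molforge <command> [flags]",
    "commands:",
    "  preprocess  --in raw.csv --out corpus.smi [--rejects rej.csv]",
    "  build-vocab --in corpus.smi --out vocab.txt",
    "  train-qsar  --in ligands.csv --out model.rds [--seed N]",
    "  pretrain    --config run.yaml --out ckpt.rds [--epochs N] [--seed N]",
    "  finetune    --config run.yaml --ckpt pre.rds --out ckpt.rds",
    "              [--epochs N] [--seed N]",
    "  rl          --config run.yaml [--scheme weighted|pareto] [--epochs N]",
    "              [--seed N] [--out dir] [--objectives objectives.yaml]",
    "  sample      --config run.yaml --ckpt ckpt.rds --n N --out file.smi",
    "  rank        --in rewards.csv --out top.csv [--n N]",
    sep = "\n")
}

.cmdGeneratorConfig <- function(cfg, vocab) {
  do.call(generatorConfig,
          c(list(vocab_size = vocabSize(vocab), seed = cfg$seed),
            cfg$generator))
}

.requireFlags <- function(flags, need) {
  miss <- setdiff(need, names(flags))
  if (length(miss)) stop(sprintf("missing required flag --%s", miss[1]))
}

#' Command-line entry point
#'
#' Dispatches the pipeline stages (`preprocess`, `build-vocab`, `train-qsar`,
#' `pretrain`, `finetune`, `rl`, `sample`, `rank`) from an argument vector,
#' as used by the shipped `molforge` script (`system.file("cli",
#' "molforge.R", package = "molforge")`). Errors are reported on stderr and
#' turn into a non-zero exit status rather than an R error.
#'
#' @param argv character vector: subcommand followed by `--flag value` pairs.
#' @return integer exit status, 0 on success (invisibly).
#' @export
runCommand <- function(argv) {
  status <- tryCatch({
    if (!length(argv)) stop("no command given")
    cmd <- argv[1]
    flags <- .parseArgs(argv[-1])
    cfg <- if (!is.null(flags$config)) loadRunConfig(flags$config)
    seed <- if (!is.null(flags$seed)) as.integer(flags$seed)
            else if (!is.null(cfg)) cfg$seed else 1L
    switch(cmd,
      "preprocess" = {
        .requireFlags(flags, c("in", "out"))
        raw <- utils::read.csv(flags[["in"]], stringsAsFactors = FALSE)
        if (!"source_id" %in% names(raw))
          raw$source_id <- sprintf("row%d", seq_len(nrow(raw)))
        res <- filterDataset(raw[, c("source_id", "smiles")])
        writeSmilesFile(res$retained$smiles, flags$out)
        if (!is.null(flags$rejects))
          utils::write.csv(res$rejected, flags$rejects, row.names = FALSE)
        message(sprintf("retained %d / %d molecules", nrow(res$retained),
                        nrow(raw)))
      },
      "build-vocab" = {
        .requireFlags(flags, c("in", "out"))
        vocab <- buildVocabulary(readSmilesFile(flags[["in"]]))
        writeVocabulary(vocab, flags$out)
        message(sprintf("vocabulary of %d tokens written", vocabSize(vocab)))
      },
      "train-qsar" = {
        .requireFlags(flags, c("in", "out"))
        rec <- assignPxLabels(readLigandTable(flags[["in"]]))
        model <- trainQsar(rec, seed = seed)
        saveQsarModel(model, flags$out)
      },
      "pretrain" = {
        .requireFlags(flags, c("config", "out"))
        corpus <- readSmilesFile(cfg$paths$corpus)
        vocab <- buildVocabulary(corpus)
        gcfg <- .cmdGeneratorConfig(cfg, vocab)
        gcfg$seed <- seed
        epochs <- if (!is.null(flags$epochs)) as.integer(flags$epochs)
                  else if (!is.null(cfg$epochs)) cfg$epochs else 10L
        fit <- pretrainGenerator(buildGenerator(gcfg, vocab), corpus, epochs,
                                 checkpointPath = flags$out)
        message(sprintf("best loss %.4f", min(fit$log$loss)))
      },
      "finetune" = {
        .requireFlags(flags, c("config", "ckpt", "out"))
        model <- loadGeneratorCheckpoint(flags$ckpt)
        lig <- readLigandTable(cfg$paths$ligand_table)
        epochs <- if (!is.null(flags$epochs)) as.integer(flags$epochs)
                  else if (!is.null(cfg$epochs)) cfg$epochs else 10L
        fit <- finetuneGenerator(model, lig$smiles, epochs,
                                 checkpointPath = flags$out)
        message(sprintf("best loss %.4f", min(fit$log$loss)))
      },
      "rl" = {
        .requireFlags(flags, "config")
        outDir <- if (!is.null(flags$out)) flags$out
                  else if (!is.null(cfg$paths$output_dir)) cfg$paths$output_dir
                  else "."
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        scheme <- if (!is.null(flags$scheme)) flags$scheme else cfg$scheme
        epochs <- if (!is.null(flags$epochs)) as.integer(flags$epochs)
                  else if (!is.null(cfg$epochs)) cfg$epochs
                  else cfg$evolution$epochs
        fine <- loadGeneratorCheckpoint(cfg$paths$finetuned)
        pre <- loadGeneratorCheckpoint(cfg$paths$pretrained)
        descriptors <- if (!is.null(flags$objectives)) {
          yaml::read_yaml(flags$objectives)
        } else cfg$objectives
        objectives <- .buildObjectives(descriptors)
        evo <- cfg$evolution
        evo$seed <- seed
        res <- trainRL(fine, fine, pre, objectives, scheme, evo,
                       epochs = epochs, sampleSize = cfg$sample_size,
                       temperature = cfg$temperature,
                       metricsPath = file.path(outDir, "metrics.csv"),
                       checkpointPath = file.path(outDir, "agent_best.rds"),
                       quiet = TRUE)
        message(sprintf("best epoch %d; metrics written to %s",
                        res$bestEpoch, file.path(outDir, "metrics.csv")))
      },
      "sample" = {
        .requireFlags(flags, c("config", "ckpt", "n", "out"))
        model <- loadGeneratorCheckpoint(flags$ckpt)
        set.seed(seed)
        batch <- sampleSmiles(model, as.integer(flags$n),
                              temperature = cfg$temperature)
        writeSmilesFile(batch$smiles, flags$out)
        message(sprintf("validity %.3f",
                        mean(isValidSmiles(batch$smiles))))
      },
      "rank" = {
        .requireFlags(flags, c("in", "out"))
        scored <- utils::read.csv(flags[["in"]], stringsAsFactors = FALSE)
        topN <- if (!is.null(flags$n)) as.integer(flags$n) else 10L
        utils::write.csv(compositeRank(scored, topN), flags$out,
                         row.names = FALSE)
      },
      stop(sprintf("unknown command '%s'\n%s", cmd, .usage()))
    )
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
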