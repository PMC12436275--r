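# Reinforcement-learning loop: evolutionary agent/crover/prior sampling,
# roulette selection, policy-gradient updates, epoch metrics, checkpointing
# and the final composite ranking.

#' Evolutionary sampling configuration
#'
#' Settings of the crossover/mutation/selection machinery around the RL loop.
#' Defaults follow the method's full-scale settings: crossover threshold 0.5,
#' mutation threshold 0.01, crover resynchronized to the best checkpoint
#' every 250 epochs, top 20% of each batch selected for the policy update.
#'
#' @param crossover_threshold crossover draw above this hands the step to the
#'   crover model.
#' @param mutation_rate mutation draw below this hands the step to the frozen
#'   prior.
#' @param crover_sync_interval epochs between resynchronizations of agent and
#'   crover to the best checkpoint.
#' @param selection_fraction fraction of each scored batch kept by roulette
#'   selection.
#' @param epochs default number of RL epochs.
#' @param seed integer seed for the whole RL run.
#' @return named list.
#' @export
evolutionConfig <- function(crossover_threshold = 0.5, mutation_rate = 0.01,
                            crover_sync_interval = 250L,
                            selection_fraction = 0.2, epochs = 1000L,
                            seed = 1L) {
  stopifnot(crossover_threshold > 0, crossover_threshold <= 1,
            mutation_rate >= 0, mutation_rate < 1,
            selection_fraction > 0, selection_fraction <= 1,
            crover_sync_interval >= 1L, epochs >= 1L)
  list(crossover_threshold = crossover_threshold,
       mutation_rate = mutation_rate,
       crover_sync_interval = as.integer(crover_sync_interval),
       selection_fraction = selection_fraction,
       epochs = as.integer(epochs),
       seed = as.integer(seed))
}

#' Sample with evolutionary crossover and mutation
#'
#' Draws a batch from three models of identical architecture and vocabulary.
#' At every generation step of every sequence, a mutation draw below
#' `mutation_rate` takes the token distribution from the frozen prior;
#' otherwise a crossover draw above `crossover_threshold` takes it from the
#' crover model, else from the agent. All three models consume the chosen
#' token, so their hidden states stay in lockstep. Agent log-probabilities
#' of the emitted tokens are recorded for the policy gradient. With mutation
#' off and `crossover_threshold = 1` no selection draws are consumed and the
#' result is identical to [sampleSmiles()] on the agent.
#'
#' @param agent,crover,prior [SmilesGenerator-class] models sharing one
#'   vocabulary.
#' @param n batch size.
#' @param config from [evolutionConfig()].
#' @param temperature softmax temperature.
#' @return list with `smiles`, `tokens`, `lengths`, `logp` (agent).
#' @export
evolutionarySample <- function(agent, crover, prior, n, config,
                               temperature = 1.0) {
  if (!identical(agent@vocab@tokens, crover@vocab@tokens) ||
      !identical(agent@vocab@tokens, prior@vocab@tokens))
    stop("agent, crover and prior must share one vocabulary")
  cfg <- agent@config
  pure <- config$mutation_rate <= 0 && config$crossover_threshold >= 1
  r <- if (pure) {
    nc_sample(agent@params, cfg, as.integer(n), temperature, cfg$max_len,
              goIndex(agent@vocab), eosIndex(agent@vocab))
  } else {
    nc_sample(agent@params, cfg, as.integer(n), temperature, cfg$max_len,
              goIndex(agent@vocab), eosIndex(agent@vocab),
              croverParams = crover@params, priorParams = prior@params,
              mutationRate = config$mutation_rate,
              crossoverThreshold = config$crossover_threshold)
  }
  smiles <- vapply(seq_len(n), function(i) {
    L <- r$lengths[i]
    if (L == 0L) return("")
    decodeSmiles(r$tokens[i, seq_len(L)], agent@vocab)
  }, character(1))
  list(smiles = smiles, tokens = r$tokens, lengths = r$lengths,
       logp = r$logp)
}

#' Roulette-wheel selection
#'
#' Samples exactly `ceiling(fraction * N)` distinct molecules with
#' probability proportional to their scores, without replacement
#' (probabilities renormalized after each draw). All-zero scores fall back
#' to uniform probabilities; if fewer molecules than requested have positive
#' score, the remainder is drawn uniformly from the zero-score ones.
#'
#' @param scores non-negative numeric vector.
#' @param fraction fraction of the batch to select, in (0, 1].
#' @return integer vector of selected indices.
#' @export
rouletteSelect <- function(scores, fraction = 0.2) {
  stopifnot(all(scores >= 0), fraction > 0, fraction <= 1)
  n <- length(scores)
  size <- ceiling(fraction * n)
  if (all(scores == 0)) return(sample.int(n, size))
  pos <- which(scores > 0)
  if (length(pos) >= size)
    return(sample.int(n, size, prob = scores))
  rest <- which(scores == 0)
  c(if (length(pos) > 1L) sample(pos, length(pos), prob = scores[pos])
    else pos,
    if (length(rest) > 1L) sample(rest, size - length(pos)) else rest)
}

#' Policy-gradient (REINFORCE) update
#'
#' Maximizes `J = sum_t log G(y_t | y_{1:t-1}) * R*` summed over the batch by
#' one Adam step on its negation. Sequences with reward 0 contribute no
#' gradient, so an all-zero batch leaves the parameters unchanged (with a
#' fresh optimizer state).
#'
#' @param agent a [SmilesGenerator-class].
#' @param tokens,lengths sampled batch (from [evolutionarySample()] or
#'   [sampleSmiles()]).
#' @param rewards per-sequence final rewards, aligned with the batch.
#' @param optState Adam state from a previous call, or NULL for fresh.
#' @param lr learning rate; defaults to the generator's configured rate.
#' @return list with `model`, `optState` and `loss` (the negated objective).
#' @export
policyGradientUpdate <- function(agent, tokens, lengths, rewards,
                                 optState = NULL, lr = NULL) {
  if (nrow(tokens) != length(rewards))
    stop("rewards must align with the sampled batch")
  cfg <- agent@config
  if (is.null(lr)) lr <- cfg$learning_rate
  tb <- .sampledBatch(tokens, lengths, agent@vocab)
  r <- nc_forward_backward(agent@params, cfg, tb$input, tb$target, tb$mask,
                           as.numeric(rewards), TRUE)
  if (is.null(optState)) optState <- adamInit(agent@params)
  if (all(rewards == 0)) {
    # multiplicative null: no gradient, no parameter motion
    return(list(model = agent, optState = optState, loss = r$loss))
  }
  st <- adamStep(agent@params, r$grads, optState, lr)
  model <- new("SmilesGenerator", config = cfg, params = st$params,
               vocab = agent@vocab)
  list(model = model, optState = st$state, loss = r$loss)
}

#' Epoch metrics of a scored batch
#'
#' Validity is the parseable fraction; desirability the desirable fraction;
#' uniqueness the fraction of molecules whose canonical SMILES is distinct
#' within the batch and unseen in the accumulated set of earlier epochs.
#'
#' @param scored data.frame from [scoreMolecules()].
#' @param seen character vector of canonical SMILES already generated
#'   (default none).
#' @return list with `validity`, `desirability`, `uniqueness`, `mean_reward`
#'   (all in [0,1]) and `canonical` (canonical SMILES of the valid molecules,
#'   for accumulating).
#' @export
computeMetrics <- function(scored, seen = character(0)) {
  n <- nrow(scored)
  if (n == 0L) stop("empty batch")
  can <- rep(NA_character_, n)
  if (any(scored$valid))
    can[scored$valid] <- canonicalSmiles(scored$smiles[scored$valid])
  newUnique <- !is.na(can) & !duplicated(can) & !(can %in% seen)
  list(validity = mean(scored$valid),
       desirability = mean(scored$desirable),
       uniqueness = sum(newUnique) / n,
       mean_reward = mean(scored$r_star),
       canonical = can[!is.na(can)])
}

#' Reinforcement-learning training loop
#'
#' Per epoch: evolutionary sampling from agent/crover/prior, per-objective
#' pX prediction and reward assembly under the chosen scheme, roulette
#' selection of the top fraction, and one policy-gradient update of the
#' agent on the selected molecules. The agent checkpoint with the highest
#' epoch mean reward is kept, and both agent and crover are resynchronized
#' to it every `crover_sync_interval` epochs. The prior is never touched.
#'
#' @param agent,crover,prior starting models: agent and crover from the
#'   fine-tuned checkpoint, prior from the pretrained one.
#' @param objectives list of [ObjectiveSpec-class] objects.
#' @param scheme `"pareto"` or `"weighted"`.
#' @param config from [evolutionConfig()].
#' @param epochs number of epochs (defaults to `config$epochs`).
#' @param sampleSize molecules sampled per epoch (defaults to the agent's
#'   configured batch size).
#' @param temperature sampling temperature.
#' @param metricsPath optional CSV path for the per-epoch metrics log.
#' @param checkpointPath optional path for the best-agent checkpoint.
#' @param quiet suppress per-epoch messages.
#' @return list with `agent` (final), `best` (best-checkpoint model),
#'   `crover`, `metrics` (data.frame epoch, validity, desirability,
#'   uniqueness, mean_reward) and `bestEpoch`.
#' @export
trainRL <- function(agent, crover, prior, objectives,
                    scheme = c("pareto", "weighted"), config = evolutionConfig(),
                    epochs = NULL, sampleSize = NULL, temperature = 1.0,
                    metricsPath = NULL, checkpointPath = NULL, quiet = FALSE) {
  scheme <- match.arg(scheme)
  if (is.null(epochs)) epochs <- config$epochs
  if (is.null(sampleSize)) sampleSize <- agent@config$batch_size
  set.seed(config$seed)
  opt <- NULL
  seen <- character(0)
  metrics <- vector("list", epochs)
  best <- list(reward = -Inf, model = agent, epoch = 0L)
  for (ep in seq_len(epochs)) {
    batch <- evolutionarySample(agent, crover, prior, sampleSize, config,
                                temperature)
    scored <- scoreMolecules(batch$smiles, objectives, scheme)
    met <- computeMetrics(scored, seen)
    seen <- union(seen, met$canonical)
    metrics[[ep]] <- data.frame(epoch = ep, validity = met$validity,
                                desirability = met$desirability,
                                uniqueness = met$uniqueness,
                                mean_reward = met$mean_reward)
    sel <- rouletteSelect(scored$r_star, config$selection_fraction)
    upd <- policyGradientUpdate(agent, batch$tokens[sel, , drop = FALSE],
                                batch$lengths[sel], scored$r_star[sel],
                                optState = opt)
    agent <- upd$model; opt <- upd$optState
    if (met$mean_reward > best$reward)
      best <- list(reward = met$mean_reward, model = agent, epoch = ep)
    if (ep %% config$crover_sync_interval == 0L) {
      agent <- best$model
      crover <- best$model
    }
    if (!quiet)
      message(sprintf(
        "epoch %d: validity %.3f desirability %.3f uniqueness %.3f mean R* %.3f",
        ep, met$validity, met$desirability, met$uniqueness, met$mean_reward))
  }
  metrics <- do.call(rbind, metrics)
  if (!is.null(metricsPath))
    utils::write.csv(metrics, metricsPath, row.names = FALSE)
  if (!is.null(checkpointPath))
    saveGeneratorCheckpoint(best$model, checkpointPath)
  list(agent = agent, best = best$model, crover = crover, metrics = metrics,
       bestEpoch = best$epoch)
}

#' Composite ranking of generated molecules
#'
#' Ranks molecules by `0.4 * desirability + 0.4 * reward + 0.2 * uniqueness`,
#' where desirability is the molecule's 0/1 desirable flag, reward its final
#' reward score, and uniqueness a 0/1 indicator of being the first occurrence
#' of its canonical structure in the batch (invalid molecules score 0).
#'
#' @param scored data.frame from [scoreMolecules()].
#' @param topN number of molecules to return (default 10).
#' @return the top rows of `scored`, with `composite` and `unique` columns
#'   added, in descending composite order.
#' @export
compositeRank <- function(scored, topN = 10L) {
  n <- nrow(scored)
  can <- rep(NA_character_, n)
  if (any(scored$valid))
    can[scored$valid] <- canonicalSmiles(scored$smiles[scored$valid])
  uniq <- as.numeric(!is.na(can) & !duplicated(can))
  composite <- 0.4 * as.numeric(scored$desirable) + 0.4 * scored$r_star +
    0.2 * uniq
  out <- scored
  out$unique <- uniq
  out$composite <- composite
  out <- out[base::order(-composite), , drop = FALSE]
  utils::head(out, topN)
}
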