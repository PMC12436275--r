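# The SMILES language model: configuration, initialization, NLL training and
# autoregressive sampling. The numerical core (LSTM stack + causal multi-head
# self-attention + backprop) is compiled; this file owns batching, the Adam
# optimizer and checkpoints.

#' Generator configuration
#'
#' Architecture and optimization settings of the SMILES language model. The
#' defaults are the full-scale settings (embedding 128, three 3-layer LSTM
#' blocks of width 512 -- nine recurrent layers in total -- four attention
#' heads of key width 128); tests and desk-scale runs shrink them.
#'
#' @param vocab_size vocabulary size (required).
#' @param embed_dim token embedding width.
#' @param hidden_size LSTM width; must equal `attention_heads * key_dim`.
#' @param block_layers LSTM layers per block.
#' @param num_blocks number of stacked blocks, joined by a rectifier and a
#'   learned projection back to the embedding width.
#' @param attention_heads,key_dim multi-head attention shape.
#' @param max_len maximum sequence length in tokens.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed used for initialization and training order.
#' @return named list of class-checked settings.
#' @export
generatorConfig <- function(vocab_size, embed_dim = 128L, hidden_size = 512L,
                            block_layers = 3L, num_blocks = 3L,
                            attention_heads = 4L, key_dim = 128L,
                            max_len = 100L, learning_rate = 1e-3,
                            batch_size = 512L, seed = 1L) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              embed_dim = as.integer(embed_dim),
              hidden_size = as.integer(hidden_size),
              block_layers = as.integer(block_layers),
              num_blocks = as.integer(num_blocks),
              attention_heads = as.integer(attention_heads),
              key_dim = as.integer(key_dim),
              max_len = as.integer(max_len),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              seed = as.integer(seed))
  if (any(unlist(cfg[1:8]) <= 0L)) stop("all dimensions must be positive")
  if (cfg$attention_heads * cfg$key_dim != cfg$hidden_size)
    stop("attention_heads * key_dim must equal hidden_size")
  cfg
}

# Fan-in-scaled normal initialization; LSTM forget-gate biases start at 1.
.initParams <- function(cfg) {
  wmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)),
                                  nr, nc)
  h <- cfg$hidden_size; e <- cfg$embed_dim
  p <- list(E = wmat(cfg$vocab_size, e))
  for (b in seq_len(cfg$num_blocks)) {
    for (l in seq_len(cfg$block_layers)) {
      inDim <- if (l == 1L) e else h
      p[[sprintf("Wx_%d_%d", b, l)]] <- wmat(inDim, 4L * h)
      p[[sprintf("Wh_%d_%d", b, l)]] <- wmat(h, 4L * h)
      bias <- numeric(4L * h)
      bias[(h + 1L):(2L * h)] <- 1  # forget gate
      p[[sprintf("b_%d_%d", b, l)]] <- bias
    }
    if (b < cfg$num_blocks) {
      p[[sprintf("P_%d", b)]] <- wmat(h, e)
      p[[sprintf("bP_%d", b)]] <- numeric(e)
    }
  }
  for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[nm]] <- wmat(h, h)
  p$Wout <- wmat(h, cfg$vocab_size)
  p$bout <- numeric(cfg$vocab_size)
  p
}

#' Build a SMILES generator
#'
#' Initializes all weights from the configuration seed. The architecture is
#' embedding -> `num_blocks` stacked LSTM blocks (rectifier + projection back
#' to the embedding width between blocks) -> causal multi-head self-attention
#' over the final block's outputs -> linear layer to vocabulary logits.
#'
#' @param config from [generatorConfig()]; its `vocab_size` must equal the
#'   vocabulary size.
#' @param vocab a [Vocabulary-class].
#' @return a [SmilesGenerator-class].
#' @export
buildGenerator <- function(config, vocab) {
  if (config$vocab_size != vocabSize(vocab))
    stop("config vocab_size does not match the vocabulary")
  set.seed(config$seed)
  new("SmilesGenerator", config = config, params = .initParams(config),
      vocab = vocab)
}

# Teacher-forcing batch tensors from encoded sequences (lists of index
# vectors ending in EOS). Pads with EOS; the mask covers real positions only.
.teacherBatch <- function(encoded, vocab) {
  n <- length(encoded)
  lens <- lengths(encoded)
  T <- max(lens)
  go <- goIndex(vocab); eos <- eosIndex(vocab)
  input <- matrix(eos, n, T)
  target <- matrix(eos, n, T)
  mask <- matrix(0L, n, T)
  for (i in seq_len(n)) {
    s <- encoded[[i]]
    L <- lens[i]
    input[i, seq_len(L)] <- c(go, s[-L])
    target[i, seq_len(L)] <- s
    mask[i, seq_len(L)] <- 1L
  }
  list(input = input, target = target, mask = mask)
}

# Same tensors from a sampled token matrix (1-based, 0-padded after EOS).
.sampledBatch <- function(tokens, lengths, vocab) {
  n <- nrow(tokens); T <- max(lengths)
  go <- goIndex(vocab); eos <- eosIndex(vocab)
  input <- matrix(eos, n, T)
  target <- matrix(eos, n, T)
  mask <- matrix(0L, n, T)
  for (i in seq_len(n)) {
    L <- lengths[i]
    s <- tokens[i, seq_len(L)]
    input[i, seq_len(L)] <- c(go, s[-L])
    target[i, seq_len(L)] <- s
    mask[i, seq_len(L)] <- 1L
  }
  list(input = input, target = target, mask = mask)
}

#' Teacher-forced negative log-likelihood of a SMILES batch
#'
#' Average per-sequence NLL (natural log) of the batch under the model, with
#' GO prepended and EOS appended, padding masked out of the loss.
#'
#' @param model a [SmilesGenerator-class].
#' @param smiles character vector of in-vocabulary SMILES.
#' @return scalar loss (non-negative).
#' @export
generatorLoss <- function(model, smiles) {
  enc <- lapply(smiles, encodeSmiles, vocab = model@vocab)
  tb <- .teacherBatch(enc, model@vocab)
  r <- nc_forward_backward(model@params, model@config, tb$input, tb$target,
                           tb$mask, rep(1, nrow(tb$input)), FALSE)
  r$loss
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Pretrain or fine-tune the generator on a SMILES corpus
#'
#' Teacher-forced NLL training with Adam at the configured learning rate and
#' batch size. Sequences longer than `max_len` tokens are dropped with a
#' logged count. The epoch/loss trajectory is returned, and the parameters at
#' the best (lowest) epoch loss are kept; a checkpoint file is written when
#' `checkpointPath` is given. Fully deterministic for a fixed config seed.
#'
#' @param model a [SmilesGenerator-class].
#' @param corpus character vector of SMILES.
#' @param epochs number of passes over the corpus.
#' @param checkpointPath optional path for the best-loss checkpoint.
#' @param logPath optional CSV path for the training log
#'   (`epoch,loss,validity_sample`).
#' @param validitySample if positive, sample this many sequences after each
#'   epoch and record their validity in the log (costs one sampling pass per
#'   epoch; 0 disables, leaving NA).
#' @param quiet suppress per-epoch messages.
#' @return list with `model` (best-loss parameters) and `log`
#'   (data.frame `epoch`, `loss`, `validity_sample`).
#' @export
pretrainGenerator <- function(model, corpus, epochs, checkpointPath = NULL,
                              logPath = NULL, validitySample = 0L,
                              quiet = FALSE) {
  stopifnot(length(corpus) > 0L, epochs >= 1L)
  cfg <- model@config
  vocab <- model@vocab
  enc <- lapply(corpus, encodeSmiles, vocab = vocab)
  keep <- lengths(enc) <= cfg$max_len
  if (any(!keep))
    message(sprintf("dropped %d sequence(s) longer than max_len = %d",
                    sum(!keep), cfg$max_len))
  enc <- enc[keep]
  if (!length(enc)) stop("empty corpus after length filtering")

  set.seed(cfg$seed)
  params <- model@params
  opt <- adamInit(params)
  n <- length(enc)
  bs <- min(cfg$batch_size, n)
  log <- vector("list", epochs)
  best <- list(loss = Inf, params = params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    epLoss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      tb <- .teacherBatch(enc[idx], vocab)
      r <- nc_forward_backward(params, cfg, tb$input, tb$target, tb$mask,
                               rep(1, length(idx)), TRUE)
      st <- adamStep(params, r$grads, opt, cfg$learning_rate)
      params <- st$params; opt <- st$state
      epLoss <- epLoss + r$loss; nb <- nb + 1L
    }
    epLoss <- epLoss / nb
    validity <- NA_real_
    if (validitySample > 0L) {
      cur <- new("SmilesGenerator", config = cfg, params = params,
                 vocab = vocab)
      validity <- mean(isValidSmiles(
        sampleSmiles(cur, validitySample)$smiles))
    }
    log[[ep]] <- data.frame(epoch = ep, loss = epLoss,
                            validity_sample = validity)
    if (!quiet) message(sprintf("epoch %d: loss %.4f", ep, epLoss))
    if (epLoss < best$loss) best <- list(loss = epLoss, params = params)
  }
  log <- do.call(rbind, log)
  out <- new("SmilesGenerator", config = cfg, params = best$params,
             vocab = vocab)
  if (!is.null(checkpointPath)) saveGeneratorCheckpoint(out, checkpointPath)
  if (!is.null(logPath)) utils::write.csv(log, logPath, row.names = FALSE)
  list(model = out, log = log)
}

#' @rdname pretrainGenerator
#' @param ... passed on to [pretrainGenerator()].
#' @export
finetuneGenerator <- function(model, corpus, epochs, ...) {
  pretrainGenerator(model, corpus, epochs, ...)
}

#' Sample SMILES from the generator
#'
#' Autoregressive sampling: every sequence starts from GO and stops at EOS or
#' `max_len`. Per-sequence summed log selection probabilities are recorded
#' for the policy gradient. Randomness comes from R's RNG, so `set.seed()`
#' reproduces batches exactly; `temperature = 0` is greedy decoding.
#'
#' @param model a [SmilesGenerator-class].
#' @param n number of sequences.
#' @param temperature softmax temperature (default 1).
#' @param maxLen optional override of the configured `max_len`.
#' @return list with `smiles` (decoded strings), `tokens` (1-based index
#'   matrix, 0-padded), `lengths` and `logp`.
#' @export
sampleSmiles <- function(model, n, temperature = 1.0, maxLen = NULL) {
  if (n <= 0L) stop("n must be positive")
  cfg <- model@config
  if (is.null(maxLen)) maxLen <- cfg$max_len
  r <- nc_sample(model@params, cfg, as.integer(n), temperature,
                 as.integer(maxLen), goIndex(model@vocab),
                 eosIndex(model@vocab))
  smiles <- vapply(seq_len(n), function(i) {
    L <- r$lengths[i]
    if (L == 0L) return("")
    decodeSmiles(r$tokens[i, seq_len(L)], model@vocab)
  }, character(1))
  list(smiles = smiles, tokens = r$tokens, lengths = r$lengths,
       logp = r$logp)
}

#' Save / load generator checkpoints
#'
#' A checkpoint holds the weights, the configuration and the vocabulary
#' (plus a vocabulary digest so mismatched checkpoints are caught on load).
#'
#' @param model a [SmilesGenerator-class].
#' @param path file path.
#' @return `loadGeneratorCheckpoint` the model; the writer returns its input
#'   invisibly.
#' @export
saveGeneratorCheckpoint <- function(model, path) {
  saveRDS(list(params = model@params, config = model@config,
               tokens = model@vocab@tokens,
               vocab_hash = sum(utf8ToInt(paste(model@vocab@tokens,
                                                collapse = "\r")))),
          path)
  invisible(model)
}

#' @rdname saveGeneratorCheckpoint
#' @export
loadGeneratorCheckpoint <- function(path) {
  x <- readRDS(path)
  vocab <- new("Vocabulary", tokens = x$tokens)
  hash <- sum(utf8ToInt(paste(x$tokens, collapse = "\r")))
  if (!identical(hash, x$vocab_hash)) stop("corrupt checkpoint: vocab hash")
  new("SmilesGenerator", config = x$config, params = x$params, vocab = vocab)
}

#' Multi-head self-attention on a sequence
#'
#' Direct access to the attention layer used by the generator: per head,
#' `softmax(Q W_q (K W_k)' / sqrt(d_k))` applied to `V W_v`, heads
#' concatenated and projected by `W_o`. Output shape equals input shape.
#'
#' @param H numeric matrix, sequence length x width (`heads * keyDim`).
#' @param weights named list with `Wq`, `Wk`, `Wv`, `Wo` (width x width).
#' @param heads,keyDim attention shape.
#' @param causal restrict position t to attend to positions <= t (the
#'   generator's setting); `FALSE` gives full bidirectional attention.
#' @return matrix of the same shape as `H`.
#' @export
attentionLayer <- function(H, weights, heads, keyDim, causal = TRUE) {
  nc_attention(H, weights$Wq, weights$Wk, weights$Wv, weights$Wo,
               as.integer(heads), as.integer(keyDim), causal)
}
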