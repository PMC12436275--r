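test_that("configuration is validated at construction", {
  expect_error(generatorConfig(vocab_size = 10, attention_heads = 3,
                               key_dim = 100, hidden_size = 512),
               "attention_heads")
  cfg <- generatorConfig(vocab_size = 10)
  expect_identical(cfg$num_blocks * cfg$block_layers, 9L)
  expect_identical(cfg$embed_dim, 128L)
  v <- smallVocab()
  expect_error(buildGenerator(generatorConfig(vocab_size = 3), v),
               "vocab_size")
})

test_that("attention matches a dense-algebra oracle and its limit cases", {
  set.seed(42)
  h <- 8L; heads <- 2L; dk <- 4L
  w <- list(Wq = matrix(rnorm(h * h), h), Wk = matrix(rnorm(h * h), h),
            Wv = matrix(rnorm(h * h), h), Wo = matrix(rnorm(h * h), h))
  H <- matrix(rnorm(3 * h), 3, h)
  out <- attentionLayer(H, w, heads, dk, causal = FALSE)
  expect_identical(dim(out), dim(H))
  # brute-force oracle
  oracle <- matrix(0, 3, h)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1) * dk + 1):(hd * dk)
    Q <- (H %*% w$Wq)[, cols]; K <- (H %*% w$Wk)[, cols]
    V <- (H %*% w$Wv)[, cols]
    S <- Q %*% t(K) / sqrt(dk)
    W <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    oracle[, cols] <- W %*% V
  }
  oracle <- oracle %*% w$Wo
  expect_equal(out, oracle, tolerance = 1e-5)
  # sequence of length 1: the only position gets attention weight exactly 1
  H1 <- H[1, , drop = FALSE]
  expect_equal(attentionLayer(H1, w, heads, dk),
               (H1 %*% w$Wv) %*% w$Wo, tolerance = 1e-12)
  # causal attention at position 1 equals the length-1 case
  expect_equal(attentionLayer(H, w, heads, dk, causal = TRUE)[1, ],
               ((H1 %*% w$Wv) %*% w$Wo)[1, ], tolerance = 1e-12)
  expect_error(attentionLayer(H, w, heads = 3, keyDim = 4), "width")
})

test_that("NLL has its closed forms and batches average per sequence", {
  v <- smallVocab()
  cfg <- tinyConfig(v)
  gen <- buildGenerator(cfg, v)
  # zero all parameters: logits constant, model uniform over the vocabulary
  zero <- lapply(generatorParams(gen), function(x) x * 0)
  gz <- new("SmilesGenerator", config = cfg, params = zero, vocab = v)
  smi <- c("CCO", "CCNC")
  lens <- vapply(smi, function(s) length(encodeSmiles(s, v)), numeric(1))
  expect_equal(generatorLoss(gz, smi), mean(lens) * log(vocabSize(v)),
               tolerance = 1e-10)
  # batch loss is the mean of single-sequence losses, and non-negative
  l1 <- generatorLoss(gen, smi[1]); l2 <- generatorLoss(gen, smi[2])
  expect_equal(generatorLoss(gen, smi), (l1 + l2) / 2, tolerance = 1e-8)
  expect_gte(l1, 0)
})

test_that("analytic gradients agree with finite differences", {
  v <- buildVocabulary(c("CCO", "NC(C)O", "c1ccccc1"))
  cfg <- generatorConfig(vocab_size = vocabSize(v), embed_dim = 6,
                         hidden_size = 8, block_layers = 2, num_blocks = 2,
                         attention_heads = 2, key_dim = 4, max_len = 20,
                         seed = 42)
  gen <- buildGenerator(cfg, v)
  params <- generatorParams(gen)
  enc <- lapply(c("CCO", "NC(C)O", "CO"), encodeSmiles, vocab = v)
  tb <- molforge:::.teacherBatch(enc, v)
  w <- c(0.5, 1.0, 0.2)  # exercises the reward-weighted (REINFORCE) path
  fb <- molforge:::nc_forward_backward(params, cfg, tb$input, tb$target,
                                       tb$mask, w, TRUE)
  loss <- function(p) molforge:::nc_forward_backward(
    p, cfg, tb$input, tb$target, tb$mask, w, FALSE)$loss
  eps <- 1e-5
  set.seed(1)
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(4L, length(params[[nm]])))) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps; lp <- loss(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; lm <- loss(p2)
      expect_equal(fb$grads[[nm]][i], (lp - lm) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("short training reduces the loss deterministically", {
  corpus <- makeToyCorpus(200, seed = 13)
  v <- buildVocabulary(corpus)
  gen <- buildGenerator(tinyConfig(v, seed = 3L), v)
  f1 <- suppressMessages(pretrainGenerator(gen, corpus, 4, quiet = TRUE))
  expect_lt(f1$log$loss[4], f1$log$loss[1])
  f2 <- suppressMessages(pretrainGenerator(gen, corpus, 4, quiet = TRUE))
  expect_identical(f1$log$loss, f2$log$loss)
  # checkpoints round-trip
  f <- tempfile(fileext = ".rds")
  saveGeneratorCheckpoint(f1$model, f)
  back <- loadGeneratorCheckpoint(f)
  expect_identical(generatorParams(back), generatorParams(f1$model))
})

test_that("sampling respects contracts: bounds, determinism, greedy limit", {
  gen <- smallPretrained()
  set.seed(21)
  b <- sampleSmiles(gen, 100)
  expect_identical(length(b$smiles), 100L)
  expect_true(all(b$lengths <= generatorConfigOf(gen)$max_len))
  expect_true(all(b$logp <= 0))
  set.seed(21)
  b2 <- sampleSmiles(gen, 100)
  expect_identical(b$tokens, b2$tokens)
  # temperature -> 0 is greedy decoding: all sequences identical
  set.seed(5)
  g <- sampleSmiles(gen, 10, temperature = 0)
  expect_identical(length(unique(g$smiles)), 1L)
  expect_error(sampleSmiles(gen, 0), "positive")
})

test_that("step distributions are valid probabilities", {
  gen <- smallPretrained()
  cfg <- generatorConfigOf(gen)
  enc <- lapply(c("CCO", "CCNC"), encodeSmiles, vocab = generatorVocab(gen))
  tb <- molforge:::.teacherBatch(enc, generatorVocab(gen))
  r <- molforge:::nc_forward_backward(generatorParams(gen), cfg, tb$input,
                                      tb$target, tb$mask, c(1, 1), FALSE)
  # exp(logp) of a real sequence must be a valid probability
  expect_true(all(r$logp <= 0))
  expect_true(all(is.finite(r$logp)))
})
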