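test_that("roulette selection returns the exact count with score bias", {
  set.seed(1)
  sel <- rouletteSelect(runif(100), fraction = 0.2)
  expect_identical(length(sel), 20L)
  expect_identical(anyDuplicated(sel), 0L)
  # certainty case: the only scored molecule is selected
  sc <- c(rep(0, 99), 1)
  expect_identical(rouletteSelect(sc, fraction = 0.01), 100L)
  # all-zero scores fall back to uniform, still exact count
  set.seed(2)
  expect_identical(length(rouletteSelect(rep(0, 50), 0.2)), 10L)
  # determinism under a fixed seed
  set.seed(3); a <- rouletteSelect(runif(80), 0.25)
  set.seed(3); b <- rouletteSelect(runif(80), 0.25)
  expect_identical(a, b)
  # more positive scores than slots: never picks a zero-score molecule
  set.seed(4)
  sc2 <- c(rep(1, 30), rep(0, 70))
  expect_true(all(rouletteSelect(sc2, 0.2) <= 30))
})

test_that("policy gradient obeys the null, determinism and sign contracts", {
  gen <- smallPretrained()
  set.seed(31)
  b <- sampleSmiles(gen, 16)
  # zero rewards: zero gradient, parameters bit-identical
  upd0 <- policyGradientUpdate(gen, b$tokens, b$lengths, rep(0, 16))
  expect_identical(generatorParams(upd0$model), generatorParams(gen))
  # same batch, same state: identical updates
  u1 <- policyGradientUpdate(gen, b$tokens, b$lengths, rep(1, 16))
  u2 <- policyGradientUpdate(gen, b$tokens, b$lengths, rep(1, 16))
  expect_identical(generatorParams(u1$model), generatorParams(u2$model))
  expect_error(policyGradientUpdate(gen, b$tokens, b$lengths, rep(1, 5)),
               "align")
})

test_that("rewarding an element's presence raises its sampled frequency", {
  gen <- smallPretrained()
  oxygenFreq <- function(model, n = 60) {
    set.seed(77)
    s <- sampleSmiles(model, n)$smiles
    mean(vapply(s, function(x)
      grepl("O", x, fixed = TRUE) || grepl("o", x, fixed = TRUE),
      logical(1)))
  }
  before <- oxygenFreq(gen)
  agent <- gen; opt <- NULL
  set.seed(55)
  for (i in 1:25) {
    b <- sampleSmiles(agent, 32)
    hasO <- vapply(b$smiles, function(x)
      grepl("O", x, fixed = TRUE) || grepl("o", x, fixed = TRUE), logical(1))
    upd <- policyGradientUpdate(agent, b$tokens, b$lengths, as.numeric(hasO),
                                optState = opt)
    agent <- upd$model; opt <- upd$optState
  }
  expect_gt(oxygenFreq(agent), before)
})

test_that("epoch metrics are the stated ratios", {
  objs <- toyObjectiveSet()
  smiles <- c(rep("CCNOCC", 5), rep("CCCCCC", 4), "C((")
  sc <- scoreMolecules(smiles, objs, "pareto")
  met <- computeMetrics(sc)
  expect_equal(met$validity, 0.9)
  expect_equal(met$desirability, 0.5)
  # two distinct structures among ten molecules
  expect_equal(met$uniqueness, 0.2)
  expect_true(met$mean_reward >= 0 && met$mean_reward <= 1)
  # molecules already seen stop counting as unique
  met2 <- computeMetrics(sc, seen = met$canonical)
  expect_equal(met2$uniqueness, 0)
  expect_error(computeMetrics(sc[0, ]), "empty")
})

test_that("evolutionary sampling honors its limit cases and contracts", {
  gen <- smallPretrained()
  other <- buildGenerator(generatorConfigOf(gen), generatorVocab(gen))
  # crossover off + mutation off: identical to plain agent sampling
  cfgPure <- evolutionConfig(crossover_threshold = 1, mutation_rate = 0)
  set.seed(41); e <- evolutionarySample(gen, other, other, 20, cfgPure)
  set.seed(41); p <- sampleSmiles(gen, 20)
  expect_identical(e$tokens, p$tokens)
  # reproducibility of the full evolutionary path
  cfg <- evolutionConfig(crossover_threshold = 0.5, mutation_rate = 0.05)
  set.seed(42); e1 <- evolutionarySample(gen, other, gen, 20, cfg)
  set.seed(42); e2 <- evolutionarySample(gen, other, gen, 20, cfg)
  expect_identical(e1$tokens, e2$tokens)
  expect_true(all(e1$logp <= 0))
  # vocabulary mismatch is an error
  v2 <- buildVocabulary(c("CCO"))
  g2 <- buildGenerator(tinyConfig(v2), v2)
  expect_error(evolutionarySample(gen, g2, gen, 5, cfg), "vocabulary")
})

test_that("the RL loop logs metrics, checkpoints, syncs and spares the prior", {
  gen <- smallPretrained()
  priorBefore <- generatorParams(gen)
  metricsFile <- tempfile(fileext = ".csv")
  ckptFile <- tempfile(fileext = ".rds")
  res <- trainRL(gen, gen, gen, toyObjectiveSet(), scheme = "pareto",
                 config = evolutionConfig(crover_sync_interval = 2L, seed = 5L),
                 epochs = 2L, sampleSize = 24L,
                 metricsPath = metricsFile, checkpointPath = ckptFile,
                 quiet = TRUE)
  expect_true(file.exists(metricsFile))
  expect_true(file.exists(ckptFile))
  log <- read.csv(metricsFile)
  expect_identical(nrow(log), 2L)
  expect_true(all(unlist(log[, -1]) >= 0 & unlist(log[, -1]) <= 1))
  # prior parameters are bit-identical after training
  expect_identical(generatorParams(gen), priorBefore)
  # epoch 2 is a sync epoch: crover equals the best checkpoint
  expect_identical(generatorParams(res$crover), generatorParams(res$best))
})

test_that("composite ranking weights desirability, reward and uniqueness", {
  scored <- data.frame(
    smiles = c("CCNOCC", "CCCCCC", "CCNOCC", "C(("),
    valid = c(TRUE, TRUE, TRUE, FALSE),
    desirable = c(TRUE, FALSE, TRUE, FALSE),
    r_star = c(1, 0.5, 0.9, 0),
    stringsAsFactors = FALSE)
  top <- compositeRank(scored, topN = 4L)
  # (desirable 1, reward 1, unique 1) -> composite 1
  expect_equal(top$composite[1], 1)
  expect_identical(top$smiles[1], "CCNOCC")
  # duplicate structure loses its uniqueness credit
  dup <- top[top$smiles == "CCNOCC" & top$r_star == 0.9, ]
  expect_equal(dup$unique, 0)
  expect_equal(dup$composite, 0.4 + 0.4 * 0.9)
  # affine midpoint
  mid <- data.frame(smiles = "CCO", valid = TRUE, desirable = TRUE,
                    r_star = 0.5, stringsAsFactors = FALSE)
  mid$desirable <- 0.5  # direct component check of the affine form
  expect_equal(compositeRank(mid, 1L)$composite,
               0.4 * 0.5 + 0.4 * 0.5 + 0.2 * 1)
  # top-N contract
  b <- makeScoredBatch(100, 1, seed = 1)
  big <- data.frame(smiles = sprintf("C%s", strrep("C", 1:100)), valid = TRUE,
                    desirable = b$rewards[, 1] > 0.5, r_star = b$rewards[, 1],
                    stringsAsFactors = FALSE)
  expect_identical(nrow(compositeRank(big, 10L)), 10L)
})
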