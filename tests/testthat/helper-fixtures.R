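# Shared fixtures, built once per test run. Chemistry-backend noise on stderr
# (OpenBabel parse warnings for deliberately bad SMILES) is expected.

.molforge_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .molforge_cache))
    assign(key, force(expr), envir = .molforge_cache)
  get(key, envir = .molforge_cache)
}

# A small corpus + vocabulary for cheap unit tests.
smallCorpus <- function() cached("smallCorpus", makeToyCorpus(300, seed = 7))
smallVocab <- function() cached("smallVocab", buildVocabulary(smallCorpus()))

# Tiny generator configuration used across generator/RL tests.
tinyConfig <- function(vocab, seed = 11L)
  generatorConfig(vocab_size = vocabSize(vocab), embed_dim = 32L,
                  hidden_size = 64L, block_layers = 2L, num_blocks = 1L,
                  attention_heads = 2L, key_dim = 32L, max_len = 60L,
                  batch_size = 64L, seed = seed)

# A briefly pretrained small generator: enough training that most samples are
# grammatical, cheap enough to build once and reuse.
smallPretrained <- function() cached("smallPretrained", {
  corpus <- makeToyCorpus(1500, seed = 5)
  vocab <- buildVocabulary(corpus)
  gen <- buildGenerator(tinyConfig(vocab), vocab)
  suppressMessages(pretrainGenerator(gen, corpus, 12, quiet = TRUE))$model
})

# Toy design objectives mirroring a two-on-target / one-off-target problem:
# reward nitrogen and oxygen content, penalize sulfur.
toyObjectiveSet <- function()
  list(toyObjective("TN", "N", "high_affinity", cap = 2L),
       toyObjective("TO", "O", "high_affinity", cap = 2L),
       toyObjective("TS", "S", "low_affinity", cap = 1L))

# Independent O(N^2) oracle for non-dominated sorting: peel layers by
# direct pairwise dominance comparison.
bruteForceFronts <- function(scores) {
  # peel non-dominated layers by direct pairwise comparison
  left <- seq_len(nrow(scores))
  fronts <- list()
  while (length(left)) {
    nd <- left[vapply(left, function(i)
      !any(vapply(left, function(j)
        j != i && dominates(scores[j, ], scores[i, ]), logical(1))),
      logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    left <- setdiff(left, nd)
  }
  fronts
}

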