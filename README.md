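# molforge

Multi-objective de novo molecular design in R: a recurrent SMILES language
model trained by policy-gradient reinforcement learning against
random-forest QSAR activity predictors, with Pareto or weighted-sum
multi-objective rewards and evolutionary crossover/mutation sampling.

## The problem

Lead molecules must usually satisfy several pharmacological objectives at
once — for instance, high affinity for the adenosine A1/A2A receptors while
avoiding the cardiotoxic hERG channel. `molforge` implements the full design
loop for such problems:

1. **Corpus preparation** — SMILES standardization (salt stripping, charge
   neutralization, metal and size filters, canonical deduplication),
   atom-level tokenization and vocabulary construction.
2. **QSAR reward models** — each molecule becomes a 2067-dimensional vector
   (2048-bit ECFP6 + 19 physicochemical descriptors, min–max scaled) feeding
   a 1000-tree random-forest regression of pX (−log activity). Records
   without a defined activity get the placeholder pX 3.99 at sample weight
   0.1; actives (pX ≥ 6.5) carry weight 1.0.
3. **Generator** — token embedding → stacked LSTM blocks (rectifier +
   projection between blocks) → causal multi-head self-attention → softmax
   over the vocabulary; teacher-forced NLL pretraining with Adam. The
   network and its backpropagation are implemented in compiled
   RcppArmadillo code and verified against finite-difference gradients.
4. **Multi-objective rewards** — predicted pX is normalized over [4, 9]
   (pX 6.5 ↦ 0.5, the threshold); high-affinity objectives score the value,
   off-targets its complement, invalid SMILES score 0. Rewards combine
   either by an adaptive **weighted sum** (w_i ∝ N_below/N_above per
   objective) or by the **Pareto scheme**: threshold-clipped scores,
   non-dominated sorting, within-front ranking by mean Tanimoto distance
   (diversity), and the rank-to-reward map R\* = 0.5 + (k − N_und)/(2·N_des)
   for desired molecules, k/(2·N_und) for undesired ones.
5. **Reinforcement learning** — per epoch: evolutionary sampling from agent
   / crover / frozen prior networks (crossover threshold 0.5, mutation
   threshold 0.01), roulette-wheel selection of the top 20%, and a REINFORCE
   update J = Σ_t log G(y_t|y_{1:t−1})·R\*; the best checkpoint is kept and
   agent/crover resynchronize to it on a fixed interval. Generated molecules
   are finally ranked by 0.4·desirability + 0.4·reward + 0.2·uniqueness.

Deterministic synthetic-data generators (fragment-grammar corpora, a known
structure–activity law, random scored batches) make every stage runnable and
testable without any database download. See the methods vignette
(`vignettes/molforge-methods.Rmd`) for the model details, parameter
defaults, design decisions and limitations.

## Worked example

A desk-scale run: pretrain a small generator on a synthetic corpus, sample,
and score against a conflicted three-objective set (reward N and O content,
penalize N+O excess — a miniature on-/off-target problem):

```r
library(molforge)

corpus <- makeToyCorpus(1500, seed = 5)
vocab  <- buildVocabulary(corpus)
vocab
#> Vocabulary of 17 tokens (GO at 1, EOS at 2)
#>    GO EOS ( ) 1 2 = C Cl F N O ...

cfg <- generatorConfig(vocab_size = vocabSize(vocab), embed_dim = 32,
                       hidden_size = 64, block_layers = 2, num_blocks = 1,
                       attention_heads = 2, key_dim = 32, max_len = 60,
                       batch_size = 64, seed = 11)
fit <- pretrainGenerator(buildGenerator(cfg, vocab), corpus, epochs = 12,
                         quiet = TRUE)
round(range(fit$log$loss), 2)   # per-sequence NLL across epochs (min, max)
#> [1] 16.03 48.85

set.seed(42)
batch <- sampleSmiles(fit$model, 100)
mean(isValidSmiles(batch$smiles))
#> [1] 0.52

scored <- scoreMolecules(batch$smiles, conflictedObjectives(),
                         scheme = "pareto")
compositeRank(scored, topN = 3)[, c("smiles", "valid", "desirable",
                                    "r_star", "composite")]
#>           smiles valid desirable r_star composite
#>  CC(C)CC1CCNCC1O  TRUE      TRUE 0.9375     0.975
#>         CNCC(=O)  TRUE      TRUE 0.8750     0.950
#>     CCCC(=O)CCNc  TRUE      TRUE 0.8125     0.925
```

After only 12 pretraining epochs half the samples are already valid (30
epochs on a 5,000-molecule corpus takes this above 0.95 — that is what the
acceptance script measures); the top-ranked molecules are valid, desirable
(threshold reached on all three objectives) and structurally distinct, with
`r_star` the Pareto rank-to-reward score and `composite` the final 0.4/0.4/0.2
blend. `trainRL()` would now sharpen the generator toward such molecules.

A command-line interface over the same functions ships at
`inst/cli/molforge.R` (subcommands `preprocess`, `build-vocab`, `train-qsar`,
`pretrain`, `finetune`, `rl`, `sample`, `rank`).

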