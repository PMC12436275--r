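---
title: "Multi-objective de novo molecular design with molforge"
author: "molforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective de novo molecular design with molforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Designing a drug candidate is rarely a single-objective exercise. A molecule
aimed at the adenosine receptors, for example, should bind A1 and/or A2A
tightly while staying away from the hERG potassium channel, whose blockade is
cardiotoxic. molforge implements a complete de novo design loop for this kind
of problem: a recurrent SMILES language model proposes molecules, per-target
QSAR models predict their activities, a multi-objective scheme condenses
those activities into a single reward, and policy-gradient reinforcement
learning pushes the generator toward molecules that satisfy every objective
at once. Because the full-scale setting needs a ChEMBL-sized corpus and long
training, the package also ships deterministic synthetic-data generators so
that every stage runs, and is tested, at desk scale.

## Data preparation

Activity records enter as a CSV table (compound id, SMILES, target id, pX,
comment, standard type/relation). `standardizeMolecule()` mirrors the usual
database clean-up: the largest organic fragment is kept (counter-ions
dropped), charges are neutralized by hydrogen shifts where chemistry permits,
molecules containing atoms outside the organic subset {H, B, C, N, O, F, Si,
P, S, Cl, Se, Br, I} are rejected as metals, and the survivor is rendered as
a canonical SMILES. The size window separating "too small" and "too large"
molecules is a free choice; we default to 5–100 heavy atoms (configurable),
which brackets drug-like space. `filterDataset()` then
deduplicates on the canonical SMILES; filtering is idempotent.

pX labelling (`assignPxLabels()`) follows the low-quality-data rule: records
with no defined pX, or flagged inactive, receive the placeholder pX = 3.99 —
just under the "inactive" boundary of 4 — and a sample weight of 0.1, so the
regression forest learns that such structures score low without letting them
swamp the actives, which carry weight 1.0 at or above the bioactivity
threshold pX = 6.5. Replicates of a compound–target pair are aggregated by
the mean of their defined pX values; aggregation by mean is our choice where
the procedure is otherwise unspecified.

## Featurization and the QSAR model

Each molecule becomes a 2067-dimensional vector: a 2048-bit circular
fingerprint of radius 3 (ECFP6) plus 19 physicochemical descriptors
(molecular weight, logP, H-bond acceptors/donors, rotatable bonds, amide
bonds, bridgehead atoms, heteroatoms, spiro atoms, heavy atoms, fraction of
sp3 carbons, aliphatic/saturated/total/aromatic rings, heterocycles, valence
electrons, TPSA, molar refractivity). The chemistry backend is OpenBabel
(through ChemmineR/ChemmineOB and the `obabel` CLI): its ECFP6 implementation
emits 4096 bits, which we fold to 2048 by OR-ing the two halves; bulk
properties come from OpenBabel descriptors, count descriptors from SMARTS
matching, and ring-system descriptors from ring perception on the connection
table. Ring counting uses the ring basis (rings of size ≤ 7 plus the
cyclomatic number for the total); heavily bridged cage systems may count
slightly differently than in other toolkits, which matters little for
drug-like chemistry and not at all for internal consistency, since the same
featurizer is used for training and prediction. Features are min–max scaled
to [0,1] on the training set; features constant in the fit set map to 0 and
out-of-range values at prediction time are clamped.

The activity model is a 1000-tree random-forest regression
(`trainQsar()`, backed by ranger) with the 1.0/0.1 weights applied as case
weights. Splitting uses variance reduction (squared error): the Gini index
sometimes quoted for random forests is a classification criterion and cannot
drive a regression forest. `mtry` defaults to the forest library's
default (⌊√p⌋ ≈ 45 of 2067): on the synthetic structure–activity benchmark
below this recovers the activity law with held-out R² ≈ 0.91 in a fraction
of the time denser splits need, and the setting is exposed for users who
want the costlier ⌊p/3⌋. Prediction canonicalizes its inputs first, so
equivalent SMILES renderings receive identical predictions; invalid SMILES
are marked `NA` and handled downstream as invalid molecules, never raised as
errors.

A note on evaluating recovery: the held-out R² is computed over records with
a *defined* pX. Placeholder-labelled records stay in the training set — they
are what the 3.99 rule is for — but scoring predictions against an imputed
constant would measure the imputation, not the model.

## The generator

The SMILES language model is, in full scale: a 128-dimensional token
embedding; three stacked LSTM blocks of three layers each (nine recurrent
layers) with hidden width 512; between blocks, an element-wise rectifier
followed by a learned projection back to the embedding width, so each block
consumes an embedding-shaped input; a single multi-head self-attention layer
over the final block's output sequence (4 heads × key width 128 = 512, no
residual connection); and a linear layer to vocabulary logits. The
nine recurrent layers are organized as 3 blocks × 3 layers with the
activation/projection in between; both counts are configurable. Attention is
standard scaled dot-product attention, softmax(QKᵀ/√d_k)V. It is causal (position t attends to positions ≤ t) so that training
and autoregressive sampling see the same information flow. The ordering
"rectifier, then projection" between blocks is our resolution of an
unspecified detail.

Vocabularies are built from the corpus: atom-level tokens (bracket
expressions, two-letter halogens and `%nn` ring closures atomic, which
guarantees lossless round-trips), with the control tokens GO and EOS first
and the rest in radix order, so identical corpora give identical vocabulary
files. Training is teacher-forced negative log-likelihood (GO prepended, EOS
appended, right-padding masked out of the loss, loss summed per sequence and
averaged per batch) under Adam at learning rate 1e-3; batch size defaults to
512 at full scale. Sampling draws tokens from the temperature-scaled softmax
(default 1.0; 0 is greedy) until EOS or the 100-token cap, recording
per-sequence log-probabilities for the policy gradient. There is no deep
learning framework in the package's dependency footprint: the forward and
backward passes (including attention) are implemented in compiled
RcppArmadillo code and verified against finite-difference gradients in the
test suite. All randomness flows through R's RNG, so a single `set.seed()`
reproduces batches, trajectories and whole training runs bit for bit.

## Rewards and the two multi-objective schemes

Predicted pX is normalized by an affine map over the fixed activity range
[4, 9], clamped to [0,1]; pX 6.5 lands exactly on 0.5, which doubles as the
objective threshold. (Normalizing across the batch instead cannot pin 6.5 to
0.5, so the fixed range is the default and batch-relative scaling is
available behind an argument.) High-affinity objectives score the normalized value, off-target
(low-affinity) objectives its complement, and an invalid SMILES scores 0 on
every objective. A molecule is *desirable* when it is valid and reaches the
threshold on every objective; *validity* and *uniqueness* (new distinct
canonical structures) complete the per-epoch metrics.

The weighted scheme counts, per objective, molecules below and above the
threshold, forms rᵢ = N_below/N_above (denominator floored at one molecule),
normalizes the ratios into weights summing to 1 (uniform when all ratios
vanish), and scores each molecule by the weighted mean of its objective
rewards — objectives the batch is failing at get more weight.

The Pareto scheme first clips each reward at its threshold (scores above t
become 1, below scale as R/t), so dominance cannot distinguish molecules
that are already good enough on an objective. Non-dominated sorting peels
the batch into fronts; within a front molecules are ordered by the mean
Tanimoto distance (2048-bit fingerprints) to the other front members, more
distant — more structurally novel — molecules ranking higher. Mean pairwise
Tanimoto distance within the front is our choice of diversity measure, and
the distance function is injectable. Ranks are then re-sorted with desirability as the
primary key and mapped to rewards: undesired molecules get k/(2·N_undesired)
∈ [0, 0.5), desired ones 0.5 + (k − N_undesired)/(2·N_desired) ∈ [0.5, 1),
so the classes are separated by construction. When one class is
empty the other uses its own block formula. Ties in the distance ranking are
broken by input order, for determinism.

## The reinforcement-learning loop

Each epoch: (1) sample a batch of SMILES; (2) predict pX per objective and
assemble rewards under the chosen scheme; (3) select the top 20% of the
batch by roulette-wheel selection (probability proportional to reward,
without replacement, renormalizing after each draw — exactly ⌈0.2·N⌉
winners); (4) update the agent by one Adam step on the REINFORCE objective
J = Σ_t log G(y_t|y_{1:t−1})·R\*, i.e. sequence log-likelihood weighted by
final reward. An all-zero reward batch contributes no gradient and leaves
the parameters untouched.

Sampling is evolutionary: three models of identical architecture take part.
The *agent* is trained; the *crover* carries the last synchronized best
checkpoint; the *prior* keeps the pretrained weights and never changes. At
every generation step of every sequence, a mutation draw below the mutation
threshold hands the step's token distribution to the prior; otherwise a
crossover draw above the crossover threshold (0.5) hands it to the crover,
else the agent emits. All three models consume the chosen token so their
hidden states stay in lockstep. The mutation threshold defaults to 0.01 and
is exposed in the configuration. The agent checkpoint with the highest
epoch mean reward is kept, and every `crover_sync_interval` epochs (250 at
full scale) both agent and crover are reset to it.

After training, `compositeRank()` orders generated molecules by
0.4·desirability + 0.4·reward + 0.2·uniqueness (uniqueness as a per-molecule
first-occurrence indicator, since a batch-level fraction is not attributable
to one molecule) and returns the top 10 by default.

## Synthetic data: what it does and does not emulate

`makeToyCorpus()` assembles valid, standardizable SMILES from a ~20-fragment
grammar (alkyl chains and ether/amine/amide/ester/thioether linkers around
benzene, pyridine, furan, pyrrole and saturated rings). The grammar is
deliberately compact so a reduced generator reaches high sampled validity
within a short pretraining budget. `makeToySar()` overlays a known activity
law, px = 4 + 5·min(marker count, cap)/cap + Gaussian noise, clamped to
[3, 10], with ~10% of records emitted without a pX to exercise the 3.99
rule; the default marker is the amide bond, which the grammar installs in
varying numbers. `makeScoredBatch()` supplies uniform random reward vectors
with paired random fingerprints for the Pareto machinery's oracle tests.
Everything is a deterministic function of its seed.

These fixtures establish that the machinery works: that the tokenizer,
models, rewards and training loop do what they claim on data whose truth is
known. They do not emulate real structure–activity landscapes — activity
cliffs, assay noise structure, scaffold bias, or the sheer diversity of
ChEMBL — so passing tests bound the implementation's correctness, not the
method's real-world performance.

For desk-scale reinforcement-learning experiments the package provides
`toyObjective()` (pseudo-pX from saturating element counts, evaluated in
microseconds) and `conflictedObjectives()`, a three-objective miniature of
an on-/off-target problem: two high-affinity objectives reward nitrogen and
oxygen content (saturating at two atoms), one off-target penalizes total
N+O (saturating at four), so all three are jointly satisfiable only on a
narrow composition while the on-target rewards keep rising past it. The
conflict is essential: with independent, easily satisfied objectives the
weighted sum is an excellent reward and the two schemes do not separate —
the Pareto scheme's advantage is precisely in refusing the shortcut of
over-optimizing a subset of objectives, the same tension as potency versus
hERG liability.

## Problem sizes used by the tests

The shipped tests and the acceptance script run reduced configurations,
chosen as the package's own desk-scale reproduction sizes:

* Pretraining/validity: 5,000 fixture molecules (seed 1), a generator with
  embedding 64, one 2-layer LSTM block of width 128, 2 attention heads,
  batch 128, 30 epochs; 1,000 samples at temperature 1.0.
* QSAR recovery: 2,000 synthetic records, noise 0.2 pX units, 1,600/400
  split, 1000 trees, default `mtry`; R² scored on defined-pX records.
* Scheme comparison: a small generator (1,500-molecule corpus, 12
  pretraining epochs, width 64) run for 200 RL epochs per scheme on
  `conflictedObjectives()`, batch 64, crover sync every 25 epochs, three
  seeds; compared on mean desirability over the final 10 epochs. The
  comparison is stochastic by nature and asserted as an ordering across
  seeds, not as absolute values.
* Unit tests use yet smaller models; the full-scale defaults (512-wide,
  9-layer generator, 1000/1500-epoch RL runs) are exercised only for shape
  and configuration correctness.

## Numerical and engineering choices

* Weight initialization: fan-in-scaled normals; LSTM forget-gate biases
  start at 1. Optimizer: Adam (β₁ 0.9, β₂ 0.999, ε 1e-8).
* Softmax computations subtract the row maximum; log-probabilities are
  floored at ~1e-300 before logging.
* Validity = our own syntax check (token grammar, balanced branches, paired
  ring bonds) *and* an OpenBabel parse. OpenBabel alone is too lenient (it
  silently accepts `C((` as `C`), and the in-process conversion stream
  aborts at hard errors, so batch canonicalization goes through the
  `obabel` CLI with continue-after-error.
* Sequences longer than `max_len` tokens are dropped from training with a
  logged count; generation stops at EOS or `max_len`.
* Roulette selection with all-zero scores falls back to uniform; if fewer
  molecules than requested have positive score, the remainder is drawn
  uniformly from the zero-score ones.
* One run seed drives everything (corpus, initialization, shuffling,
  sampling, selection), so equal configurations give bit-identical CSV
  outputs.

## Limitations

* The chemistry backend is OpenBabel, not RDKit: descriptor values (logP,
  TPSA, fingerprint hashing) differ numerically from RDKit's, so models
  trained here are internally consistent but not bit-comparable with
  RDKit-based pipelines.
* Charge neutralization is a hydrogen-shift heuristic; permanently charged
  species (quaternary ammonium) keep their charge.
* Full-scale training (millions of molecules, 512-wide generator, 1000+
  RL epochs) is out of desk scope; the compiled core is single-threaded.
* Docking or any structure-based triage of designed molecules is out of
  scope; the composite ranking is the package's final output.
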