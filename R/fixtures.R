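# Deterministic synthetic-data generators: a fragment-grammar SMILES corpus,
# a synthetic structure-activity table, and random scored batches for the
# multi-objective machinery. Everything is a pure function of its seed, so
# every pipeline stage is testable without external databases.

.FIX_STARTS <- c("C", "CC", "CCC", "CCO", "CCN", "CC(C)")
.FIX_LINKERS <- c("O", "N", "C", "CC", "S", "C(=O)", "C(=O)N", "C(=O)O",
                  "NC(=O)")
.FIX_ENDS <- c("", "C", "CC", "O", "N", "F", "Cl", "C(=O)O", "C(=O)N")
# ring templates; '1' is replaced by the ring-instance digit
.FIX_RINGS <- c("c1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccoc1", "c1cc[nH]c1",
                "C1CCCCC1", "C1CCNCC1")

.composeMolecule <- function() {
  nRings <- sample.int(3L, 1L, prob = c(0.2, 0.5, 0.3)) - 1L
  parts <- sample(.FIX_STARTS, 1L)
  if (nRings > 0L) {
    for (j in seq_len(nRings)) {
      ring <- gsub("1", as.character(j), sample(.FIX_RINGS, 1L), fixed = TRUE)
      parts <- c(parts, sample(.FIX_LINKERS, 1L), ring)
    }
  } else {
    parts <- c(parts, sample(.FIX_LINKERS, 1L), sample(.FIX_STARTS, 1L))
  }
  paste(c(parts, sample(.FIX_ENDS, 1L)), collapse = "")
}

#' Synthetic drug-like SMILES corpus
#'
#' Assembles syntactically valid, standardizable SMILES from a small fragment
#' grammar (alkyl chains, benzene/pyridine/furan/pyrrole/saturated rings,
#' ether/amine/amide/ester/thioether linkers). The grammar is deliberately
#' compact (about 20 fragments) so that a reduced language model reaches
#' high sampled validity within a short pretraining budget. Deterministic per
#' seed.
#'
#' @param n number of SMILES.
#' @param seed integer seed.
#' @param maxHeavyAtoms upper bound on heavy atoms (oversized draws are
#'   redrawn; the grammar's range is roughly 5-40).
#' @return character vector of `n` SMILES.
#' @export
makeToyCorpus <- function(n, seed = 1L, maxHeavyAtoms = 60L) {
  stopifnot(n > 0L)
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:20) {
      s <- .composeMolecule()
      nh <- .heavyAtomCount(tokenizeSmiles(s))
      if (nh >= 5L && nh <= maxHeavyAtoms) break
      s <- "CCCCC"
    }
    out[i] <- s
  }
  out
}

#' Synthetic structure-activity table
#'
#' Emits ligand-style activity records over a fragment-grammar corpus whose
#' pX is a deterministic function of substructure content plus Gaussian
#' noise: `px = 4 + 5 * min(count, cap) / cap + N(0, noiseSd)`, clamped to
#' [3, 10], where `count` is the number of (unique) matches of the marker
#' SMARTS. About 10% of records are emitted with an undefined pX to exercise
#' the placeholder-labelling rule.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param noiseSd Gaussian noise standard deviation in pX units.
#' @param marker SMARTS pattern carrying the activity signal (default: amide
#'   bond, which the fragment grammar installs in varying numbers).
#' @param cap marker count at which the activity saturates (default 2).
#' @param missingFraction fraction of records with undefined pX.
#' @param targetId target identifier stamped on every record.
#' @return data.frame with columns `compound_id`, `smiles`, `target_id`,
#'   `px` (NA where undefined), `comment`, `standard_type`,
#'   `standard_relation`, plus attribute `true_px` (the noise-free value).
#' @export
makeToySar <- function(n, seed = 1L, noiseSd = 0.2,
                       marker = "[CX3](=[OX1])[NX3]", cap = 2L,
                       missingFraction = 0.1, targetId = "TOY") {
  smiles <- makeToyCorpus(n, seed = seed)
  ids <- paste0("mfid", seq_len(n))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids)))
  ChemmineR::cid(sdf) <- ids
  counts <- tryCatch(
    as.numeric(ChemmineR::smartsSearchOB(sdf, marker, uniqueMatches = TRUE)),
    error = function(e) stop(sprintf("invalid marker SMARTS '%s'", marker)))
  truePx <- 4 + 5 * pmin(counts, cap) / cap
  px <- pmin(pmax(truePx + stats::rnorm(n, 0, noiseSd), 3), 10)
  missing <- stats::runif(n) < missingFraction
  px[missing] <- NA_real_
  out <- data.frame(compound_id = sprintf("TOY%06d", seq_len(n)),
                    smiles = smiles, target_id = targetId, px = px,
                    comment = ifelse(missing, "No activity recorded", ""),
                    standard_type = "Ki", standard_relation = "=",
                    stringsAsFactors = FALSE)
  attr(out, "true_px") <- truePx
  out
}

#' Random scored batch for the multi-objective machinery
#'
#' Uniform random reward vectors in `[0,1]^k` paired with random binary
#' fingerprints; the test harness for non-dominated sorting and the
#' diversity ranking.
#'
#' @param n batch size (>= 2).
#' @param nObjectives number of objectives.
#' @param seed integer seed.
#' @param fpBits fingerprint length.
#' @param fpDensity probability of a set bit.
#' @return list with `rewards` (n x nObjectives) and `fps` (n x fpBits 0/1).
#' @export
makeScoredBatch <- function(n, nObjectives = 3L, seed = 1L, fpBits = 128L,
                            fpDensity = 0.3) {
  stopifnot(n >= 2L)
  set.seed(seed)
  list(rewards = matrix(stats::runif(n * nObjectives), n, nObjectives),
       fps = matrix(as.integer(stats::runif(n * fpBits) < fpDensity),
                    n, fpBits))
}

#' Toy design objective from element counts
#'
#' A synthetic [ObjectiveSpec-class] whose "predicted" pX is a deterministic
#' function of the molecule's composition:
#' `px = 4 + 5 * min(count, cap) / cap`, where `count` is the number of atoms
#' of the given element. Useful for desk-scale reinforcement-learning runs
#' where a real QSAR model would dominate the runtime: the reward is fast,
#' noise-free and directly interpretable (e.g. a high-affinity objective on
#' nitrogen rewards molecules containing amines/azines).
#'
#' @param targetId identifier for the objective.
#' @param element element symbol(s) counted in the molecule (e.g. `"N"`, or
#'   `c("N", "O")` for a summed count).
#' @param direction `"high_affinity"` or `"low_affinity"`.
#' @param cap count at which the pseudo-activity saturates.
#' @param threshold reward threshold of the objective.
#' @return an [ObjectiveSpec-class].
#' @export
toyObjective <- function(targetId, element, direction = "high_affinity",
                         cap = 2L, threshold = 0.5) {
  force(element); force(cap)
  predictor <- function(smiles) {
    vapply(smiles, function(s) {
      cnt <- tryCatch({
        toks <- tokenizeSmiles(s)
        if (!.syntaxOk(toks)) NA_real_ else {
          els <- vapply(toks, .tokenElement, character(1), USE.NAMES = FALSE)
          sum(!is.na(els) & els %in% element)
        }
      }, error = function(e) NA_real_)
      if (is.na(cnt)) return(NA_real_)
      4 + 5 * min(cnt, cap) / cap
    }, numeric(1), USE.NAMES = FALSE)
  }
  objectiveSpec(targetId, direction, threshold, predictor)
}

#' Conflicted toy objective set for scheme comparisons
#'
#' A three-objective miniature of an on-/off-target selectivity problem over
#' the fixture chemistry: two high-affinity objectives reward nitrogen and
#' oxygen content (saturating at two atoms each) and one low-affinity
#' off-target penalizes total N+O content (saturating at four). All three are
#' jointly satisfiable only on a narrow composition (exactly one N and one
#' O), but the on-target rewards keep rising past it -- the same structural
#' tension as designing potent A1/A2A ligands without hERG liability, where
#' the features that drive potency also drive the off-target.
#'
#' @return list of three [ObjectiveSpec-class] objects.
#' @export
conflictedObjectives <- function() {
  list(toyObjective("ON1", "N", "high_affinity", cap = 2L),
       toyObjective("ON2", "O", "high_affinity", cap = 2L),
       toyObjective("OFF", c("N", "O"), "low_affinity", cap = 4L))
}
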