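# Multi-objective reward engine: per-objective rewards, the adaptive
# weighted-sum scheme, and Pareto non-dominated sorting with the
# diversity-ranked reward map.

#' Normalize predicted pX to a [0,1] reward score
#'
#' Affine map over the fixed activity range [4, 9], clamped: pX 4 maps to 0,
#' pX 9 to 1, and the bioactivity threshold pX 6.5 to exactly 0.5 (the reward
#' threshold). A batch-relative min-max mode is available for experimentation
#' but cannot guarantee the 6.5 -> 0.5 anchor, so the fixed range is the
#' default.
#'
#' @param px numeric vector of pX values (NA allowed; propagated).
#' @param range activity range, default `c(4, 9)`.
#' @param batch if `TRUE`, scale by the batch's own min/max instead.
#' @return numeric vector in [0,1] (monotone non-decreasing in `px`).
#' @export
normalizePx <- function(px, range = c(4, 9), batch = FALSE) {
  if (batch) {
    fin <- px[is.finite(px)]
    if (!length(fin)) return(rep(NA_real_, length(px)))
    lo <- min(fin); hi <- max(fin)
    if (hi == lo) return(ifelse(is.finite(px), 0.5, NA_real_))
    return(pmin(pmax((px - lo) / (hi - lo), 0), 1))
  }
  pmin(pmax((px - range[1]) / (range[2] - range[1]), 0), 1)
}

#' Reward of one objective for one predicted pX
#'
#' Invalid molecules score 0 on every objective. High-affinity objectives
#' reward the normalized pX directly; low-affinity (off-target) objectives
#' reward its complement `1 - normalizePx(px)`.
#'
#' @param px numeric vector of predicted pX (NA treated as invalid).
#' @param direction `"high_affinity"` or `"low_affinity"` (or an
#'   [ObjectiveSpec-class] whose direction is used).
#' @param valid logical vector; `FALSE` forces a 0 reward.
#' @param range passed to [normalizePx()].
#' @return numeric vector in [0,1].
#' @export
objectiveReward <- function(px, direction = "high_affinity",
                            valid = TRUE, range = c(4, 9)) {
  if (is(direction, "ObjectiveSpec")) direction <- direction@direction
  direction <- match.arg(direction, c("high_affinity", "low_affinity"))
  r <- normalizePx(px, range)
  if (direction == "low_affinity") r <- 1 - r
  r[!is.finite(r)] <- 0
  r[!valid] <- 0
  r
}

#' Adaptive weighted-sum reward
#'
#' Per objective i, counts the molecules scoring below (`N_il`) and at or
#' above (`N_ih`) the threshold, forms the ratio `r_i = N_il / N_ih`
#' (denominator floored at 1) and normalizes the ratios to weights summing
#' to 1 (uniform if every ratio is 0). The final reward of each molecule is
#' the weighted sum of its objective rewards, so objectives on which the
#' batch is failing gain weight.
#'
#' @param rewards numeric matrix, molecules x objectives, entries in [0,1].
#' @param thresholds per-objective thresholds (recycled; default 0.5).
#' @return list with `rstar` (per-molecule final reward in [0,1]) and
#'   `allocation` (data.frame `N_l`, `N_h`, `r`, `w`).
#' @export
weightedReward <- function(rewards, thresholds = 0.5) {
  stopifnot(is.matrix(rewards), nrow(rewards) >= 1L)
  k <- ncol(rewards)
  thresholds <- rep_len(thresholds, k)
  Nl <- vapply(seq_len(k), function(i) sum(rewards[, i] < thresholds[i]),
               numeric(1))
  Nh <- nrow(rewards) - Nl
  r <- Nl / pmax(Nh, 1)
  w <- if (sum(r) == 0) rep(1 / k, k) else r / sum(r)
  list(rstar = as.numeric(rewards %*% w),
       allocation = data.frame(N_l = Nl, N_h = Nh, r = r, w = w))
}

#' Threshold-clipped Pareto score
#'
#' Rewards above the objective threshold are indistinguishable for dominance
#' purposes (clipped to 1); below it they scale linearly as `R / t`.
#'
#' @param reward numeric vector/matrix of rewards in [0,1].
#' @param threshold objective threshold(s) in (0,1), recycled across columns
#'   for a matrix.
#' @return clipped scores, same shape.
#' @export
clipScore <- function(reward, threshold = 0.5) {
  if (is.matrix(reward)) {
    threshold <- rep_len(threshold, ncol(reward))
    return(vapply(seq_len(ncol(reward)),
                  function(i) clipScore(reward[, i], threshold[i]),
                  numeric(nrow(reward))))
  }
  ifelse(reward > threshold, 1, reward / threshold)
}

#' Pareto dominance
#'
#' `a` dominates `b` when it is at least as good in every component and
#' strictly better in at least one.
#'
#' @param a,b numeric score vectors of equal length.
#' @return logical.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors must have equal length")
  all(a >= b) && any(a > b)
}

#' Non-dominated sorting
#'
#' Partitions a batch of score vectors into successive Pareto fronts: front 1
#' holds the solutions dominated by none, front m those dominated only by
#' members of earlier fronts.
#'
#' @param scores numeric matrix, molecules x objectives (clipped scores).
#' @return list of integer vectors (row indices), best front first.
#' @export
nondominatedSort <- function(scores) {
  stopifnot(is.matrix(scores), nrow(scores) >= 1L)
  n <- nrow(scores)
  domCount <- integer(n)
  dominated <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(scores[i, ], scores[j, ]))
        dominated[[i]] <- c(dominated[[i]], j)
      else if (dominates(scores[j, ], scores[i, ]))
        domCount[i] <- domCount[i] + 1L
    }
  }
  fronts <- list()
  current <- which(domCount == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated[[i]]) {
        domCount[j] <- domCount[j] - 1L
        if (domCount[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Pairwise Tanimoto distance of binary fingerprints
#'
#' @param fps 0/1 matrix, molecules x bits.
#' @return symmetric distance matrix (1 - Tanimoto similarity); pairs with no
#'   set bits on either side get distance 0.
#' @export
tanimotoDistance <- function(fps) {
  stopifnot(is.matrix(fps))
  inter <- fps %*% t(fps)
  sz <- rowSums(fps)
  denom <- outer(sz, sz, "+") - inter
  sim <- ifelse(denom > 0, inter / denom, 1)
  1 - sim
}

#' Diversity-aware global ranking of Pareto fronts
#'
#' Orders molecules front by front, worst front first and the non-dominated
#' front last; within a front, ascending by the mean Tanimoto distance to the
#' other front members, so structurally more distant (more diverse) molecules
#' receive the later positions and hence the higher ranks. Ties preserve
#' input order; a singleton front has distance 0 by convention.
#'
#' @param fronts list of index vectors from [nondominatedSort()] (best
#'   first).
#' @param fps binary fingerprint matrix aligned with the molecule indices.
#' @return integer vector `k`: the 0-based global rank of each molecule (a
#'   permutation of `0..N-1`, higher is better).
#' @export
frontDistanceRank <- function(fronts, fps) {
  n <- sum(lengths(fronts))
  dist <- tanimotoDistance(fps)
  k <- integer(n)
  pos <- 0L
  for (f in rev(seq_along(fronts))) {
    idx <- fronts[[f]]
    meanDist <- if (length(idx) > 1L)
      vapply(seq_along(idx), function(i)
        mean(dist[idx[i], idx[-i]]), numeric(1))
    else 0
    ord <- idx[order(meanDist)]  # stable: ties keep input order
    k[ord] <- pos + seq_along(ord) - 1L
    pos <- pos + length(idx)
  }
  k
}

#' Rank-to-reward map over a Pareto ordering
#'
#' Re-sorts the global order so that desirability is the primary key (all
#' undesired molecules occupy ranks `0..N_undesired-1`, preserving the given
#' order within each class) and maps ranks to rewards: desired molecules get
#' `0.5 + (k - N_undesired) / (2 N_desired)`, undesired ones
#' `k / (2 N_undesired)`. Desired rewards therefore lie in [0.5, 1) and
#' undesired ones in [0, 0.5), separating the classes. When one class is
#' empty the occupied class uses its own block formula.
#'
#' @param order integer vector of 0-based global ranks (higher = better),
#'   e.g. from [frontDistanceRank()].
#' @param desired logical vector aligned with `order`.
#' @return list with `rstar` (per-molecule final reward) and `k` (the
#'   desirability-primary 0-based rank actually used).
#' @export
paretoReward <- function(order, desired) {
  stopifnot(length(order) == length(desired))
  n <- length(order)
  desired <- as.logical(desired)
  # primary key: desirability; secondary: the supplied order
  k <- integer(n)
  k[base::order(desired, order)] <- seq_len(n) - 1L
  nDes <- sum(desired); nUnd <- n - nDes
  rstar <- numeric(n)
  if (nDes > 0L)
    rstar[desired] <- 0.5 + (k[desired] - nUnd) / (2 * nDes)
  if (nUnd > 0L)
    rstar[!desired] <- k[!desired] / (2 * nUnd)
  list(rstar = rstar, k = k)
}

# Predicted pX from an objective's predictor (QSAR model or plain function).
.predictObjective <- function(spec, smiles) {
  pred <- spec@predictor
  if (is(pred, "QsarModel")) return(predictPx(pred, smiles))
  if (is.function(pred)) return(pred(smiles))
  stop(sprintf("objective %s has no predictor", spec@targetId))
}

#' Score a batch of generated molecules
#'
#' The full reward pipeline: validity, per-objective predicted pX and
#' rewards, desirability (valid and at/above threshold on every objective),
#' and the final reward under either the weighted-sum or the Pareto scheme.
#' The Pareto scheme clips scores at the objective thresholds, runs
#' non-dominated sorting, ranks within fronts by structural diversity
#' (Tanimoto on 2048-bit fingerprints) and maps ranks to rewards.
#'
#' @param smiles character vector of generated SMILES.
#' @param objectives list of [ObjectiveSpec-class] objects.
#' @param scheme `"pareto"` or `"weighted"`.
#' @param fingerprints optional 0/1 matrix for the diversity ranking;
#'   computed from the molecules when missing (invalid molecules get empty
#'   fingerprints).
#' @param batchNormalize use batch-relative pX normalization (see
#'   [normalizePx()]).
#' @return data.frame with columns `smiles`, `valid`, one reward column
#'   `R_<targetId>` per objective, `desirable`, `k` (Pareto rank; NA under
#'   the weighted scheme) and `r_star`. The weight allocation (weighted) or
#'   front list (Pareto) is attached as attribute `scheme_detail`.
#' @export
scoreMolecules <- function(smiles, objectives,
                           scheme = c("pareto", "weighted"),
                           fingerprints = NULL, batchNormalize = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(length(smiles) >= 1L, length(objectives) >= 1L)
  valid <- isValidSmiles(smiles)
  kObj <- length(objectives)
  thresholds <- vapply(objectives, function(o) o@threshold, numeric(1))
  rewards <- matrix(0, length(smiles), kObj)
  px <- matrix(NA_real_, length(smiles), kObj)
  for (i in seq_len(kObj)) {
    if (any(valid)) px[valid, i] <- .predictObjective(objectives[[i]],
                                                      smiles[valid])
    r <- if (batchNormalize)
      normalizePx(px[, i], batch = TRUE)
    else
      normalizePx(px[, i])
    if (objectives[[i]]@direction == "low_affinity") r <- 1 - r
    r[!is.finite(r)] <- 0
    r[!valid] <- 0
    rewards[, i] <- r
  }
  desirable <- valid &
    rowSums(sweep(rewards, 2L, thresholds, ">=")) == kObj

  out <- data.frame(smiles = smiles, valid = valid, stringsAsFactors = FALSE)
  for (i in seq_len(kObj))
    out[[paste0("R_", objectives[[i]]@targetId)]] <- rewards[, i]
  out$desirable <- desirable

  if (scheme == "weighted") {
    wr <- weightedReward(rewards, thresholds)
    out$k <- NA_integer_
    out$r_star <- wr$rstar
    attr(out, "scheme_detail") <- wr$allocation
  } else {
    clipped <- clipScore(rewards, thresholds)
    fronts <- nondominatedSort(clipped)
    if (is.null(fingerprints)) {
      fingerprints <- matrix(0L, length(smiles), 2048L)
      if (any(valid)) fingerprints[valid, ] <- .ecfp6(smiles[valid])
    }
    kOrder <- frontDistanceRank(fronts, fingerprints)
    pr <- paretoReward(kOrder, desirable)
    out$k <- pr$k
    out$r_star <- pr$rstar
    attr(out, "scheme_detail") <- fronts
  }
  out
}

#' Write a reward table to CSV
#'
#' @param scored data.frame from [scoreMolecules()].
#' @param path file path.
#' @return the input, invisibly.
#' @export
writeRewardTable <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE)
  invisible(scored)
}
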