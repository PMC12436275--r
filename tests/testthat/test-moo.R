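test_that("pX normalization anchors the activity range and threshold", {
  expect_identical(normalizePx(6.5), 0.5)
  expect_identical(normalizePx(4), 0)
  expect_identical(normalizePx(9), 1)
  expect_identical(normalizePx(11), 1)   # clamped
  expect_identical(normalizePx(2), 0)
  # monotone non-decreasing
  px <- sort(runif(50, 0, 14))
  expect_true(all(diff(normalizePx(px)) >= 0))
  # batch-relative mode normalizes by the batch extremes
  expect_equal(normalizePx(c(5, 6, 7), batch = TRUE), c(0, 0.5, 1))
})

test_that("objective rewards mirror direction and zero out invalid input", {
  expect_identical(objectiveReward(NA_real_, "high_affinity"), 0)
  expect_identical(objectiveReward(9, "low_affinity"), 0)
  expect_identical(objectiveReward(6.5, "high_affinity"), 0.5)
  expect_identical(objectiveReward(6.5, "low_affinity"), 0.5)
  expect_identical(objectiveReward(8, "high_affinity", valid = FALSE), 0)
  # low-affinity mirrors the high-affinity reward
  px <- runif(20, 3, 10)
  expect_equal(objectiveReward(px, "low_affinity"),
               1 - objectiveReward(px, "high_affinity"))
})

test_that("weighted scheme reproduces the hand-computed allocation", {
  # 40 molecules; objective 1 splits 20 below / 20 above threshold (r = 1),
  # objective 2 splits 30 below / 10 above (r = 3) -> weights (0.25, 0.75)
  r1 <- c(rep(0.4, 20), rep(0.6, 20))
  r2 <- c(rep(0.4, 30), rep(0.6, 10))
  wr <- weightedReward(cbind(r1, r2))
  expect_equal(wr$allocation$r, c(1, 3))
  expect_equal(wr$allocation$w, c(0.25, 0.75))
  expect_equal(sum(wr$allocation$w), 1)
  expect_true(all(wr$rstar >= 0 & wr$rstar <= 1))
  # unit rewards give unit final reward under any weights
  wr2 <- weightedReward(matrix(c(1, 1, 1, 0.2, 0.9, 0.1), 2, 3, byrow = TRUE))
  expect_equal(wr2$rstar[1], 1)
  # single objective: w = 1, R* = R
  wr3 <- weightedReward(matrix(c(0.3, 0.8), 2, 1))
  expect_equal(wr3$allocation$w, 1)
  expect_equal(wr3$rstar, c(0.3, 0.8))
  # degenerate: every molecule above threshold on every objective -> uniform
  wr4 <- weightedReward(matrix(0.9, 4, 2))
  expect_equal(wr4$allocation$w, c(0.5, 0.5))
  # monotonicity: raising one objective's reward never lowers R*
  b <- makeScoredBatch(30, 3, seed = 2)
  base <- weightedReward(b$rewards)
  up <- b$rewards; up[7, 2] <- min(1, up[7, 2] + 0.2)
  # reuse the baseline weights: same allocation applied to higher rewards
  expect_gte(sum(base$allocation$w * up[7, ]),
             sum(base$allocation$w * b$rewards[7, ]))
})

test_that("score clipping saturates above the threshold", {
  expect_identical(clipScore(0.8, 0.5), 1)
  expect_identical(clipScore(0.25, 0.5), 0.5)
  expect_identical(clipScore(0, 0.5), 0)
  expect_identical(clipScore(0.5, 0.5), 1)  # R = t -> R/t = 1
  m <- clipScore(matrix(c(0.8, 0.25, 0.3, 0.9), 2, 2), c(0.5, 0.6))
  expect_equal(m, matrix(c(1, 0.5, 0.5, 1), 2, 2))
})

test_that("dominance is a strict partial order on score vectors", {
  expect_true(dominates(c(0.6, 0.6, 0.6), c(0.5, 0.6, 0.4)))
  expect_false(dominates(c(0.5, 0.5), c(0.5, 0.5)))
  expect_false(dominates(c(1, 0), c(0, 1)))
  expect_false(dominates(c(0, 1), c(1, 0)))
  expect_error(dominates(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("non-dominated sorting agrees with the brute-force oracle", {
  for (s in 1:5) {
    b <- makeScoredBatch(40, 3, seed = s)
    scores <- clipScore(b$rewards, 0.5)
    expect_identical(nondominatedSort(scores), bruteForceFronts(scores))
  }
  # all-identical vectors form a single front
  expect_identical(nondominatedSort(matrix(0.5, 5, 2)),
                   list(1:5))
  # single molecule: one front
  expect_identical(nondominatedSort(matrix(c(0.2, 0.9), 1, 2)), list(1L))
  # fronts partition the batch
  b <- makeScoredBatch(60, 2, seed = 9)
  fr <- nondominatedSort(b$rewards)
  expect_identical(sort(unlist(fr)), 1:60)
})

test_that("diversity ranking orders fronts and is a permutation", {
  b <- makeScoredBatch(25, 3, seed = 3)
  fronts <- nondominatedSort(b$rewards)
  k <- frontDistanceRank(fronts, b$fps)
  expect_identical(sort(k), 0:24)
  # the best front occupies the highest ranks
  expect_equal(sort(k[fronts[[1]]], decreasing = TRUE),
                   seq(24, by = -1, length.out = length(fronts[[1]])))
  # duplicates tie and keep input order
  fps <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1))
  k2 <- frontDistanceRank(list(1:3), fps)
  expect_lt(k2[1], k2[2])     # tied duplicates stay in input order
  expect_identical(k2[3], 2L) # the distant structure ranks last (highest)
  # singleton front has distance 0 by convention and still ranks
  k3 <- frontDistanceRank(list(1L, 2:3), matrix(1, 3, 4))
  expect_identical(k3[1], 2L)
})

test_that("rank-to-reward separates desired from undesired molecules", {
  # hand-evaluated example: two desired, two undesired
  pr <- paretoReward(order = c(0, 1, 2, 3),
                     desired = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(pr$rstar, c(0, 0.25, 0.5, 0.75))
  # separation property on random batches
  for (s in 1:3) {
    b <- makeScoredBatch(30, 3, seed = s + 10)
    des <- b$rewards[, 1] > 0.5
    if (!any(des) || all(des)) next
    pr <- paretoReward(seq_len(30) - 1L, des)
    expect_gt(min(pr$rstar[des]), max(pr$rstar[!des]))
    expect_true(all(pr$rstar >= 0 & pr$rstar < 1))
  }
  # empty undesired class: block formula with its own count
  pr2 <- paretoReward(0:3, rep(TRUE, 4))
  expect_equal(pr2$rstar, 0.5 + (0:3) / 8)
  pr3 <- paretoReward(0:3, rep(FALSE, 4))
  expect_equal(pr3$rstar, (0:3) / 8)
})

test_that("the scoring pipeline assembles rewards, desirability and R*", {
  objs <- toyObjectiveSet()
  smiles <- c("CCNOCC",          # N and O, no S -> desirable
              "CCCCCC",          # neither
              "CCSNOC",          # has S -> off-target objective fails
              "C((")             # invalid
  sc <- scoreMolecules(smiles, objs, scheme = "pareto")
  expect_identical(sc$valid, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(sc$desirable[1])
  expect_false(any(sc$desirable[2:4]))
  expect_true(all(sc[4, grep("^R_", names(sc))] == 0))
  expect_true(all(sc$r_star >= 0 & sc$r_star <= 1))
  expect_identical(sort(sc$k), 0:3)
  # desired molecules sit in the upper reward half
  expect_gte(sc$r_star[1], 0.5)
  sw <- scoreMolecules(smiles, objs, scheme = "weighted")
  expect_true(all(is.na(sw$k)))
  expect_true(all(sw$r_star >= 0 & sw$r_star <= 1))
  aw <- attr(sw, "scheme_detail")
  expect_equal(sum(aw$w), 1)
})
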