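test_that("the toy corpus is deterministic, parseable and standardizable", {
  c1 <- makeToyCorpus(400, seed = 1)
  c2 <- makeToyCorpus(400, seed = 1)
  expect_identical(c1, c2)
  expect_identical(length(c1), 400L)
  expect_true(all(isValidSmiles(c1)))
  # every entry survives standardization unchanged in count
  std <- standardizeMolecule(unique(c1))
  expect_true(all(std$reason == ""))
  # different seeds give different corpora
  expect_false(identical(c1, makeToyCorpus(400, seed = 2)))
})

test_that("the synthetic SAR table encodes the stated activity law", {
  sar0 <- makeToySar(300, seed = 3, noiseSd = 0, missingFraction = 0)
  truePx <- attr(sar0, "true_px")
  # molecules without the marker sit at the floor, saturated ones at the top
  expect_true(any(truePx == 4) && any(truePx == 9))
  expect_equal(sar0$px, truePx)
  expect_true(all(sar0$px >= 3 & sar0$px <= 10))
  # about 10% of records lack pX at the default missing fraction
  sar <- makeToySar(1000, seed = 4)
  expect_gt(mean(is.na(sar$px)), 0.05)
  expect_lt(mean(is.na(sar$px)), 0.16)
  expect_identical(makeToySar(50, seed = 5)$px, makeToySar(50, seed = 5)$px)
  expect_error(makeToySar(10, marker = "[[[bad"), "invalid marker")
})

test_that("random scored batches are reproducible and well-ranged", {
  b1 <- makeScoredBatch(100, 3, seed = 1)
  b2 <- makeScoredBatch(100, 3, seed = 1)
  expect_identical(b1, b2)
  expect_identical(dim(b1$rewards), c(100L, 3L))
  expect_true(all(b1$rewards >= 0 & b1$rewards <= 1))
  expect_true(all(b1$fps %in% c(0L, 1L)))
})

test_that("toy objectives report the saturating element-count pseudo-pX", {
  ob <- toyObjective("T", "N", cap = 2L)
  px <- molforge:::.predictObjective(ob, c("CCCC", "CCN", "NCCN", "NNNCN"))
  expect_equal(px, c(4, 6.5, 9, 9))
  expect_true(is.na(molforge:::.predictObjective(ob, "C((")))
})
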