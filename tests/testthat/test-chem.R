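test_that("feature vectors are 2067-dimensional with sane descriptors", {
  x <- featurize(c("c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "CC(=O)NC"))
  expect_identical(dim(x), c(3L, 2067L))
  expect_identical(colnames(x), featureNames())
  benz <- x[1, ]
  expect_identical(unname(benz["aromatic_rings"]), 1)
  expect_identical(unname(benz["heteroatoms"]), 0)
  expect_identical(unname(benz["total_rings"]), 1)
  expect_identical(unname(benz["heavy_atoms"]), 6)
  # benzene C6H6: 6*4 + 6*1 valence electrons
  expect_identical(unname(benz["valence_electrons"]), 30)
  expect_identical(unname(x[3, "amide_bonds"]), 1)
  # aspirin and benzene differ in their fingerprints
  expect_gt(sum(x[1, 1:2048] != x[2, 1:2048]), 0)
  # fingerprint block is binary
  expect_true(all(x[, 1:2048] %in% c(0, 1)))
  expect_error(featurize("C(("), "invalid SMILES")
})

test_that("featurization is invariant to the SMILES rendering", {
  a <- featurize(c("OCCc1ccccc1", "CC(=O)NC"))
  b <- featurize(c("c1ccccc1CCO", "CNC(C)=O"))
  expect_equal(a[, , drop = FALSE], b[, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("min-max scaling maps the fit set onto [0,1] and constants to 0", {
  x <- matrix(c(0, 5, 10,
                2, 2, 2,
                -1, 0, 3), 3, 3)
  sc <- fitScaler(x)
  xs <- applyScaler(x, sc)
  expect_equal(xs[2, 1], 0.5)
  expect_true(all(xs[, 2] == 0))        # constant feature
  expect_equal(unname(apply(xs[, c(1, 3)], 2, min)), c(0, 0))
  expect_equal(unname(apply(xs[, c(1, 3)], 2, max)), c(1, 1))
  # new out-of-range data is clamped into [0,1]
  y <- applyScaler(matrix(c(20, 2, -5), 1, 3), sc)
  expect_true(all(y >= 0 & y <= 1))
  expect_error(applyScaler(x, list()), "not been fitted")
})
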