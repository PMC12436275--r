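test_that("pX labelling applies the placeholder, weights and aggregation", {
  rows <- data.frame(
    compound_id = c("a", "b", "c", "c", "d", "e"),
    smiles = c("CCO", "CCN", "CCCC", "CCCC", "CCS", ""),
    target_id = "T1",
    px = c(NA, 7.2, 6.0, 7.0, 5.0, 8.0),
    comment = c("", "", "", "", "", ""),
    stringsAsFactors = FALSE)
  expect_message(rec <- assignPxLabels(rows), "dropped 1")
  expect_identical(nrow(rec), 4L)
  a <- rec[rec$compound_id == "a", ]
  expect_equal(a$px, 3.99)
  expect_equal(a$sample_weight, 0.1)
  expect_equal(rec$sample_weight[rec$compound_id == "b"], 1.0)
  # replicate aggregation: mean of 6.0 and 7.0, at the 6.5 boundary -> active
  cc <- rec[rec$compound_id == "c", ]
  expect_equal(cc$px, 6.5)
  expect_equal(cc$sample_weight, 1.0)
  expect_equal(rec$sample_weight[rec$compound_id == "d"], 0.1)
  # "not active" comments force the placeholder
  rows2 <- data.frame(compound_id = "x", smiles = "CCO", target_id = "T1",
                      px = 7.5, comment = "Not Active", stringsAsFactors = FALSE)
  rec2 <- assignPxLabels(rows2)
  expect_equal(rec2$px, 3.99)
  expect_equal(rec2$sample_weight, 0.1)
})

test_that("the forest trains deterministically and predicts finitely", {
  sar <- makeToySar(60, seed = 4, noiseSd = 0.1)
  rec <- assignPxLabels(sar)
  m1 <- suppressMessages(trainQsar(rec, numTrees = 60L, seed = 9))
  m2 <- suppressMessages(trainQsar(rec, numTrees = 60L, seed = 9))
  probe <- c("CCOc1ccccc1", "CC(=O)NCC", "CCCCCC")
  expect_identical(predictPx(m1, probe), predictPx(m2, probe))
  expect_true(all(is.finite(predictPx(m1, probe))))
  # the stored weights are the 1.0/0.1 scheme
  expect_true(all(rec$sample_weight %in% c(0.1, 1.0)))
})

test_that("prediction marks invalid SMILES instead of raising", {
  sar <- makeToySar(40, seed = 6, noiseSd = 0.1)
  m <- suppressMessages(trainQsar(assignPxLabels(sar), numTrees = 40L, seed = 2))
  p <- predictPx(m, c("CCO", "C((", "c1ccccc1"))
  expect_identical(length(p), 3L)
  expect_true(is.na(p[2]))
  expect_true(all(is.finite(p[c(1, 3)])))
})

test_that("ligand tables round-trip through CSV", {
  sar <- makeToySar(25, seed = 8)
  f <- tempfile(fileext = ".csv")
  writeLigandTable(sar, f)
  back <- readLigandTable(f)
  expect_equal(back$px, sar$px)
  expect_identical(back$smiles, sar$smiles)
})
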