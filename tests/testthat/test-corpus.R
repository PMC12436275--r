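test_that("tokenizer keeps multi-character tokens atomic and round-trips", {
  expect_identical(tokenizeSmiles("CCO"), c("C", "C", "O"))
  expect_identical(tokenizeSmiles("CCl"), c("C", "Cl"))
  expect_identical(tokenizeSmiles("c1cc[nH]c1"),
                   c("c", "1", "c", "c", "[nH]", "c", "1"))
  expect_identical(tokenizeSmiles("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  for (s in smallCorpus())
    expect_identical(paste(tokenizeSmiles(s), collapse = ""), s)
})

test_that("tokenizer errors name the offending position", {
  expect_error(tokenizeSmiles("CC[nH"), "unmatched bracket at position 3")
  expect_error(tokenizeSmiles("CxQ"), "position 2")
  expect_error(tokenizeSmiles(""), "empty")
})

test_that("standardization strips salts, neutralizes and canonicalizes", {
  # counter-ion stripped + charge neutralized; expectation frozen from an
  # independent OpenBabel canonicalization of the neutral parent acid
  res <- standardizeMolecule("CC(=O)[O-].[Na+]", minHeavy = 1L)
  expect_identical(res$canonical, "CC(=O)O")
  # already-standard molecules pass through canonically
  res <- standardizeMolecule("CCO", minHeavy = 1L)
  expect_identical(res$canonical, "CCO")
  expect_identical(res$reason, "")
  # bare metal ion is rejected as metal
  expect_identical(standardizeMolecule("[Fe+2]")$reason, "metal")
  # unparseable strings are rejections, not errors
  expect_identical(standardizeMolecule("C((")$reason, "unparseable")
  expect_identical(standardizeMolecule("")$reason, "unparseable")
})

test_that("dataset filtering deduplicates, bounds size and is idempotent", {
  df <- data.frame(
    source_id = paste0("s", 1:5),
    smiles = c("OCCCC", "CCCCO", "CCC", "c1ccccc1CCCC(N)=O", "CCCCO"),
    stringsAsFactors = FALSE)
  res <- filterDataset(df)
  # OCCCC and CCCCO share a canonical form, duplicated again; CCC is small
  expect_identical(res$rejected$reason[res$rejected$source_id == "s3"],
                   "too_small")
  canon <- res$retained$smiles
  expect_false(anyDuplicated(canon) > 0)
  expect_true(sum(res$rejected$reason == "duplicate") >= 1L)
  # idempotence: filtering the retained set changes nothing
  again <- filterDataset(res$retained)
  expect_identical(again$retained$smiles, res$retained$smiles)
  expect_identical(nrow(again$rejected), 0L)
  # vacuous case
  empty <- filterDataset(df[0, ])
  expect_identical(nrow(empty$retained), 0L)
})

test_that("vocabulary construction is content-determined and order-stable", {
  v <- buildVocabulary(list(c("C", "C", "O")))
  expect_identical(vocabTokens(v), c("GO", "EOS", "C", "O"))
  expect_identical(vocabSize(v), 4L)
  corpus <- smallCorpus()
  v1 <- buildVocabulary(corpus)
  v2 <- buildVocabulary(rev(corpus))
  expect_identical(vocabTokens(v1), vocabTokens(v2))
  expect_error(buildVocabulary(list()), "empty")
  # save/load keeps order
  f <- tempfile()
  writeVocabulary(v1, f)
  expect_identical(vocabTokens(readVocabulary(f)), vocabTokens(v1))
})

test_that("encode appends EOS, decode stops at EOS, round trip is identity", {
  v <- smallVocab()
  enc <- encodeSmiles("CCO", v)
  expect_identical(enc[length(enc)], eosIndex(v))
  expect_identical(decodeSmiles(enc, v), "CCO")
  expect_error(encodeSmiles("CBr", v), "'Br' not in vocabulary")
  # decode ignores a leading GO and everything after the first EOS
  expect_identical(decodeSmiles(c(goIndex(v), enc, enc), v), "CCO")
  # round trip over a thousand fixture molecules
  corpus <- makeToyCorpus(1000, seed = 19)
  vb <- buildVocabulary(corpus)
  for (s in corpus)
    expect_identical(decodeSmiles(encodeSmiles(s, vb), vb), s)
})
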