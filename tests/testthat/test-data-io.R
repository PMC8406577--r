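test_that("association edge lists load with first-appearance order and set semantics", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "d1\tm1", "d1 m2", "d2\tm2", "d1\tm1"), f)
  am <- loadAssociations(f)
  expect_identical(diseaseIds(am), c("d1", "d2"))
  expect_identical(mirnaIds(am), c("m1", "m2"))
  expect_equal(assocMatrix(am),
               matrix(c(1, 0, 1, 1), 2, dimnames = list(c("d1", "d2"),
                                                        c("m1", "m2"))))
  # duplicates collapse: still exactly 3 ones
  expect_equal(sum(assocMatrix(am)), 3)

  lex <- loadAssociations(f, idOrder = "lexicographic")
  expect_identical(diseaseIds(lex), sort(diseaseIds(am)))

  f1 <- withr::local_tempfile(lines = "d1 m1")
  expect_equal(assocMatrix(loadAssociations(f1)),
               matrix(1, 1, 1, dimnames = list("d1", "m1")))
})

test_that("association loader rejects empty and malformed input", {
  f <- withr::local_tempfile(lines = "# only a comment")
  expect_error(loadAssociations(f), "no associations")
  f2 <- withr::local_tempfile(lines = c("d1\tm1", "orphan"))
  expect_error(loadAssociations(f2), "line 2")
  expect_error(loadAssociations(file.path(tempdir(), "nope.tsv")), "exist")
})

test_that("association write/load round-trips and zero counts are exact", {
  for (seed in 1:3) {
    am <- randomBinaryAssoc(7, 9, density = 0.3, seed = seed)
    f <- withr::local_tempfile()
    writeAssociations(am, f)
    back <- loadAssociations(f)
    expect_identical(diseaseIds(back),
                     diseaseIds(am)[rowSums(assocMatrix(am)) > 0])
    kept <- assocMatrix(am)[rowSums(assocMatrix(am)) > 0,
                            colSums(assocMatrix(am)) > 0, drop = FALSE]
    # column order after reload is first-appearance order; realign by label
    expect_setequal(colnames(assocMatrix(back)), colnames(kept))
    expect_equal(assocMatrix(back),
                 kept[rownames(assocMatrix(back)),
                      colnames(assocMatrix(back)), drop = FALSE])
    rep <- sparsityReport(am)
    expect_equal(rep$nKnown + rep$nZeros, 7 * 9)
    expect_equal(rep$nKnown, sum(assocMatrix(am)))
  }
})

test_that("similarity matrices load with symmetrisation and mask sidecars", {
  sim <- SimilarityMatrix(matrix(c(1, 0, 0, 1), 2,
                                 dimnames = list(c("m1", "m2"),
                                                 c("m1", "m2"))))
  f <- withr::local_tempfile()
  writeSimilarityMatrix(sim, f)
  back <- loadSimilarityMatrix(f)
  expect_equal(simValues(back), simValues(sim))
  expect_equal(availableMask(back),
               matrix(c(TRUE, FALSE, FALSE, TRUE), 2,
                      dimnames = list(c("m1", "m2"), c("m1", "m2"))))

  # symmetric off-diagonal passes through untouched
  f2 <- withr::local_tempfile(
    lines = c("\tm1\tm2", "m1\t1\t0.4", "m2\t0.4\t1"))
  expect_equal(simValues(loadSimilarityMatrix(f2))["m1", "m2"], 0.4)

  # asymmetric input is averaged with a warning
  f3 <- withr::local_tempfile(
    lines = c("\tm1\tm2", "m1\t1\t0.4", "m2\t0.5\t1"))
  expect_warning(s3 <- loadSimilarityMatrix(f3), "symmetrised")
  expect_equal(simValues(s3)["m1", "m2"], 0.45)
  expect_equal(simValues(s3)["m2", "m1"], 0.45)

  # explicit mask sidecar overrides the positivity default
  fm <- withr::local_tempfile(
    lines = c("\tm1\tm2", "m1\t1\t1", "m2\t1\t0"))
  s4 <- loadSimilarityMatrix(f2, maskPath = fm)
  expect_identical(unname(availableMask(s4)),
                   matrix(c(TRUE, TRUE, TRUE, FALSE), 2))
})

test_that("similarity loader rejects non-square and non-numeric bodies", {
  f <- withr::local_tempfile(lines = c("\tm1\tm2", "m1\t1\t0"))
  expect_error(loadSimilarityMatrix(f), "square")
  f2 <- withr::local_tempfile(
    lines = c("\tm1\tm2", "m1\t1\tabc", "m2\t0.2\t1"))
  expect_error(loadSimilarityMatrix(f2), "m1.*m2|non-numeric")
})

test_that("DAG edge lists load, detect cycles and self-edges", {
  f <- withr::local_tempfile(lines = c("A\tB", "A\tC"))
  dag <- loadDiseaseDAG(f)
  expect_setequal(dagNodes(dag), c("A", "B", "C"))
  expect_equal(nrow(dagEdges(dag)), 2)
  expect_identical(dagRoots(dag), "A")

  f2 <- withr::local_tempfile(lines = c("A\tB", "B\tA"))
  expect_error(loadDiseaseDAG(f2), "cycle")
  f3 <- withr::local_tempfile(lines = "A\tA")
  expect_error(loadDiseaseDAG(f3), "self-edge")
  f4 <- withr::local_tempfile(lines = character())
  empty <- loadDiseaseDAG(f4)
  expect_length(dagNodes(empty), 0)
})

test_that("cycle detection agrees with a transitive-closure oracle", {
  set.seed(42)
  for (trial in 1:40) {
    n <- sample(3:8, 1)
    labs <- LETTERS[seq_len(n)]
    nE <- sample(2:(n + 3), 1)
    E <- cbind(sample(labs, nE, replace = TRUE),
               sample(labs, nE, replace = TRUE))
    E <- E[E[, 1] != E[, 2], , drop = FALSE] # self-edges tested separately
    if (nrow(E) == 0) next
    cyclic <- oracleHasCycle(labs, E)
    if (cyclic) expect_error(DiseaseDAG(E, labs), "cycle")
    else expect_s4_class(DiseaseDAG(E, labs), "DiseaseDAG")
  }
})

test_that("score files round-trip at 1e-9 with deterministic tie order", {
  set.seed(9)
  S <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("d", 1:3), paste0("m", 1:4)))
  S[2, 2] <- S[2, 3] # force a tie
  sm <- ScoreMatrix(S)
  am <- randomBinaryAssoc(3, 4, seed = 2)
  am <- AssociationMatrix(assocMatrix(am), paste0("d", 1:3), paste0("m", 1:4))
  f <- withr::local_tempfile()
  writeScores(sm, f, assoc = am)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_named(tab, c("disease", "mirna", "score", "known"))
  # per-disease descending scores, ties broken by miRNA label
  d2 <- tab[tab$disease == "d2", ]
  expect_true(all(diff(d2$score) <= 0))
  tied <- d2$mirna[d2$score == max(S[2, 2])]
  expect_identical(tied, sort(tied))
  back <- readScores(f)
  expect_equal(scoreValues(back)[rownames(S), colnames(S)], S,
               tolerance = 1e-9)
  expect_equal(attr(back, "known")[rownames(S), colnames(S)],
               assocMatrix(am), tolerance = 0)

  one <- ScoreMatrix(matrix(0.5, 1, 1, dimnames = list("d1", "m1")))
  f2 <- withr::local_tempfile()
  writeScores(one, f2)
  expect_length(readLines(f2), 2) # header + one data line
})

test_that("sparsity report prints all counts", {
  am <- randomBinaryAssoc(5, 6, seed = 1)
  out <- capture.output(print(sparsityReport(am)))
  expect_match(paste(out, collapse = " "), as.character(sum(assocMatrix(am))))
  expect_match(paste(out, collapse = " "),
               as.character(sum(assocMatrix(am) == 0)))
})
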