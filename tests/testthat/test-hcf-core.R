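test_that("SVD denoising reconstructs exactly at full rank and on rank-1 input", {
  am <- randomBinaryAssoc(6, 5, seed = 4)
  cfg <- HCFConfig(svdRank = 5L)
  expect_equal(svdDenoise(am, cfg), assocMatrix(am), tolerance = 1e-10)

  u <- c(1, 0, 1, 1); v <- c(1, 1, 0)
  r1 <- AssociationMatrix(outer(u, v))
  expect_equal(svdDenoise(r1, HCFConfig(svdRank = 1L)), assocMatrix(r1),
               tolerance = 1e-10)

  expect_error(svdDenoise(am, HCFConfig(svdRank = 6L)), "rank")
})

test_that("truncated SVD beats random same-rank competitors in Frobenius error", {
  am <- randomBinaryAssoc(6, 5, density = 0.4, seed = 11)
  X <- assocMatrix(am)
  k <- 2L
  Xk <- svdDenoise(am, HCFConfig(svdRank = k))
  errSvd <- sqrt(sum((X - Xk)^2))
  set.seed(100)
  for (trial in 1:100) {
    M <- matrix(rnorm(6 * k), 6) %*% matrix(rnorm(k * 5), k)
    expect_lte(errSvd, sqrt(sum((X - M)^2)))
  }
})

test_that("energy-fraction rank selection keeps the smallest sufficient rank", {
  X <- diag(c(4, 2, 1)) # singular values 4, 2, 1; energies 16/21, 20/21, 1
  am <- AssociationMatrix((X > 0) * 1)
  d <- svd(assocMatrix(am))$d
  expect_equal(d, c(1, 1, 1))
  # a graded matrix via scores: use .svdDenoiseMatrix through svdDenoise on
  # a matrix with distinct spectrum
  Y <- outer(c(2, 1), c(2, 1)) + diag(0.1, 2)
  dec <- svd(Y)
  frac <- dec$d[1]^2 / sum(dec$d^2)
  got <- mdacf:::.svdDenoiseMatrix(Y, frac) # rank 1 suffices exactly
  want <- dec$u[, 1, drop = FALSE] %*% t(dec$v[, 1, drop = FALSE]) * dec$d[1]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("top-N neighbour selection ranks by similarity with index tie-breaks", {
  S <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.5, 0.2, 0.5, 1), 3)
  sim <- SimilarityMatrix(S, c("a", "b", "c"), matrix(TRUE, 3, 3))
  nb <- topNeighbors(sim, 1, 1)
  expect_equal(nb$index, 2)
  expect_equal(nb$sim, 0.9)
  expect_false(nb$shortfall)

  # tie: equal similarity at indices 2 and 4 -> index 2 wins
  S5 <- diag(5)
  S5[2, 1] <- S5[1, 2] <- 0.5
  S5[4, 1] <- S5[1, 4] <- 0.5
  sim5 <- SimilarityMatrix(S5, letters[1:5], matrix(TRUE, 5, 5))
  expect_equal(topNeighbors(sim5, 1, 1)$index, 2)

  big <- topNeighbors(sim, 1, 10)
  expect_true(big$shortfall)
  expect_equal(big$index, c(2, 3))

  expect_error(topNeighbors(sim, 9, 1), "out of range")
  # exclusion removes candidates
  expect_equal(topNeighbors(sim, 1, 1, exclude = 2)$index, 3)
})

test_that("the three pool scores match their defining averages", {
  # 3 diseases, 1 test miRNA: neighbours of d1 are d2 (0.8) and d3 (0.4)
  ID <- SimilarityMatrix(matrix(c(1, 0.8, 0.4, 0.8, 1, 0.1, 0.4, 0.1, 1), 3),
                         paste0("d", 1:3), matrix(TRUE, 3, 3))
  Xt <- matrix(c(0, 1, 0), 3, 1)
  cfg <- HCFConfig(nNeighbors = 2, svdEnabled = FALSE)
  expect_equal(sdaScore(Xt, ID, 1, 1, cfg), (0.8 * 1 + 0.4 * 0) / 2)

  # mirror on the miRNA side: neighbours (0.6, 1) and (0.2, 1)
  IM <- SimilarityMatrix(matrix(c(1, 0.6, 0.2, 0.6, 1, 0.1, 0.2, 0.1, 1), 3),
                         paste0("m", 1:3), matrix(TRUE, 3, 3))
  Xrow <- matrix(c(0, 1, 1), 1, 3)
  expect_equal(smaScore(Xrow, IM, 1, 1, cfg), (0.6 + 0.2) / 2)

  # transposition symmetry: sma on t(X) with roles swapped equals sda
  expect_equal(smaScore(t(Xt), ID, 1, 1, cfg), sdaScore(Xt, ID, 1, 1, cfg))

  # empty neighbourhood gives 0
  lonely <- SimilarityMatrix(matrix(1, 1, 1), "d1", matrix(TRUE, 1, 1))
  expect_equal(sdaScore(matrix(1, 1, 1), lonely, 1, 1, cfg), 0)
})

test_that("pair similarity is the harmonic-style combination with NA for nonpositive input", {
  expect_equal(pairSimilarity(1, 1), 1 / sqrt(2))
  for (s in c(0.2, 0.7, 1.3))
    expect_equal(pairSimilarity(s, s), s / sqrt(2))
  expect_equal(pairSimilarity(0.8, 0.6), 0.48)
  expect_equal(pairSimilarity(0.3, 0.9), pairSimilarity(0.9, 0.3))
  expect_lt(pairSimilarity(1e-8, 1), 1e-7) # vanishes with either argument
  expect_true(is.na(pairSimilarity(0, 1)))
  expect_true(is.na(pairSimilarity(0.5, -0.2)))
})

test_that("pair-pool scoring selects top-K pairs and divides by K", {
  # 2x2 toy, N = 1, K = 1: single candidate (s_d = 0.8, s_m = 0.6, X = 1)
  ID <- SimilarityMatrix(matrix(c(1, 0.8, 0.8, 1), 2), c("d1", "d2"),
                         matrix(TRUE, 2, 2))
  IM <- SimilarityMatrix(matrix(c(1, 0.6, 0.6, 1), 2), c("m1", "m2"),
                         matrix(TRUE, 2, 2))
  Xt <- matrix(c(0, 0, 0, 1), 2, 2)
  cfg <- HCFConfig(nNeighbors = 1, kPairs = 1, svdEnabled = FALSE)
  expect_equal(sdmaScore(Xt, ID, IM, 1, 1, cfg), 0.48)

  # all candidate evidence zero -> 0
  expect_equal(sdmaScore(matrix(0, 2, 2), ID, IM, 1, 1, cfg), 0)

  # K identical pairs with s_d = s_m = 1 and X = 1 -> 1/sqrt(2)
  n <- 4
  ones <- SimilarityMatrix(matrix(1, n, n), paste0("d", 1:n),
                           matrix(TRUE, n, n))
  onesM <- SimilarityMatrix(matrix(1, n, n), paste0("m", 1:n),
                            matrix(TRUE, n, n))
  cfg2 <- HCFConfig(nNeighbors = 3, kPairs = 9, svdEnabled = FALSE)
  expect_equal(sdmaScore(matrix(1, n, n), ones, onesM, 1, 1, cfg2),
               1 / sqrt(2))

  # nonpositive similarities are excluded from candidacy
  IDneg <- SimilarityMatrix(matrix(c(1, -0.5, -0.5, 1), 2), c("d1", "d2"),
                            matrix(TRUE, 2, 2))
  expect_equal(sdmaScore(matrix(1, 2, 2), IDneg, IM, 1, 1, cfg), 0)
})

test_that("fusion weights are convex and degenerate correctly", {
  # beta = 1: pure pair-pool score whatever the others are
  expect_equal(fuseScores(99, -5, 3, HCFConfig(alpha = 0.7, beta = 1)), 3)
  # alpha = 1, beta = 0: pure disease-pool score
  expect_equal(fuseScores(2, 7, 9, HCFConfig(alpha = 1, beta = 0)), 2)
  # equal inputs pass through any weights (the weights sum to 1)
  for (a in seq(0, 1, 0.25)) for (b in seq(0, 1, 0.25)) {
    expect_equal(fuseScores(1, 1, 1, HCFConfig(alpha = a, beta = b)), 1)
    expect_equal(a * (1 - b) + (1 - a) * (1 - b) + b, 1)
  }
  # linearity in each pool
  cfg <- HCFConfig(alpha = 0.3, beta = 0.1)
  expect_equal(fuseScores(2, 0, 0, cfg), 2 * 0.3 * 0.9)
  expect_equal(fuseScores(0, 2, 0, cfg), 2 * 0.7 * 0.9)
  expect_equal(fuseScores(0, 0, 2, cfg), 2 * 0.1)
})

test_that("vectorised prediction equals the naive per-entry oracle", {
  for (seed in 1:4) {
    am <- randomBinaryAssoc(6, 7, density = 0.35, seed = seed)
    ID <- randomSimilarity(diseaseIds(am), seed = seed + 50)
    IM <- randomSimilarity(mirnaIds(am), seed = seed + 90)
    for (cfg in list(HCFConfig(nNeighbors = 3, kPairs = 4, svdEnabled = FALSE),
                     HCFConfig(alpha = 0.6, beta = 0.4, nNeighbors = 2,
                               kPairs = 2, svdRank = 3L))) {
      got <- scoreValues(predictAll(am, ID, IM, cfg))
      want <- oraclePredict(am, ID, IM, cfg)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("beta = 1 prediction reproduces the per-entry pair-pool matrix", {
  am <- randomBinaryAssoc(5, 6, seed = 8)
  ID <- randomSimilarity(diseaseIds(am), seed = 1)
  IM <- randomSimilarity(mirnaIds(am), seed = 2)
  cfg <- HCFConfig(beta = 1, nNeighbors = 3, kPairs = 4, svdEnabled = FALSE)
  got <- scoreValues(predictAll(am, ID, IM, cfg))
  X <- assocMatrix(am)
  for (i in 1:5) for (j in 1:6)
    expect_identical(got[i, j], sdmaScore(X, ID, IM, i, j, cfg))
})

test_that("all-zero evidence yields all-zero scores", {
  am <- AssociationMatrix(matrix(0, 4, 5))
  ID <- randomSimilarity(diseaseIds(am), seed = 3)
  IM <- randomSimilarity(mirnaIds(am), seed = 4)
  sc <- predictAll(am, ID, IM, HCFConfig(nNeighbors = 2, kPairs = 3))
  expect_true(all(scoreValues(sc) == 0))
})

test_that("adding a known association never decreases any score", {
  am <- randomBinaryAssoc(6, 7, density = 0.3, seed = 21)
  ID <- randomSimilarity(diseaseIds(am), seed = 5) # nonnegative similarities
  IM <- randomSimilarity(mirnaIds(am), seed = 6)
  cfg <- HCFConfig(nNeighbors = 3, kPairs = 4, svdEnabled = FALSE)
  before <- scoreValues(predictAll(am, ID, IM, cfg))
  zeros <- which(assocMatrix(am) == 0, arr.ind = TRUE)
  set.seed(7)
  for (r in sample(nrow(zeros), 5)) {
    X2 <- assocMatrix(am)
    X2[zeros[r, 1], zeros[r, 2]] <- 1
    am2 <- AssociationMatrix(X2, diseaseIds(am), mirnaIds(am))
    after <- scoreValues(predictAll(am2, ID, IM, cfg))
    expect_true(all(after - before >= -1e-12))
  }
})

test_that("prediction rejects mismatched identifier lists", {
  am <- randomBinaryAssoc(4, 4, seed = 1)
  ID <- randomSimilarity(paste0("x", 1:4), seed = 1)
  IM <- randomSimilarity(mirnaIds(am), seed = 2)
  expect_error(predictAll(am, ID, IM, HCFConfig()), "id mismatch")
})

test_that("configuration validity rejects out-of-range parameters", {
  expect_error(HCFConfig(alpha = 1.5), "alpha")
  expect_error(HCFConfig(beta = -0.1), "beta")
  expect_error(HCFConfig(nNeighbors = 0), "nNeighbors")
  expect_error(HCFConfig(rho = 1), "rho")
  expect_error(HCFConfig(deltaPrimeD = 0), "deltaPrimeD")
})
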