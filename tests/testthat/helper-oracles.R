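# Independent reference implementations and fixture builders.  All oracles
# are deliberately naive (explicit loops, exhaustive enumeration) and avoid
# the package's optimized code paths.

# ---- fixtures -------------------------------------------------------------

randomBinaryAssoc <- function(nd, nm, density = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(as.numeric(runif(nd * nm) < density), nd, nm)
  if (sum(X) == 0) X[1, 1] <- 1
  AssociationMatrix(X, sprintf("d%d", seq_len(nd)), sprintf("m%d", seq_len(nm)))
}

# symmetric similarity with unit diagonal, available everywhere
randomSimilarity <- function(ids, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  S <- matrix(runif(n * n), n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  SimilarityMatrix(S, ids, matrix(TRUE, n, n))
}

# random DAG over <= n nodes: edges only from earlier to later labels
randomDag <- function(n, pEdge = 0.35, seed = 1) {
  set.seed(seed)
  labs <- LETTERS[seq_len(n)]
  E <- NULL
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    if (runif(1) < pEdge) E <- rbind(E, c(labs[a], labs[b]))
  if (is.null(E)) E <- matrix(character(), ncol = 2)
  DiseaseDAG(E, labs)
}

smallSyntheticSet <- function(nd = 12, nm = 15, seed = 3, density = 0.2) {
  spec <- SyntheticSpec(nd, nm, density = density, latentRank = 2L,
                        noiseFlipProb = 0, seed = seed)
  gen <- makeAssociations(spec)
  list(spec = spec, gen = gen,
       dag = makeDag(spec, gen$diseaseClusters, excludeFrac = 0.2),
       fm = makeFunctionalSim(spec, gen$mirnaFactors, maskFrac = 0.2))
}

# ---- graph oracles --------------------------------------------------------

# cycle detection by boolean transitive closure: cyclic iff a node reaches
# itself
oracleHasCycle <- function(nodes, edges) {
  n <- length(nodes)
  R <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) R[edges] <- TRUE
  for (k in seq_len(n))
    R <- R | (R %*% R > 0)
  any(diag(R))
}

# semantic contributions by exhaustive upward-path enumeration:
# rho^(min number of edges on any path from ancestor down to the disease)
oracleSemanticContributions <- function(dag, disease, rho = 0.5) {
  E <- dagEdges(dag)
  parentsOf <- function(v) if (nrow(E)) E[E[, 2] == v, 1] else character()
  best <- numeric(0)
  walk <- function(v, len) {
    if (!(v %in% names(best)) || best[[v]] > len)
      best[v] <<- len
    for (p in parentsOf(v)) walk(p, len + 1)
  }
  walk(disease, 0)
  rho^best
}

# ---- predictor oracle -----------------------------------------------------

# neighbour selection from first principles: similarity descending, ties by
# ascending index, self excluded
oracleTopN <- function(S, avail, i, n) {
  cand <- setdiff(which(avail[, i]), i)
  ord <- order(-S[cand, i], cand)
  idx <- cand[ord][seq_len(min(n, length(cand)))]
  list(index = idx, sim = S[idx, i])
}

# naive per-entry triple-loop scorer implementing the three pools + fusion
oraclePredict <- function(assoc, ID, IM, config) {
  X <- assocMatrix(assoc)
  Xt <- if (config@svdEnabled) svdDenoise(assoc, config) else X
  Sd <- simValues(ID); Ad <- availableMask(ID)
  Sm <- simValues(IM); Am <- availableMask(IM)
  N <- config@nNeighbors; K <- config@kPairs
  out <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  a <- config@alpha; b <- config@beta
  for (i in seq_len(nrow(X))) {
    nbD <- oracleTopN(Sd, Ad, i, N)
    for (j in seq_len(ncol(X))) {
      nbM <- oracleTopN(Sm, Am, j, N)
      sda <- sum(nbD$sim * Xt[nbD$index, j]) / N
      sma <- sum(nbM$sim * Xt[i, nbM$index]) / N
      # pair pool: cross product, nonpositive similarities dropped
      pool <- NULL
      for (ui in seq_along(nbD$index)) for (vi in seq_along(nbM$index)) {
        p <- pairSimilarity(nbD$sim[ui], nbM$sim[vi])
        if (!is.na(p))
          pool <- rbind(pool, c(nbD$index[ui], nbM$index[vi], p))
      }
      sdma <- 0
      if (!is.null(pool)) {
        ord <- order(-pool[, 3], pool[, 1], pool[, 2])
        sel <- pool[ord, , drop = FALSE][seq_len(min(K, nrow(pool))), ,
                                         drop = FALSE]
        sdma <- sum(sel[, 3] * Xt[sel[, 1:2, drop = FALSE]]) / K
      }
      out[i, j] <- sda * a * (1 - b) + sma * (1 - a) * (1 - b) + sdma * b
    }
  }
  out
}
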