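#' @include AllClasses.R AllGenerics.R similarity.R
NULL

#' Truncated-SVD denoising of the association matrix
#'
#' Replaces the binary association matrix by its rank-k truncated singular
#' value decomposition \eqn{\tilde X = U_k \Sigma_k V_k^T}, the best rank-k
#' approximation in Frobenius norm (Eckart-Young).  The reconstruction
#' smooths the sparse 0/1 evidence before it is consumed by the three
#' neighbourhood scorers.  When `svdRank` is a fraction f in (0, 1), k is
#' the smallest rank whose squared singular values retain at least f of the
#' total spectrum energy.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param config an [HCFConfig-class] with `svdEnabled = TRUE`.
#' @return Dense numeric matrix of the same shape as the association matrix.
#' @export
svdDenoise <- function(assoc, config = HCFConfig()) {
  stopifnot(config@svdEnabled)
  X <- assocMatrix(assoc)
  .svdDenoiseMatrix(X, config@svdRank)
}

.svdDenoiseMatrix <- function(X, svdRank) {
  r <- min(dim(X))
  dec <- svd(X)
  if (svdRank < 1) {
    energy <- cumsum(dec$d^2) / sum(dec$d^2)
    k <- which(energy >= svdRank)[1L]
    if (is.na(k)) k <- r
  } else {
    k <- as.integer(svdRank)
    if (k > r) stop("svd rank ", k, " exceeds min(dim) = ", r)
  }
  Xt <- dec$u[, seq_len(k), drop = FALSE] %*%
    (dec$d[seq_len(k)] * t(dec$v[, seq_len(k), drop = FALSE]))
  dimnames(Xt) <- dimnames(X)
  Xt
}

#' Top-N most similar neighbours
#'
#' Ranks candidates by similarity to the query (self and `exclude` removed,
#' unavailable entries skipped), descending, ties broken by ascending index
#' for determinism.  When fewer than `n` candidates exist, all are returned
#' and `shortfall` is set.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param index query index (1-based).
#' @param n neighbourhood size, >= 1.
#' @param exclude integer indices never to return.
#' @return `list(index = , sim = , shortfall = )`.
#' @export
topNeighbors <- function(sim, index, n, exclude = integer()) {
  S <- simValues(sim)
  if (index < 1L || index > nrow(S)) stop("index out of range: ", index)
  stopifnot(n >= 1L)
  cand <- setdiff(which(availableMask(sim)[, index]), c(index, exclude))
  vals <- unname(S[cand, index])
  ord <- order(-vals, cand)
  take <- utils::head(ord, n)
  list(index = cand[take], sim = vals[take], shortfall = length(cand) < n)
}

# top-N neighbour indices + similarities for every column of sim, excluding
# self; vectorised version of topNeighbors used by the hot paths.
.allNeighborhoods <- function(sim, n) {
  S <- simValues(sim)
  p <- nrow(S)
  lapply(seq_len(p), function(i) {
    cand <- setdiff(which(availableMask(sim)[, i]), i)
    vals <- unname(S[cand, i])
    take <- utils::head(order(-vals, cand), n)
    list(index = cand[take], sim = vals[take])
  })
}

#' Similar-disease association score
#'
#' Mean, over the top-N diseases most similar to \eqn{d_i}, of similarity
#' times association evidence with the test miRNA:
#' \eqn{\hat x_{ij} = \frac{1}{N}\sum_{d_u \in T_d(d_i)} s_d(d_i, d_u)
#' \tilde X_{uj}}.  The divisor is N even when fewer neighbours exist.
#'
#' @param Xt association evidence matrix (binary or SVD-denoised).
#' @param ID integrated disease [SimilarityMatrix-class].
#' @param i,j disease and miRNA indices.
#' @param config an [HCFConfig-class] (uses `nNeighbors`).
#' @return Scalar score (0 for an empty neighbourhood).
#' @export
sdaScore <- function(Xt, ID, i, j, config = HCFConfig()) {
  nb <- topNeighbors(ID, i, config@nNeighbors)
  if (length(nb$index) == 0L) return(0)
  sum(nb$sim * Xt[nb$index, j]) / config@nNeighbors
}

#' Similar-miRNA association score
#'
#' Mirror of [sdaScore()] over the top-N miRNAs most similar to \eqn{m_j}:
#' \eqn{\hat x_{ij} = \frac{1}{N}\sum_{m_v \in T_m(m_j)} s_m(m_j, m_v)
#' \tilde X_{iv}}.
#'
#' @inheritParams sdaScore
#' @param IM integrated miRNA [SimilarityMatrix-class].
#' @export
smaScore <- function(Xt, IM, i, j, config = HCFConfig()) {
  nb <- topNeighbors(IM, j, config@nNeighbors)
  if (length(nb$index) == 0L) return(0)
  sum(nb$sim * Xt[i, nb$index]) / config@nNeighbors
}

#' Similarity between two disease-miRNA pairs
#'
#' Harmonic-style combination of the disease-side and miRNA-side
#' similarities: \eqn{s_{d,m} = 1 / \sqrt{(1/s_d)^2 + (1/s_m)^2}}.  It is
#' symmetric in its arguments and bounded by \eqn{\min(s_d, s_m)/\sqrt 2}
#' when the two are equal.  Nonpositive inputs (possible after z-scoring)
#' make the expression meaningless, so such pairs are excluded from
#' candidacy: `NA` is returned as the "undefined" sentinel.
#'
#' @param sd_,sm_ disease-side and miRNA-side similarity values.
#' @return Scalar, or `NA_real_` when either input is nonpositive.
#' @examples
#' pairSimilarity(1, 1) # 1 / sqrt(2)
#' @export
pairSimilarity <- function(sd_, sm_) {
  if (sd_ <= 0 || sm_ <= 0) return(NA_real_)
  1 / sqrt(1 / sd_^2 + 1 / sm_^2)
}

# SDMA score for one cell given its disease/miRNA neighbourhoods.
# du/sd_: top-N disease neighbour indices and similarities (self excluded);
# mv/sm_: same for miRNAs.  Pool = cross product, pairs with nonpositive
# similarity dropped, top-K by pair similarity (ties by ascending (u, v)).
.sdmaCell <- function(Xt, du, sd_, mv, sm_, K) {
  okU <- sd_ > 0; okV <- sm_ > 0
  if (!any(okU) || !any(okV)) return(0)
  du <- du[okU]; sd_ <- sd_[okU]
  mv <- mv[okV]; sm_ <- sm_[okV]
  P <- 1 / sqrt(outer(1 / sd_^2, 1 / sm_^2, "+"))
  u <- rep(du, times = length(mv))
  v <- rep(mv, each = length(du))
  p <- as.vector(P)
  sel <- utils::head(order(-p, u, v), K)
  sum(p[sel] * Xt[cbind(u[sel], v[sel])]) / K
}

#' Similar disease-miRNA pair association score
#'
#' The "not-so-similar" evidence pool: candidates are every pair
#' \eqn{(d_u, m_v)} with \eqn{d_u} in the top-N disease neighbourhood of
#' \eqn{d_i} and \eqn{m_v} in the top-N miRNA neighbourhood of \eqn{m_j}
#' (so \eqn{u \neq i}, \eqn{v \neq j}).  Candidates are ranked by
#' [pairSimilarity()]; the top K contribute
#' \eqn{\hat x_{ij} = \frac{1}{K}\sum s_{d,m} \tilde X_{uv}}, with the
#' divisor K kept even under a candidate shortfall.
#'
#' @inheritParams sdaScore
#' @param IM integrated miRNA [SimilarityMatrix-class].
#' @export
sdmaScore <- function(Xt, ID, IM, i, j, config = HCFConfig()) {
  nbD <- topNeighbors(ID, i, config@nNeighbors)
  nbM <- topNeighbors(IM, j, config@nNeighbors)
  .sdmaCell(Xt, nbD$index, nbD$sim, nbM$index, nbM$sim, config@kPairs)
}

#' Fuse the three evidence scores
#'
#' \eqn{\hat x = \alpha(1-\beta)\,sda + (1-\alpha)(1-\beta)\,sma +
#' \beta\,sdma}.  The three weights sum to 1 for every
#' \eqn{\alpha, \beta \in [0,1]}; with \eqn{\beta = 1} the fused score is
#' the pair-pool score alone.
#'
#' @param sda,sma,sdma numeric scalars, vectors or matrices (recycled
#'   elementwise).
#' @param config an [HCFConfig-class] (uses `alpha`, `beta`).
#' @return Fused score(s), same shape as the inputs.
#' @export
fuseScores <- function(sda, sma, sdma, config = HCFConfig()) {
  a <- config@alpha; b <- config@beta
  sda * a * (1 - b) + sma * (1 - a) * (1 - b) + sdma * b
}

#' Predict scores for every disease-miRNA pair
#'
#' Orchestrates the full scorer: optional SVD denoising of the association
#' evidence, neighbourhoods precomputed once per disease and per miRNA,
#' the three pool scores per entry, and fusion.  Deterministic for fixed
#' inputs and configuration.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param ID,IM integrated [SimilarityMatrix-class] objects whose ids match
#'   the association matrix.
#' @param config an [HCFConfig-class].
#' @return A [ScoreMatrix-class].
#' @export
predictAll <- function(assoc, ID, IM, config = HCFConfig()) {
  if (!identical(simIds(ID), diseaseIds(assoc)) ||
      !identical(simIds(IM), mirnaIds(assoc)))
    stop("id mismatch between similarities and association matrix")
  X <- assocMatrix(assoc)
  Xt <- if (config@svdEnabled) .svdDenoiseMatrix(X, config@svdRank) else X
  S <- .scoreRows(Xt, ID, IM, seq_len(nrow(X)), config)
  ScoreMatrix(S, diseaseIds(assoc), mirnaIds(assoc))
}

# score a subset of disease rows (all columns); shared by predictAll and the
# cross-validation loop, which only needs the held-out disease's row.
.scoreRows <- function(Xt, ID, IM, rows, config,
                       nbM = .allNeighborhoods(IM, config@nNeighbors)) {
  N <- config@nNeighbors
  K <- config@kPairs
  nm <- ncol(Xt)
  out <- matrix(0, length(rows), nm,
                dimnames = list(rownames(Xt)[rows], colnames(Xt)))
  for (r in seq_along(rows)) {
    i <- rows[r]
    nbD <- topNeighbors(ID, i, N)
    sda <- if (length(nbD$index))
      as.numeric(crossprod(nbD$sim, Xt[nbD$index, , drop = FALSE])) / N
    else numeric(nm)
    sma <- vapply(seq_len(nm), function(j) {
      nb <- nbM[[j]]
      if (length(nb$index) == 0L) return(0)
      sum(nb$sim * Xt[i, nb$index]) / N
    }, 0)
    sdma <- vapply(seq_len(nm), function(j)
      .sdmaCell(Xt, nbD$index, nbD$sim, nbM[[j]]$index, nbM[[j]]$sim, K), 0)
    out[r, ] <- fuseScores(sda, sma, sdma, config)
  }
  out
}

#' End-to-end prediction from raw inputs
#'
#' Builds the integrated similarities from the association matrix, the
#' miRNA functional similarity and the disease DAG, then scores every pair.
#'
#' @inheritParams buildIntegratedSimilarities
#' @return A [ScoreMatrix-class].
#' @export
hcfPredict <- function(assoc, fm, dag, config = HCFConfig()) {
  sims <- buildIntegratedSimilarities(assoc, fm, dag, config)
  predictAll(assoc, sims$ID, sims$IM, config)
}
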