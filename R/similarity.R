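#' @include AllClasses.R AllGenerics.R
NULL

.dagGraph <- function(dag) {
  igraph::graph_from_data_frame(
    d = as.data.frame(dagEdges(dag), stringsAsFactors = FALSE),
    directed = TRUE, vertices = dagNodes(dag))
}

#' Semantic contributions of a disease's ancestors
#'
#' In the MeSH-style hierarchy a disease is described by its ancestor
#' closure \eqn{V(d)}: the disease itself plus every term that can reach it
#' along parent-to-child edges.  The contribution of the disease to itself
#' is 1, and each ancestor contributes \eqn{\rho} times the largest
#' contribution among its children within \eqn{V(d)} -- equivalently
#' \eqn{\rho^{\ell}} where \eqn{\ell} is the shortest downward distance from
#' the ancestor to the disease.
#'
#' @param dag a [DiseaseDAG-class].
#' @param disease a node label.
#' @param rho decay factor in (0, 1); default 0.5.
#' @return Named numeric vector over \eqn{V(d)}.
#' @examples
#' dag <- DiseaseDAG(rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
#' semanticContributions(dag, "D") # D = 1, B = C = 0.5, A = 0.25
#' @export
semanticContributions <- function(dag, disease, rho = 0.5) {
  if (!disease %in% dagNodes(dag))
    stop("unknown disease: ", disease)
  stopifnot(rho > 0, rho < 1)
  g <- .dagGraph(dag)
  anc <- names(igraph::subcomponent(g, disease, mode = "in"))
  d <- igraph::distances(g, v = anc, to = disease, mode = "out")[, 1L]
  out <- rho^d
  names(out) <- anc
  out
}

#' Disease semantic value
#'
#' Sum of the semantic contributions over the ancestor closure; at least 1
#' (the disease's own contribution).
#'
#' @inheritParams semanticContributions
#' @return Scalar DSV.
#' @export
semanticValue <- function(dag, disease, rho = 0.5) {
  sum(semanticContributions(dag, disease, rho))
}

#' Disease semantic similarity matrix
#'
#' Similarity of a disease pair is the summed contribution of their shared
#' ancestors, from both sides, normalised by the two semantic values:
#' \deqn{SD(d_k, d_l) = \frac{\sum_{t \in V(d_k) \cap V(d_l)}
#'   (D_{d_k}(t) + D_{d_l}(t))}{DSV(d_k) + DSV(d_l)}.}
#' Diseases absent from the DAG get fully unavailable rows/columns (the
#' Gaussian kernel takes over at integration); pairs with empty ancestor
#' overlap get value 0 and are marked unavailable, encoding the positivity
#' gate.
#'
#' @param dag a [DiseaseDAG-class].
#' @param diseases character vector of disease labels (need not all be DAG
#'   nodes).
#' @param rho decay factor in (0, 1).
#' @return A [SimilarityMatrix-class] over `diseases`.
#' @export
semanticSimilarity <- function(dag, diseases, rho = 0.5) {
  n <- length(diseases)
  present <- diseases %in% dagNodes(dag)
  contrib <- vector("list", n)
  contrib[present] <- lapply(diseases[present], function(d)
    semanticContributions(dag, d, rho))
  dsv <- vapply(contrib, function(x) if (is.null(x)) NA_real_ else sum(x), 0)
  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  avail <- matrix(FALSE, n, n, dimnames = list(diseases, diseases))
  for (k in seq_len(n)) {
    if (!present[k]) next
    for (l in k:n) {
      if (!present[l]) next
      shared <- intersect(names(contrib[[k]]), names(contrib[[l]]))
      val <- if (length(shared))
        sum(contrib[[k]][shared] + contrib[[l]][shared]) / (dsv[k] + dsv[l])
      else 0
      S[k, l] <- S[l, k] <- val
      avail[k, l] <- avail[l, k] <- val > 0
    }
  }
  SimilarityMatrix(S, diseases, avail)
}

#' Gaussian interaction-profile kernel bandwidth
#'
#' The effective bandwidth divides a raw bandwidth by the mean squared
#' Euclidean norm of the interaction profiles, so that the kernel scale
#' adapts to how densely connected the network is.  When every profile is
#' all-zero the mean norm is 0; the raw bandwidth is returned unchanged with
#' a warning.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @param deltaPrime raw bandwidth > 0.
#' @return Effective bandwidth \eqn{\delta = \delta' / \overline{\|BV\|^2}}.
#' @examples
#' gaussianBandwidth(rbind(c(1, 1), c(1, 1)), 1) # 1 / 2
#' @export
gaussianBandwidth <- function(profiles, deltaPrime = 1) {
  stopifnot(deltaPrime > 0, nrow(profiles) >= 1L)
  meanSq <- mean(rowSums(profiles^2))
  if (meanSq == 0) {
    warning("all interaction profiles are zero; using raw bandwidth")
    return(deltaPrime)
  }
  deltaPrime / meanSq
}

#' Gaussian interaction-profile kernel
#'
#' \eqn{K(i, j) = \exp(-\delta \|BV_i - BV_j\|^2)}: symmetric, unit
#' diagonal, entries in (0, 1], defined for every pair (no availability
#' gaps) -- this totality is what makes it the fallback similarity.
#'
#' @param profiles numeric matrix, one profile per row.
#' @param delta effective bandwidth > 0 (see [gaussianBandwidth()]).
#' @param ids labels; default rownames.
#' @return A [SimilarityMatrix-class], available everywhere.
#' @export
gaussianKernel <- function(profiles, delta, ids = rownames(profiles)) {
  stopifnot(delta > 0)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(profiles)))
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0 # numerical noise
  K <- exp(-delta * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  SimilarityMatrix(K, ids, matrix(TRUE, nrow(K), ncol(K)))
}

.gipDisease <- function(X, deltaPrime)
  gaussianKernel(X, gaussianBandwidth(X, deltaPrime), rownames(X))

.gipMirna <- function(X, deltaPrime)
  gaussianKernel(t(X), gaussianBandwidth(t(X), deltaPrime), colnames(X))

#' Gaussian kernel similarity for diseases
#'
#' Convenience wrapper: profiles are the rows of the association matrix.
#' @param assoc an [AssociationMatrix-class].
#' @param deltaPrime raw bandwidth (default 1).
#' @return A [SimilarityMatrix-class] over the diseases.
#' @export
diseaseKernel <- function(assoc, deltaPrime = 1)
  .gipDisease(assocMatrix(assoc), deltaPrime)

#' Gaussian kernel similarity for miRNAs
#'
#' Profiles are the columns of the association matrix.
#' @inheritParams diseaseKernel
#' @return A [SimilarityMatrix-class] over the miRNAs.
#' @export
mirnaKernel <- function(assoc, deltaPrime = 1)
  .gipMirna(assocMatrix(assoc), deltaPrime)

#' Z-score normalisation of a similarity matrix
#'
#' Before integration each similarity matrix is centred and scaled: subtract
#' the mean of its available entries and divide by their standard deviation
#' (population convention, divisor = count).  Unavailable entries are left
#' untouched and the availability mask is preserved, so the positivity gate
#' still refers to the raw measure.
#'
#' @param sim a [SimilarityMatrix-class] with at least two available entries
#'   of nonzero spread.
#' @return A [SimilarityMatrix-class] whose available entries have mean 0
#'   and population standard deviation 1.
#' @export
zscoreNormalize <- function(sim) {
  S <- simValues(sim)
  A <- availableMask(sim)
  v <- S[A]
  if (length(v) < 2L) stop("need at least 2 available entries to normalize")
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (sdev == 0) stop("constant similarity matrix")
  S[A] <- (S[A] - mu) / sdev
  SimilarityMatrix(S, simIds(sim), A)
}

#' Integrate a primary similarity with a total fallback
#'
#' Where the primary measure (semantic or functional similarity) is defined
#' and strictly positive, use it; everywhere else fall back to the Gaussian
#' kernel.  Both inputs are expected on a common z-score scale
#' ([zscoreNormalize()] first, then integrate), and the gate is the
#' *raw* availability carried in the primary's mask.
#'
#' @param primary,fallback [SimilarityMatrix-class] objects over the same
#'   identifier list.
#' @return A [SimilarityMatrix-class], available wherever the fallback is.
#' @export
integrateSimilarity <- function(primary, fallback) {
  if (!identical(simIds(primary), simIds(fallback)))
    stop("id mismatch between primary and fallback similarity")
  S <- simValues(fallback)
  use <- availableMask(primary)
  S[use] <- simValues(primary)[use]
  SimilarityMatrix(S, simIds(primary),
                   availableMask(primary) | availableMask(fallback))
}

# Normalised SD and FM plus their raw gates; X-independent, so computed once
# and reused across cross-validation folds.
.prepareStaticSims <- function(assoc, fm, dag, config) {
  sd_ <- semanticSimilarity(dag, diseaseIds(assoc), config@rho)
  sdNorm <- if (sum(availableMask(sd_)) >= 2L &&
                stats::sd(simValues(sd_)[availableMask(sd_)]) > 0)
    zscoreNormalize(sd_) else sd_ # fully-unavailable or degenerate: unused gate
  fmAligned <- .alignSimilarity(fm, mirnaIds(assoc))
  fmNorm <- if (sum(availableMask(fmAligned)) >= 2L &&
                stats::sd(simValues(fmAligned)[availableMask(fmAligned)]) > 0)
    zscoreNormalize(fmAligned) else fmAligned
  list(sd = sdNorm, fm = fmNorm)
}

# Restrict/expand a similarity matrix to an id list; ids absent from the
# matrix become fully unavailable rows (Gaussian fallback takes over).
.alignSimilarity <- function(sim, ids) {
  if (identical(simIds(sim), ids)) return(sim)
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  hit <- ids %in% simIds(sim)
  if (any(hit)) {
    src <- match(ids[hit], simIds(sim))
    S[hit, hit] <- simValues(sim)[src, src]
    A[hit, hit] <- availableMask(sim)[src, src]
  }
  SimilarityMatrix(S, ids, A)
}

#' Build the integrated disease and miRNA similarities
#'
#' Full similarity pipeline: semantic similarity from the DAG, functional
#' similarity as supplied, Gaussian kernels from the association matrix;
#' each z-normalised, then integrated with the kernel as fallback.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param fm miRNA functional [SimilarityMatrix-class] (ids may be a
#'   superset or subset of the association miRNAs).
#' @param dag a [DiseaseDAG-class].
#' @param config an [HCFConfig-class].
#' @param static optional precomputed result of the X-independent part
#'   (internal use by the cross-validation loop).
#' @return `list(ID = , IM = )` of integrated [SimilarityMatrix-class]
#'   objects, available everywhere.
#' @export
buildIntegratedSimilarities <- function(assoc, fm, dag, config = HCFConfig(),
                                        static = NULL) {
  if (is.null(static)) static <- .prepareStaticSims(assoc, fm, dag, config)
  gd <- zscoreNormalize(diseaseKernel(assoc, config@deltaPrimeD))
  gm <- zscoreNormalize(mirnaKernel(assoc, config@deltaPrimeM))
  list(ID = integrateSimilarity(static$sd, gd),
       IM = integrateSimilarity(static$fm, gm))
}
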