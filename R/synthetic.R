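#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Generate a planted-structure association matrix
#'
#' Draws nonnegative disease and miRNA latent factors (each entity has a
#' dominant cluster among `latentRank` factors plus small off-cluster
#' loadings), thresholds their product so that exactly
#' `round(density * nDiseases * nMirnas)` entries are 1, then flips each
#' entry independently with probability `noiseFlipProb`.  The latent-factor
#' construction (rather than an unstructured random graph) plants the very
#' assumption collaborative filtering exploits -- functionally similar
#' miRNAs associating with phenotypically similar diseases -- so recovery
#' is a meaningful end-to-end check.  Fully determined by `spec@seed`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A list: `assoc` (the observed [AssociationMatrix-class]),
#'   `truth` (noiseless 0/1 matrix), `latentScores` (the real-valued factor
#'   product), `diseaseClusters`, `mirnaClusters` (dominant factor of each
#'   entity) and `diseaseFactors`, `mirnaFactors` (the factor matrices).
#' @export
makeAssociations <- function(spec) {
  validObject(spec)
  nd <- spec@nDiseases; nm <- spec@nMirnas; r <- spec@latentRank
  nOnes <- round(spec@density * nd * nm)
  if (nOnes < 1L) stop("unreachable density: fewer than one association")
  .withSeed(spec@seed, {
    dClust <- sample(rep_len(seq_len(r), nd))
    mClust <- sample(rep_len(seq_len(r), nm))
    A <- matrix(abs(stats::rnorm(nd * r, sd = 0.15)), nd, r)
    B <- matrix(abs(stats::rnorm(nm * r, sd = 0.15)), nm, r)
    A[cbind(seq_len(nd), dClust)] <- A[cbind(seq_len(nd), dClust)] + 1
    B[cbind(seq_len(nm), mClust)] <- B[cbind(seq_len(nm), mClust)] + 1
    M <- A %*% t(B)
    # exactly nOnes ones; ties in M broken by entry order for determinism
    ord <- order(-as.vector(M), seq_along(M))
    truth <- matrix(0, nd, nm)
    truth[ord[seq_len(nOnes)]] <- 1
    flips <- matrix(stats::runif(nd * nm) < spec@noiseFlipProb, nd, nm)
    X <- ifelse(flips, 1 - truth, truth)
    dIds <- sprintf("D%03d", seq_len(nd))
    mIds <- sprintf("M%03d", seq_len(nm))
    dimnames(truth) <- dimnames(M) <- list(dIds, mIds)
    list(assoc = AssociationMatrix(X, dIds, mIds),
         truth = truth, latentScores = M,
         diseaseClusters = stats::setNames(dClust, dIds),
         mirnaClusters = stats::setNames(mClust, mIds),
         diseaseFactors = A, mirnaFactors = B)
  })
}

#' Generate a disease hierarchy matching the synthetic diseases
#'
#' Builds a rooted tree (acyclic by construction): one subtree per latent
#' cluster, each a scaffold of internal nodes of depth `dagDepth - 1` with
#' the given branching factor.  Diseases attach below the subtree of their
#' own cluster, so semantic similarity correlates with the planted latent
#' similarity.  A configurable fraction of diseases is left out of the DAG
#' entirely to exercise the Gaussian-kernel fallback of the integration
#' step.  With `dagDepth = 1` every included disease hangs directly off the
#' single root (a star).
#'
#' @param spec a [SyntheticSpec-class].
#' @param clusters named integer vector of disease clusters, as returned by
#'   [makeAssociations()].
#' @param excludeFrac fraction of diseases omitted from the DAG
#'   (default 0.2).
#' @return A [DiseaseDAG-class] whose leaves are the included diseases.
#' @export
makeDag <- function(spec, clusters, excludeFrac = 0.2) {
  validObject(spec)
  stopifnot(excludeFrac >= 0, excludeFrac < 1)
  diseases <- names(clusters)
  .withSeed(spec@seed + 1L, {
    nOut <- round(excludeFrac * length(diseases))
    excluded <- if (nOut > 0L) sample(diseases, nOut) else character()
    included <- setdiff(diseases, excluded)
    edges <- NULL
    root <- "ROOT"
    if (spec@dagDepth == 1L) {
      attach <- stats::setNames(rep(root, length(included)), included)
    } else {
      attach <- character(0)
      for (k in sort(unique(clusters))) {
        # scaffold: breadth-first tree of internal nodes under cluster root
        level <- sprintf("C%d", k)
        edges <- rbind(edges, c(root, level))
        nodes <- level
        clusterNodes <- level
        if (spec@dagDepth > 2L) for (d in seq_len(spec@dagDepth - 2L)) {
          children <- unlist(lapply(nodes, function(p)
            sprintf("%s.%d", p, seq_len(spec@dagBranching))))
          edges <- rbind(edges, cbind(rep(nodes, each = spec@dagBranching),
                                      children))
          nodes <- children
          clusterNodes <- c(clusterNodes, children)
        }
        members <- included[clusters[included] == k]
        if (length(members))
          attach <- c(attach, stats::setNames(
            sample(clusterNodes, length(members), replace = TRUE), members))
      }
    }
    if (length(attach))
      edges <- rbind(edges, cbind(unname(attach), names(attach)))
    DiseaseDAG(edges)
  })
}

#' Generate a surrogate miRNA functional similarity
#'
#' Cosine similarity of the (nonnegative) miRNA latent factors -- values in
#' \[0, 1\], 1 on the diagonal -- with a configurable fraction of
#' off-diagonal entries masked unavailable (value set to 0), to exercise
#' the Gaussian-kernel fallback at integration.
#'
#' @param spec a [SyntheticSpec-class].
#' @param mirnaFactors factor matrix from [makeAssociations()].
#' @param maskFrac fraction of off-diagonal pairs masked (default 0.2).
#' @return A [SimilarityMatrix-class] over the synthetic miRNA labels.
#' @export
makeFunctionalSim <- function(spec, mirnaFactors, maskFrac = 0.2) {
  stopifnot(maskFrac >= 0, maskFrac < 1)
  nm <- nrow(mirnaFactors)
  nrm <- sqrt(rowSums(mirnaFactors^2))
  S <- tcrossprod(mirnaFactors / nrm)
  S <- pmin(pmax((S + t(S)) / 2, 0), 1)
  diag(S) <- 1
  .withSeed(spec@seed + 2L, {
    pairs <- which(upper.tri(S), arr.ind = TRUE)
    nMask <- round(maskFrac * nrow(pairs))
    if (nMask > 0L) {
      pick <- pairs[sample(nrow(pairs), nMask), , drop = FALSE]
      S[pick] <- 0
      S[pick[, 2:1, drop = FALSE]] <- 0
    }
  })
  ids <- sprintf("M%03d", seq_len(nm))
  dimnames(S) <- list(ids, ids)
  SimilarityMatrix(S, ids) # available = S > 0: masked and orthogonal -> FALSE
}

#' Permuted-label negative control
#'
#' Redistributes the known associations uniformly at random over the matrix
#' cells, preserving their number -- a label shuffle that destroys the
#' planted structure (including the structure the Gaussian kernels would
#' read off X) while keeping the sparsity regime.  Model AUC on the control
#' should sit near 0.5.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param seed integer seed.
#' @return A permuted [AssociationMatrix-class] of the same shape.
#' @export
permuteAssociations <- function(assoc, seed) {
  X <- assocMatrix(assoc)
  .withSeed(seed, {
    Xp <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
    Xp[sample(length(X), sum(X))] <- 1
    AssociationMatrix(Xp, diseaseIds(assoc), mirnaIds(assoc))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Generates associations, DAG and functional similarity from one spec and
#' writes them in the package's text formats, plus the noiseless truth
#' matrix as a TSV for downstream evaluation.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @param excludeFrac,maskFrac forwarded to [makeDag()] and
#'   [makeFunctionalSim()].
#' @return Named character vector of the four file paths.
#' @export
simulateDataset <- function(spec, dir, excludeFrac = 0.2, maskFrac = 0.2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- makeAssociations(spec)
  dag <- makeDag(spec, gen$diseaseClusters, excludeFrac)
  fm <- makeFunctionalSim(spec, gen$mirnaFactors, maskFrac)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             dag = file.path(dir, "disease_dag.tsv"),
             functional = file.path(dir, "mirna_functional_sim.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeAssociations(gen$assoc, paths[["associations"]])
  writeDiseaseDAG(dag, paths[["dag"]])
  writeSimilarityMatrix(fm, paths[["functional"]])
  utils::write.table(data.frame(disease = rownames(gen$truth),
                                gen$truth, check.names = FALSE),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
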