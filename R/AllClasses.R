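#' @import methods
NULL

#' Binary disease-by-miRNA association matrix
#'
#' Container for the experimentally supported association network: an
#' \eqn{N_d \times N_m} matrix \eqn{X} with \eqn{X_{ij} = 1} when disease
#' \eqn{d_i} is known to be associated with miRNA \eqn{m_j} and 0 otherwise.
#' Row \eqn{i} of \eqn{X} is the interaction profile \eqn{BV(d_i)} of disease
#' \eqn{d_i}; column \eqn{j} is the interaction profile \eqn{BV(m_j)} of
#' miRNA \eqn{m_j}.
#'
#' @slot diseaseIds character vector of unique disease labels (row order).
#' @slot mirnaIds character vector of unique miRNA labels (column order).
#' @slot assoc numeric matrix with entries in \{0, 1\}.
#'
#' @seealso [loadAssociations()], [sparsityReport()], [predictAll()]
#' @export
setClass("AssociationMatrix",
  representation(
    diseaseIds = "character",
    mirnaIds   = "character",
    assoc      = "matrix"
  )
)

setValidity("AssociationMatrix", function(object) {
  msg <- character()
  X <- object@assoc
  if (nrow(X) != length(object@diseaseIds))
    msg <- c(msg, "row count must equal length(diseaseIds)")
  if (ncol(X) != length(object@mirnaIds))
    msg <- c(msg, "column count must equal length(mirnaIds)")
  if (anyDuplicated(object@diseaseIds))
    msg <- c(msg, "duplicate disease identifiers")
  if (anyDuplicated(object@mirnaIds))
    msg <- c(msg, "duplicate miRNA identifiers")
  if (!is.numeric(X) || !all(X %in% c(0, 1)))
    msg <- c(msg, "association entries must all be exactly 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct an AssociationMatrix
#'
#' @param assoc numeric matrix of 0/1 entries (diseases in rows).
#' @param diseaseIds,mirnaIds identifier vectors; default to the dimnames of
#'   `assoc`.
#' @return An [AssociationMatrix-class] object.
#' @export
AssociationMatrix <- function(assoc,
                              diseaseIds = rownames(assoc),
                              mirnaIds = colnames(assoc)) {
  if (is.null(diseaseIds)) diseaseIds <- paste0("d", seq_len(nrow(assoc)))
  if (is.null(mirnaIds)) mirnaIds <- paste0("m", seq_len(ncol(assoc)))
  assoc <- as.matrix(assoc)
  storage.mode(assoc) <- "double"
  dimnames(assoc) <- list(diseaseIds, mirnaIds)
  new("AssociationMatrix", diseaseIds = as.character(diseaseIds),
      mirnaIds = as.character(mirnaIds), assoc = assoc)
}

#' Labelled square similarity matrix with an availability mask
#'
#' Houses every similarity used by the model: miRNA functional similarity
#' (FM), disease semantic similarity (SD), the Gaussian interaction-profile
#' kernels (GD, GM) and the integrated similarities (ID, IM).  `available`
#' marks entries where the underlying measure is defined; for semantic and
#' functional similarity this encodes the positivity gate used at
#' integration time (an entry counts as available only when the raw measure
#' is defined and strictly positive).
#'
#' @slot ids character vector of labels.
#' @slot sim numeric square matrix, symmetric on available entries.
#' @slot available logical square matrix, symmetric.
#' @export
setClass("SimilarityMatrix",
  representation(
    ids       = "character",
    sim       = "matrix",
    available = "matrix"
  )
)

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  S <- object@sim; A <- object@available
  n <- length(object@ids)
  if (nrow(S) != n || ncol(S) != n)
    msg <- c(msg, "similarity matrix must be square with dim = length(ids)")
  if (nrow(A) != n || ncol(A) != n || !is.logical(A))
    msg <- c(msg, "availability mask must be a logical matrix of the same dim")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate identifiers")
  if (length(msg) == 0L) {
    if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
      msg <- c(msg, "availability mask must be symmetric")
    ok <- A & t(A)
    if (any(ok) && max(abs(S[ok] - t(S)[ok])) > 1e-8)
      msg <- c(msg, "similarity values must be symmetric on available entries")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param sim numeric square matrix.
#' @param ids labels; default dimnames.
#' @param available logical mask; default `sim > 0` (the positivity
#'   convention used by the integration gate).
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(sim, ids = rownames(sim), available = NULL) {
  sim <- as.matrix(sim)
  storage.mode(sim) <- "double"
  if (is.null(ids)) ids <- paste0("x", seq_len(nrow(sim)))
  if (is.null(available)) available <- sim > 0
  dimnames(sim) <- list(ids, ids)
  dimnames(available) <- list(ids, ids)
  new("SimilarityMatrix", ids = as.character(ids), sim = sim,
      available = available)
}

#' Disease directed acyclic graph
#'
#' MeSH-category-C style hierarchy given as parent-to-child edges.  The
#' ancestor closure of a disease (the disease itself plus everything that
#' can reach it along directed edges) is the vertex set over which semantic
#' contributions are computed.
#'
#' @slot nodes character vector of disease labels.
#' @slot edges two-column character matrix of (parent, child) pairs.
#' @export
setClass("DiseaseDAG",
  representation(
    nodes = "character",
    edges = "matrix"
  )
)

setValidity("DiseaseDAG", function(object) {
  msg <- character()
  E <- object@edges
  if (ncol(E) != 2L && length(E) > 0L)
    msg <- c(msg, "edges must be a two-column matrix")
  if (length(E) && !all(E %in% object@nodes))
    msg <- c(msg, "every edge endpoint must be a node")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node labels")
  if (length(msg) == 0L && nrow(E) > 0L) {
    if (any(E[, 1L] == E[, 2L]))
      msg <- c(msg, "self-edges are not allowed")
    else {
      cyc <- .findDirectedCycle(object@nodes, E)
      if (!is.null(cyc))
        msg <- c(msg, paste0("graph contains a cycle: ",
                             paste(cyc, collapse = " -> ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DiseaseDAG
#'
#' @param edges two-column character matrix (parent, child); may have zero
#'   rows.
#' @param nodes node labels; defaults to the union of edge endpoints.
#' @return A [DiseaseDAG-class] object.  Construction fails with an error
#'   naming one cycle if the edge set is cyclic.
#' @export
DiseaseDAG <- function(edges = matrix(character(), ncol = 2L), nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), ncol = 2L)
  storage.mode(edges) <- "character"
  if (is.null(nodes)) nodes <- unique(as.character(t(edges)))
  new("DiseaseDAG", nodes = as.character(nodes), edges = edges)
}

# depth-first search for one directed cycle; returns the vertex sequence or
# NULL.  Kept internal: igraph::is_dag() answers the yes/no question but does
# not hand back a witness for the error message.
.findDirectedCycle <- function(nodes, edges) {
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = nodes))
  state <- setNames(rep.int(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  stack <- character()
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return(invisible())
    state[[v]] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (!is.null(result)) break
      if (state[[w]] == 1L) {
        i <- match(w, stack)
        result <<- c(stack[i:length(stack)], w)
        break
      } else if (state[[w]] == 0L) visit(w)
    }
    stack <<- stack[-length(stack)]
    state[[v]] <<- 2L
    invisible()
  }
  for (v in nodes) {
    if (state[[v]] == 0L) visit(v)
    if (!is.null(result)) break
  }
  result
}

#' Model configuration
#'
#' All free parameters of the predictor in one object.
#'
#' @slot alpha weight in \[0, 1\] splitting disease-based against miRNA-based
#'   evidence inside the (1 - beta) share.
#' @slot beta weight in \[0, 1\] given to the pair-neighbourhood (SDMA) pool;
#'   `beta = 1` uses the pair pool alone.
#' @slot nNeighbors size N of the disease and miRNA neighbourhoods.
#' @slot kPairs size K of the pair neighbourhood.
#' @slot svdRank positive integer rank, or an energy fraction in (0, 1): the
#'   smallest rank whose squared singular values retain that fraction of the
#'   total spectrum energy.
#' @slot svdEnabled logical; disable to score the raw binary matrix.
#' @slot rho semantic contribution decay factor in (0, 1).
#' @slot deltaPrimeD,deltaPrimeM raw Gaussian-kernel bandwidths (> 0) for
#'   diseases and miRNAs.
#' @slot fastLoocv logical; freeze similarities at their full-data values
#'   during cross-validation instead of recomputing them per fold.
#' @export
setClass("HCFConfig",
  representation(
    alpha       = "numeric",
    beta        = "numeric",
    nNeighbors  = "integer",
    kPairs      = "integer",
    svdRank     = "numeric",
    svdEnabled  = "logical",
    rho         = "numeric",
    deltaPrimeD = "numeric",
    deltaPrimeM = "numeric",
    fastLoocv   = "logical"
  )
)

setValidity("HCFConfig", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@beta < 0 || object@beta > 1) msg <- c(msg, "beta must lie in [0, 1]")
  if (object@nNeighbors < 1L) msg <- c(msg, "nNeighbors must be >= 1")
  if (object@kPairs < 1L) msg <- c(msg, "kPairs must be >= 1")
  if (object@svdRank <= 0 && object@svdEnabled)
    msg <- c(msg, "svdRank must be a positive integer or a fraction in (0, 1)")
  if (object@rho <= 0 || object@rho >= 1) msg <- c(msg, "rho must lie in (0, 1)")
  if (object@deltaPrimeD <= 0) msg <- c(msg, "deltaPrimeD must be > 0")
  if (object@deltaPrimeM <= 0) msg <- c(msg, "deltaPrimeM must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an HCFConfig
#'
#' Defaults follow the model's published operating point where one exists
#' (`alpha = 0.3`, `beta = 0.1` from the grid search) and the field's
#' conventions elsewhere (`rho = 0.5`, unit raw bandwidths, `N = K = 20`,
#' SVD retaining 90\% of spectrum energy).
#'
#' @param alpha,beta fusion weights in \[0, 1\].
#' @param nNeighbors,kPairs neighbourhood sizes N and K.
#' @param svdRank integer rank or energy fraction in (0, 1).
#' @param svdEnabled logical.
#' @param rho semantic decay factor in (0, 1).
#' @param deltaPrimeD,deltaPrimeM raw kernel bandwidths.
#' @param fastLoocv logical, see [loocv()].
#' @return An [HCFConfig-class] object.
#' @examples
#' HCFConfig(alpha = 0.3, beta = 0.1, nNeighbors = 5)
#' @export
HCFConfig <- function(alpha = 0.3, beta = 0.1, nNeighbors = 20L, kPairs = 20L,
                      svdRank = 0.9, svdEnabled = TRUE, rho = 0.5,
                      deltaPrimeD = 1, deltaPrimeM = 1, fastLoocv = FALSE) {
  new("HCFConfig", alpha = alpha, beta = beta,
      nNeighbors = as.integer(nNeighbors), kPairs = as.integer(kPairs),
      svdRank = svdRank, svdEnabled = svdEnabled, rho = rho,
      deltaPrimeD = deltaPrimeD, deltaPrimeM = deltaPrimeM,
      fastLoocv = fastLoocv)
}

#' Predicted score matrix
#'
#' Real-valued predicted association scores \eqn{\hat x_{ij}}.  Scores are
#' rankings, not probabilities, and are deliberately not clipped to \[0, 1\].
#'
#' @slot diseaseIds,mirnaIds identifier vectors.
#' @slot scores numeric matrix of finite predicted scores.
#' @export
setClass("ScoreMatrix",
  representation(
    diseaseIds = "character",
    mirnaIds   = "character",
    scores     = "matrix"
  )
)

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  if (nrow(object@scores) != length(object@diseaseIds) ||
      ncol(object@scores) != length(object@mirnaIds))
    msg <- c(msg, "score dimensions must match identifier lists")
  if (!all(is.finite(object@scores)))
    msg <- c(msg, "all scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoreMatrix
#' @param scores numeric matrix.
#' @param diseaseIds,mirnaIds identifiers; default dimnames.
#' @export
ScoreMatrix <- function(scores, diseaseIds = rownames(scores),
                        mirnaIds = colnames(scores)) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  dimnames(scores) <- list(diseaseIds, mirnaIds)
  new("ScoreMatrix", diseaseIds = as.character(diseaseIds),
      mirnaIds = as.character(mirnaIds), scores = scores)
}

#' ROC curve with area under the curve
#'
#' The curve is produced by sweeping a score threshold: at each cutoff,
#' TPR = TP / (TP + FN) and FPR = FP / (FP + TN).  The stored `auc` is the
#' Mann-Whitney statistic (ties counted one half), which equals the
#' probability that a random positive outranks a random negative and agrees
#' with trapezoidal integration of the stored curve.
#'
#' @slot thresholds score cutoffs, descending, starting at `Inf`.
#' @slot tpr,fpr nondecreasing vectors starting at 0 and ending at 1.
#' @slot auc scalar in \[0, 1\].
#' @export
setClass("ROCResult",
  representation(
    thresholds = "numeric",
    tpr        = "numeric",
    fpr        = "numeric",
    auc        = "numeric"
  )
)

setValidity("ROCResult", function(object) {
  msg <- character()
  if (length(object@tpr) != length(object@fpr) ||
      length(object@thresholds) != length(object@tpr))
    msg <- c(msg, "thresholds, tpr and fpr must have equal length")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    msg <- c(msg, "tpr and fpr must be nondecreasing")
  n <- length(object@tpr)
  if (n > 0 && (object@tpr[1L] != 0 || object@fpr[1L] != 0 ||
                object@tpr[n] != 1 || object@fpr[n] != 1))
    msg <- c(msg, "curve must start at (0,0) and end at (1,1)")
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Leave-one-out cross-validation report
#'
#' @slot folds data.frame with one row per held-out known association:
#'   columns `disease`, `mirna`, `rank` (descending-score rank of the
#'   held-out miRNA among the fold's candidates, ties as mean rank) and
#'   `nCandidates`.
#' @slot roc pooled [ROCResult-class] over fold-normalised ranks.
#' @slot config the [HCFConfig-class] used.
#' @export
setClass("LOOCVReport",
  representation(
    folds  = "data.frame",
    roc    = "ROCResult",
    config = "HCFConfig"
  )
)

setValidity("LOOCVReport", function(object) {
  f <- object@folds
  msg <- character()
  need <- c("disease", "mirna", "rank", "nCandidates")
  if (!all(need %in% names(f)))
    msg <- c(msg, "folds must have columns disease, mirna, rank, nCandidates")
  else if (nrow(f) && (any(f$rank < 1) || any(f$rank > f$nCandidates)))
    msg <- c(msg, "every fold must satisfy 1 <= rank <= nCandidates")
  if (length(msg)) msg else TRUE
})

#' Synthetic-data specification
#'
#' Parameters of the planted-structure generator used for self-contained
#' testing.  The defaults emulate the scale and sparsity regime of curated
#' human miRNA-disease catalogues (a few percent of entries known) at desk
#' size.
#'
#' @slot nDiseases,nMirnas matrix dimensions.
#' @slot density fraction of entries set to 1 before noise.
#' @slot latentRank number of planted latent factors.
#' @slot noiseFlipProb per-entry flip probability in \[0, 1).
#' @slot dagDepth,dagBranching shape of the generated disease hierarchy.
#' @slot seed integer seed; every generator is a pure function of it.
#' @export
setClass("SyntheticSpec",
  representation(
    nDiseases     = "integer",
    nMirnas       = "integer",
    density       = "numeric",
    latentRank    = "integer",
    noiseFlipProb = "numeric",
    dagDepth      = "integer",
    dagBranching  = "integer",
    seed          = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nDiseases < 1L || object@nMirnas < 1L)
    msg <- c(msg, "dimensions must be positive")
  if (object@density <= 0 || object@density >= 1)
    msg <- c(msg, "density must lie in (0, 1)")
  if (object@density * object@nDiseases * object@nMirnas < 1)
    msg <- c(msg, "density too low: fewer than one association")
  if (object@latentRank < 1L ||
      object@latentRank > min(object@nDiseases, object@nMirnas))
    msg <- c(msg, "latentRank must lie in [1, min(nDiseases, nMirnas)]")
  if (object@noiseFlipProb < 0 || object@noiseFlipProb >= 1)
    msg <- c(msg, "noiseFlipProb must lie in [0, 1)")
  if (object@dagDepth < 1L || object@dagBranching < 1L)
    msg <- c(msg, "dagDepth and dagBranching must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticSpec
#' @param nDiseases,nMirnas matrix dimensions.
#' @param density fraction of known associations (default 0.05).
#' @param latentRank planted rank (default 3).
#' @param noiseFlipProb per-entry flip probability (default 0.02).
#' @param dagDepth,dagBranching hierarchy shape (defaults 3 and 2).
#' @param seed integer seed (mandatory; no global random state is used).
#' @export
SyntheticSpec <- function(nDiseases, nMirnas, density = 0.05, latentRank = 3L,
                          noiseFlipProb = 0.02, dagDepth = 3L,
                          dagBranching = 2L, seed) {
  new("SyntheticSpec", nDiseases = as.integer(nDiseases),
      nMirnas = as.integer(nMirnas), density = density,
      latentRank = as.integer(latentRank), noiseFlipProb = noiseFlipProb,
      dagDepth = as.integer(dagDepth), dagBranching = as.integer(dagBranching),
      seed = as.integer(seed))
}
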