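#' @include AllClasses.R
NULL

#' Accessors for mdacf classes
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param x an mdacf object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))
#' @rdname accessors
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))
#' @rdname accessors
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))
#' @rdname accessors
#' @export
setGeneric("simIds", function(x) standardGeneric("simIds"))
#' @rdname accessors
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))
#' @rdname accessors
#' @export
setGeneric("availableMask", function(x) standardGeneric("availableMask"))
#' @rdname accessors
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))
#' @rdname accessors
#' @export
setGeneric("dagEdges", function(x) standardGeneric("dagEdges"))
#' @rdname accessors
#' @export
setGeneric("dagRoots", function(x) standardGeneric("dagRoots"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("foldRanks", function(x) standardGeneric("foldRanks"))
#' @rdname accessors
#' @export
setGeneric("rocResult", function(x) standardGeneric("rocResult"))
#' @rdname accessors
#' @export
setGeneric("configUsed", function(x) standardGeneric("configUsed"))

#' @rdname accessors
#' @export
setMethod("diseaseIds", "AssociationMatrix", function(x) x@diseaseIds)
#' @rdname accessors
#' @export
setMethod("mirnaIds", "AssociationMatrix", function(x) x@mirnaIds)
#' @rdname accessors
#' @export
setMethod("assocMatrix", "AssociationMatrix", function(x) x@assoc)
#' @rdname accessors
#' @export
setMethod("diseaseIds", "ScoreMatrix", function(x) x@diseaseIds)
#' @rdname accessors
#' @export
setMethod("mirnaIds", "ScoreMatrix", function(x) x@mirnaIds)
#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("simIds", "SimilarityMatrix", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@sim)
#' @rdname accessors
#' @export
setMethod("availableMask", "SimilarityMatrix", function(x) x@available)
#' @rdname accessors
#' @export
setMethod("dagNodes", "DiseaseDAG", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("dagEdges", "DiseaseDAG", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("dagRoots", "DiseaseDAG", function(x)
  setdiff(x@nodes, unique(x@edges[, 2L])))
#' @rdname accessors
#' @export
setMethod("auc", "ROCResult", function(x) x@auc)
#' @rdname accessors
#' @export
setMethod("rocPoints", "ROCResult", function(x)
  data.frame(threshold = x@thresholds, fpr = x@fpr, tpr = x@tpr))
#' @rdname accessors
#' @export
setMethod("foldRanks", "LOOCVReport", function(x) x@folds)
#' @rdname accessors
#' @export
setMethod("rocResult", "LOOCVReport", function(x) x@roc)
#' @rdname accessors
#' @export
setMethod("configUsed", "LOOCVReport", function(x) x@config)
#' @rdname accessors
#' @export
setMethod("auc", "LOOCVReport", function(x) x@roc@auc)

setMethod("dim", "AssociationMatrix", function(x) dim(x@assoc))
setMethod("dim", "ScoreMatrix", function(x) dim(x@scores))

setMethod("show", "AssociationMatrix", function(object) {
  cat("AssociationMatrix:", length(object@diseaseIds), "diseases x",
      length(object@mirnaIds), "miRNAs,", sum(object@assoc),
      "known associations\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix:", length(object@ids), "x", length(object@ids),
      sprintf("(%.1f%% available)\n", 100 * mean(object@available)))
})

setMethod("show", "DiseaseDAG", function(object) {
  cat("DiseaseDAG:", length(object@nodes), "nodes,", nrow(object@edges),
      "edges,", length(dagRoots(object)), "root(s)\n")
})

setMethod("show", "HCFConfig", function(object) {
  cat("HCFConfig: alpha =", object@alpha, "beta =", object@beta,
      "N =", object@nNeighbors, "K =", object@kPairs, "\n",
      " svd =", if (object@svdEnabled) object@svdRank else "off",
      " rho =", object@rho, " deltaPrime =", object@deltaPrimeD, "/",
      object@deltaPrimeM, "\n")
})

setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix:", length(object@diseaseIds), "diseases x",
      length(object@mirnaIds), "miRNAs, score range [",
      sprintf("%.4g, %.4g", min(object@scores), max(object@scores)), "]\n")
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.4f (%d curve points)\n", object@auc,
              length(object@tpr)))
})

setMethod("show", "LOOCVReport", function(object) {
  cat(sprintf("LOOCVReport: %d folds, pooled AUC = %.4f\n",
              nrow(object@folds), object@roc@auc))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nDiseases, "x", object@nMirnas,
      "density", object@density, "rank", object@latentRank,
      "flip", object@noiseFlipProb, "seed", object@seed, "\n")
})
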