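#' @include AllClasses.R AllGenerics.R similarity.R hcf-core.R
NULL

#' ROC curve and AUC from positive and negative scores
#'
#' The AUC is the Mann-Whitney statistic: the probability that a randomly
#' chosen positive scores higher than a randomly chosen negative, with ties
#' counted one half (AUC 1 is a perfect ranker, 0.5 a worthless one).  The
#' curve is built by sweeping a threshold over the pooled scores;
#' trapezoidal integration of the curve equals the Mann-Whitney value
#' exactly, ties included (see [trapezoidAuc()]).
#'
#' @param positives,negatives non-empty numeric score vectors.
#' @return A [ROCResult-class].
#' @examples
#' auc(rocAuc(c(0.9, 0.4), c(0.6, 0.1))) # 0.75
#' @export
rocAuc <- function(positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("positive and negative score lists must be non-empty")
  np <- length(positives); nn <- length(negatives)
  scores <- c(positives, negatives)
  lab <- rep(c(1L, 0L), c(np, nn))
  r <- rank(scores) # ties.method = "average"
  aucMW <- (sum(r[lab == 1L]) - np * (np + 1) / 2) / (np * nn)
  o <- order(-scores)
  s <- scores[o]; l <- lab[o]
  last <- cumsum(rle(s)$lengths) # end of each tied block
  new("ROCResult",
      thresholds = c(Inf, s[last]),
      tpr = c(0, cumsum(l)[last] / np),
      fpr = c(0, cumsum(1L - l)[last] / nn),
      auc = aucMW)
}

#' Trapezoidal area under a ROC curve
#'
#' Independent integration of the stored curve; agrees with the
#' Mann-Whitney `auc` slot to machine precision.
#'
#' @param roc a [ROCResult-class].
#' @return Scalar area.
#' @export
trapezoidAuc <- function(roc) {
  tpr <- roc@tpr; fpr <- roc@fpr
  sum(diff(fpr) * (utils::head(tpr, -1L) + tpr[-1L]) / 2)
}

# flip one entry of an AssociationMatrix without reconstructing
.withEntry <- function(assoc, i, j, value) {
  assoc@assoc[i, j] <- value
  assoc
}

#' Leave-one-out cross-validation
#'
#' Each known association is held out in turn: the entry is zeroed, every
#' X-derived quantity (Gaussian kernels, integrated similarities, SVD
#' reconstruction, neighbourhoods) is recomputed on the training matrix,
#' and the held-out miRNA is ranked by descending score among the disease's
#' candidate miRNAs (the held-out one plus every miRNA not known to be
#' associated with the disease).  Ties take the mean rank.  Folds are
#' pooled into one ROC by mapping each candidate's rank r in a fold of n
#' candidates to the normalised score (n - r) / (n - 1), which makes folds
#' with different candidate-set sizes commensurable.
#'
#' @param assoc an [AssociationMatrix-class] with at least 2 known
#'   associations.
#' @param fm miRNA functional [SimilarityMatrix-class].
#' @param dag a [DiseaseDAG-class].
#' @param config an [HCFConfig-class].  With `fastLoocv = TRUE` the
#'   integrated similarities are frozen at their full-data values (common
#'   in this literature; the rigorous per-fold recomputation is the
#'   default).
#' @param method `"optimized"` scores only the held-out disease's row;
#'   `"bruteforce"` recomputes the full score matrix per fold through
#'   [predictAll()].  The two are fold-for-fold identical; the brute-force
#'   path exists as a reference.
#' @param scorer optional function `(trainX, i)` returning a score vector
#'   over all miRNAs for disease row `i`; replaces the model entirely
#'   (used to validate the harness with perfect/constant scorers).
#' @return A [LOOCVReport-class].
#' @export
loocv <- function(assoc, fm, dag, config = HCFConfig(),
                  method = c("optimized", "bruteforce"), scorer = NULL) {
  method <- match.arg(method)
  X0 <- assocMatrix(assoc)
  ones <- which(X0 == 1, arr.ind = TRUE)
  if (nrow(ones) < 2L) stop("need at least 2 known associations for LOOCV")
  ones <- ones[order(ones[, 1L], ones[, 2L]), , drop = FALSE]
  useModel <- is.null(scorer)
  static <- if (useModel) .prepareStaticSims(assoc, fm, dag, config)
  simsFull <- if (useModel && config@fastLoocv)
    buildIntegratedSimilarities(assoc, fm, dag, config, static = static)
  posScores <- numeric(nrow(ones))
  negScores <- vector("list", nrow(ones))
  folds <- data.frame(disease = character(nrow(ones)),
                      mirna = character(nrow(ones)),
                      rank = numeric(nrow(ones)),
                      nCandidates = integer(nrow(ones)))
  for (f in seq_len(nrow(ones))) {
    i <- ones[f, 1L]; j <- ones[f, 2L]
    Xtr <- X0; Xtr[i, j] <- 0
    cand <- sort(unique(c(j, which(X0[i, ] == 0))))
    if (useModel) {
      assocTr <- .withEntry(assoc, i, j, 0)
      sims <- if (config@fastLoocv) simsFull
        else buildIntegratedSimilarities(assocTr, fm, dag, config,
                                         static = static)
      Xt <- if (config@svdEnabled) .svdDenoiseMatrix(Xtr, config@svdRank)
        else Xtr
      scores <- if (method == "optimized")
        .scoreRows(Xt, sims$ID, sims$IM, i, config)[1L, cand]
      else scoreValues(predictAll(assocTr, sims$ID, sims$IM, config))[i, cand]
    } else {
      scores <- scorer(Xtr, i)[cand]
    }
    n <- length(cand)
    r <- rank(-scores) # descending, mean ties
    norm <- if (n > 1L) (n - r) / (n - 1L) else rep(0.5, n)
    hit <- which(cand == j)
    folds$disease[f] <- diseaseIds(assoc)[i]
    folds$mirna[f] <- mirnaIds(assoc)[j]
    folds$rank[f] <- r[hit]
    folds$nCandidates[f] <- n
    posScores[f] <- norm[hit]
    negScores[[f]] <- norm[-hit]
  }
  roc <- rocAuc(posScores, unlist(negScores))
  new("LOOCVReport", folds = folds, roc = roc, config = config)
}

#' Grid search over the fusion weights
#'
#' Runs [loocv()] at every (alpha, beta) grid point and reports the AUC
#' table plus the argmax (ties resolved towards the smallest alpha, then
#' the smallest beta).  The default alpha grid sweeps 0.1 to 0.9 in steps
#' of 0.2 at beta = 0.1, the published one-dimensional sweep; supply both
#' grids for a full two-dimensional search.
#'
#' @inheritParams loocv
#' @param alphaGrid,betaGrid numeric vectors of candidate weights.
#' @return `list(table = data.frame(alpha, beta, auc), best = )` where
#'   `best` is the winning row.
#' @export
gridSearch <- function(assoc, fm, dag,
                       alphaGrid = seq(0.1, 0.9, by = 0.2), betaGrid = 0.1,
                       config = HCFConfig()) {
  stopifnot(length(alphaGrid) >= 1L, length(betaGrid) >= 1L)
  grid <- expand.grid(alpha = alphaGrid, beta = betaGrid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$auc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg@alpha <- grid$alpha[g]
    cfg@beta <- grid$beta[g]
    auc(loocv(assoc, fm, dag, cfg))
  }, 0)
  best <- grid[order(-grid$auc, grid$alpha, grid$beta)[1L], ]
  rownames(best) <- NULL
  list(table = grid, best = best)
}

#' Ranked candidate miRNAs for one disease
#'
#' Case-study export.  In `"with-known"` mode the model is trained on the
#' full association matrix and only miRNAs with no known association to the
#' disease are ranked.  In `"isolated"` mode the disease's entire row is
#' zeroed first (and every X-derived quantity recomputed), emulating a
#' disease without any known miRNA; all miRNAs are then ranked, so the
#' prioritisation draws solely on similar diseases.
#'
#' @inheritParams loocv
#' @param disease a disease label present in the association matrix.
#' @param mode `"with-known"` or `"isolated"`.
#' @param top number of top-ranked candidates to return (default 50).
#' @return data.frame with columns `rank`, `mirna`, `score`, descending by
#'   score (ties by miRNA label).
#' @export
caseStudyRank <- function(assoc, fm, dag, disease, config = HCFConfig(),
                          mode = c("with-known", "isolated"), top = 50L) {
  mode <- match.arg(mode)
  i <- match(disease, diseaseIds(assoc))
  if (is.na(i)) stop("unknown disease: ", disease)
  if (mode == "isolated") {
    X <- assocMatrix(assoc)
    X[i, ] <- 0
    assoc <- AssociationMatrix(X, diseaseIds(assoc), mirnaIds(assoc))
    cand <- seq_along(mirnaIds(assoc))
  } else {
    cand <- which(assocMatrix(assoc)[i, ] == 0)
  }
  if (length(cand) == 0L)
    return(data.frame(rank = integer(), mirna = character(),
                      score = numeric()))
  sims <- buildIntegratedSimilarities(assoc, fm, dag, config)
  X <- assocMatrix(assoc)
  Xt <- if (config@svdEnabled) .svdDenoiseMatrix(X, config@svdRank) else X
  scores <- .scoreRows(Xt, sims$ID, sims$IM, i, config)[1L, cand]
  ord <- order(-scores, mirnaIds(assoc)[cand])
  keep <- utils::head(ord, top)
  data.frame(rank = seq_along(keep),
             mirna = mirnaIds(assoc)[cand][keep],
             score = unname(scores[keep]))
}
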