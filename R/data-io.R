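#' @include AllClasses.R AllGenerics.R
NULL

.readLinesNoComment <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineNo = which(keep))
}

#' Read a disease-miRNA association edge list
#'
#' The file is UTF-8 text with one association per line: a disease label and
#' a miRNA label separated by a tab (or any whitespace).  Lines starting
#' with `#` are comments.  Duplicate lines collapse to a single association:
#' the matrix is binary.
#'
#' @param path path to the edge list.
#' @param idOrder `"appearance"` (default) numbers rows/columns by first
#'   appearance in the file, making indices reproducible from the same file;
#'   `"lexicographic"` sorts the labels.
#' @return An [AssociationMatrix-class] with `X[i, j] = 1` iff the pair
#'   occurs in the file.
#' @examples
#' f <- tempfile()
#' writeLines(c("d1\tm1", "d1\tm2", "d2\tm2"), f)
#' loadAssociations(f)
#' @export
loadAssociations <- function(path, idOrder = c("appearance", "lexicographic")) {
  idOrder <- match.arg(idOrder)
  parsed <- .readLinesNoComment(path)
  if (length(parsed$lines) == 0L) stop("no associations in ", path)
  fields <- strsplit(parsed$lines, "[\t ]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop("malformed association line ", parsed$lineNo[bad[1L]],
         " in ", path, ": expected at least two fields")
  d <- vapply(fields, `[`, "", 1L)
  m <- vapply(fields, `[`, "", 2L)
  dIds <- unique(d); mIds <- unique(m)
  if (idOrder == "lexicographic") { dIds <- sort(dIds); mIds <- sort(mIds) }
  X <- matrix(0, length(dIds), length(mIds), dimnames = list(dIds, mIds))
  X[cbind(match(d, dIds), match(m, mIds))] <- 1
  AssociationMatrix(X, dIds, mIds)
}

#' Write an association edge list
#'
#' Inverse of [loadAssociations()]: writes one `disease<TAB>miRNA` line per
#' known association, in row-major matrix order so that a reload under
#' first-appearance ordering reproduces the identifier order.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param path output path.
#' @export
writeAssociations <- function(assoc, path) {
  X <- assocMatrix(assoc)
  idx <- which(t(X) == 1, arr.ind = TRUE) # transpose: row-major over diseases
  lines <- paste(diseaseIds(assoc)[idx[, 2L]], mirnaIds(assoc)[idx[, 1L]],
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled similarity matrix
#'
#' Text matrix with a header row of labels and the same labels in the first
#' column, as distributed for precomputed miRNA functional similarity.
#' Near-symmetric input (published matrices are rarely bit-symmetric) is
#' symmetrised by averaging with its transpose; a warning is raised when the
#' maximum asymmetry exceeds `1e-8`.
#'
#' @param path path to the matrix file.
#' @param maskPath optional sidecar file of the same shape holding 0/1
#'   availability flags, for measures where 0 is a legitimate measured
#'   value.  By default availability is `value > 0`, matching the positivity
#'   gate applied at similarity integration.
#' @return A [SimilarityMatrix-class].
#' @export
loadSimilarityMatrix <- function(path, maskPath = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- utils::read.table(path, header = TRUE, row.names = 1L, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#")
  if (nrow(tab) != ncol(tab))
    stop("similarity matrix body is not square: ", nrow(tab), " x ", ncol(tab))
  if (!identical(rownames(tab), colnames(tab)))
    stop("row labels do not match column labels in ", path)
  S <- suppressWarnings(matrix(as.numeric(as.matrix(tab)), nrow(tab),
                               dimnames = dimnames(tab)))
  if (anyNA(S)) {
    bad <- which(is.na(S), arr.ind = TRUE)[1L, ]
    stop("non-numeric similarity value at row ", rownames(S)[bad[1L]],
         ", column ", colnames(S)[bad[2L]])
  }
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8)
    warning(sprintf("asymmetric similarity input (max |S - t(S)| = %.3g); %s",
                    asym, "symmetrised by averaging"))
  S <- (S + t(S)) / 2
  avail <- if (is.null(maskPath)) S > 0 else {
    M <- utils::read.table(maskPath, header = TRUE, row.names = 1L, sep = "\t",
                           check.names = FALSE)
    as.matrix(M) > 0
  }
  SimilarityMatrix(S, rownames(S), avail)
}

#' Write a labelled similarity matrix
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path output path.
#' @param maskPath optional path for the availability sidecar.
#' @export
writeSimilarityMatrix <- function(sim, path, maskPath = NULL) {
  S <- simValues(sim)
  df <- data.frame(id = simIds(sim), format(S, digits = 10, trim = TRUE),
                   check.names = FALSE)
  names(df)[1L] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(maskPath)) {
    dfm <- data.frame(id = simIds(sim), availableMask(sim) + 0L,
                      check.names = FALSE)
    names(dfm)[1L] <- ""
    utils::write.table(dfm, maskPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a disease hierarchy edge list
#'
#' One `parent<TAB>child` pair per line; `#` comments allowed.  The edge set
#' must be acyclic; a cycle aborts with an error listing one offending
#' cycle.  An empty file yields an empty DAG (valid: semantic similarity is
#' then unavailable everywhere and the Gaussian kernel takes over).
#'
#' @param path path to the edge list.
#' @return A [DiseaseDAG-class].
#' @export
loadDiseaseDAG <- function(path) {
  parsed <- .readLinesNoComment(path)
  if (length(parsed$lines) == 0L) return(DiseaseDAG())
  fields <- strsplit(parsed$lines, "[\t ]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop("malformed DAG line ", parsed$lineNo[bad[1L]], " in ", path)
  E <- cbind(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L))
  DiseaseDAG(unique(E))
}

#' Write a disease hierarchy edge list
#' @param dag a [DiseaseDAG-class].
#' @param path output path.
#' @export
writeDiseaseDAG <- function(dag, path) {
  E <- dagEdges(dag)
  writeLines(if (nrow(E)) paste(E[, 1L], E[, 2L], sep = "\t") else character(),
             path)
  invisible(path)
}

#' Write predicted scores in long format
#'
#' Tab-separated columns `disease`, `mirna`, `score`, `known`, sorted per
#' disease by descending score with ties broken by miRNA label.  Scores are
#' written with 10 significant digits so a round-trip through
#' [readScores()] reproduces the matrix to 1e-9.
#'
#' @param scores a [ScoreMatrix-class].
#' @param path output path.
#' @param assoc optional [AssociationMatrix-class] supplying the `known`
#'   flag (0 everywhere when absent).
#' @export
writeScores <- function(scores, path, assoc = NULL) {
  S <- scoreValues(scores)
  if (!all(is.finite(S))) stop("scores must be finite")
  known <- if (is.null(assoc)) matrix(0, nrow(S), ncol(S)) else {
    stopifnot(identical(diseaseIds(assoc), diseaseIds(scores)),
              identical(mirnaIds(assoc), mirnaIds(scores)))
    assocMatrix(assoc)
  }
  rows <- do.call(rbind, lapply(seq_along(diseaseIds(scores)), function(i) {
    ord <- order(-S[i, ], mirnaIds(scores))
    data.frame(disease = diseaseIds(scores)[i],
               mirna = mirnaIds(scores)[ord],
               score = S[i, ord], known = known[i, ord])
  }))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("disease\tmirna\tscore\tknown", con)
  writeLines(paste(rows$disease, rows$mirna,
                   sprintf("%.10g", rows$score), rows$known, sep = "\t"), con)
  invisible(path)
}

#' Read scores written by [writeScores()]
#'
#' @param path path to the long-format score file.
#' @return A [ScoreMatrix-class]; the `known` flags are attached as the
#'   attribute `"known"`.
#' @export
readScores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  dIds <- unique(tab$disease); mIds <- unique(tab$mirna)
  S <- matrix(NA_real_, length(dIds), length(mIds),
              dimnames = list(dIds, mIds))
  K <- S
  idx <- cbind(match(tab$disease, dIds), match(tab$mirna, mIds))
  S[idx] <- tab$score
  K[idx] <- tab$known
  out <- ScoreMatrix(S, dIds, mIds)
  attr(out, "known") <- K
  out
}

#' Sparsity report for an association matrix
#'
#' Summarises how sparse the association network is: dimensions, number of
#' known associations (ones), number of unknown entries (zeros) and density.
#'
#' @param assoc an [AssociationMatrix-class].
#' @return An object of class `"mdacf_sparsity"` with fields `nDiseases`,
#'   `nMirnas`, `nKnown`, `nZeros`, `density`; printing it reports all five.
#' @examples
#' am <- AssociationMatrix(matrix(c(1, 0, 0, 1), 2))
#' sparsityReport(am)
#' @export
sparsityReport <- function(assoc) {
  X <- assocMatrix(assoc)
  out <- list(nDiseases = nrow(X), nMirnas = ncol(X),
              nKnown = sum(X == 1), nZeros = sum(X == 0),
              density = mean(X))
  class(out) <- "mdacf_sparsity"
  out
}

#' @export
print.mdacf_sparsity <- function(x, ...) {
  cat(sprintf(
    "Association matrix: %d diseases x %d miRNAs\n  known associations: %d\n  unknown (zero) entries: %d\n  density: %.4f\n",
    x$nDiseases, x$nMirnas, x$nKnown, x$nZeros, x$density))
  invisible(x)
}
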