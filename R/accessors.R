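#' @rdname AssociationMatrix-class
#' @param pairs two-column character matrix or data.frame of
#'   (disease, miRNA) associations, or `NULL` when `values` is given.
#' @param values pre-built binary matrix with dimnames (alternative to
#'   `pairs`).
#' @param normalizeIds lower-case and trim labels before matching
#'   (default TRUE).
#' @return `AssociationMatrix()` returns an \linkS4class{AssociationMatrix}.
#' @examples
#' a <- AssociationMatrix(pairs = cbind(c("d1", "d1", "d2"),
#'                                      c("m1", "m2", "m2")))
#' assocMatrix(a)
#' @export
AssociationMatrix <- function(pairs = NULL, values = NULL,
                              normalizeIds = TRUE) {
  if (is.null(values)) {
    if (is.null(pairs) || NROW(pairs) == 0L) stop("no associations")
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns")
    if (any(!nzchar(pairs))) stop("empty labels in association pairs")
    if (normalizeIds) pairs[] <- .normalizeIds(pairs)
    dup <- duplicated(paste(pairs[, 1], pairs[, 2], sep = "\r"))
    if (any(dup)) {
      warning(sum(dup), " duplicate association pair(s) removed")
      pairs <- pairs[!dup, , drop = FALSE]
    }
    dids <- sort(unique(pairs[, 1]))
    mids <- sort(unique(pairs[, 2]))
    values <- matrix(0, length(dids), length(mids),
                     dimnames = list(dids, mids))
    values[cbind(pairs[, 1], pairs[, 2])] <- 1
  }
  new("AssociationMatrix", assoc = values)
}

#' @rdname AssociationMatrix-class
#' @param x,object an `AssociationMatrix`.
#' @export
assocMatrix <- function(x) x@assoc

#' @rdname AssociationMatrix-class
#' @export
diseaseIds <- function(x) rownames(x@assoc)

#' @rdname AssociationMatrix-class
#' @export
mirnaIds <- function(x) colnames(x@assoc)

#' @rdname AssociationMatrix-class
#' @param disease a disease ID.
#' @return `knownMirnas()` returns P(i): the miRNA IDs with a known
#'   association to `disease`.
#' @export
knownMirnas <- function(x, disease) {
  stopifnot(disease %in% diseaseIds(x))
  colnames(x@assoc)[x@assoc[disease, ] == 1]
}

#' @rdname AssociationMatrix-class
#' @param mirna a miRNA ID.
#' @return `knownDiseases()` returns Q(j): the disease IDs with a known
#'   association to `mirna`.
#' @export
knownDiseases <- function(x, mirna) {
  stopifnot(mirna %in% mirnaIds(x))
  rownames(x@assoc)[x@assoc[, mirna] == 1]
}

setMethod("show", "AssociationMatrix", function(object) {
  cat("AssociationMatrix:", nrow(object@assoc), "diseases x",
      ncol(object@assoc), "miRNAs,", sum(object@assoc),
      "known associations\n")
})

#' @rdname SimilarityMatrix-class
#' @param values square symmetric numeric matrix with matching dimnames.
#' @param kind similarity kind (see the class slot documentation).
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(values, kind) {
  new("SimilarityMatrix", values = values, kind = kind)
}

#' @rdname SimilarityMatrix-class
#' @param x,object a `SimilarityMatrix`.
#' @export
simValues <- function(x) x@values

#' @rdname SimilarityMatrix-class
#' @export
simKind <- function(x) x@kind

#' @rdname SimilarityMatrix-class
#' @export
simIds <- function(x) rownames(x@values)

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix (", object@kind, "): ", nrow(object@values), " x ",
      ncol(object@values), ", mean off-diagonal ",
      if (nrow(object@values) > 1)
        signif(mean(object@values[row(object@values) !=
                                  col(object@values)]), 4) else NA,
      "\n", sep = "")
})

#' @rdname DiseaseDAG-class
#' @param root the disease label.
#' @param edges character matrix (parent, child); may have zero rows.
#' @param nodes optional node set; defaults to root plus edge endpoints.
#' @return a \linkS4class{DiseaseDAG}.
#' @export
DiseaseDAG <- function(root, edges = matrix(character(0), 0, 2),
                       nodes = NULL) {
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("parent", "child")))
  if (is.null(nodes)) nodes <- unique(c(root, as.vector(edges)))
  new("DiseaseDAG", root = root, nodes = nodes, edges = edges)
}

#' @rdname DiseaseDAG-class
#' @param x,object a `DiseaseDAG`.
#' @export
dagRoot <- function(x) x@root

#' @rdname DiseaseDAG-class
#' @export
dagNodes <- function(x) x@nodes

#' @rdname DiseaseDAG-class
#' @export
dagEdges <- function(x) x@edges

setMethod("show", "DiseaseDAG", function(object) {
  cat("DiseaseDAG of '", object@root, "': ", length(object@nodes),
      " node(s), ", nrow(object@edges), " edge(s)\n", sep = "")
})

#' @rdname IsomerCatalog-class
#' @param x,object an `IsomerCatalog`.
#' @export
graphlets <- function(x) x@graphlets

#' @rdname IsomerCatalog-class
#' @export
orbits <- function(x) x@orbits

#' @rdname IsomerCatalog-class
#' @export
isomers <- function(x) x@isomers

#' @rdname IsomerCatalog-class
#' @export
nIsomers <- function(x) length(x@isomers)

setMethod("show", "IsomerCatalog", function(object) {
  cat("IsomerCatalog:", length(object@graphlets), "graphlets,",
      nrow(object@orbits), "automorphism orbits,",
      length(object@isomers), "interaction isomers\n")
})

#' @rdname IsomerCountTensor-class
#' @param x,object an `IsomerCountTensor`.
#' @export
isomerCounts <- function(x) x@counts

#' @rdname IsomerCountTensor-class
#' @export
normalizedCounts <- function(x) {
  if (length(x@normalized) == 0)
    stop("tensor has not been normalized; call normalizeCounts() first")
  x@normalized
}

setMethod("show", "IsomerCountTensor", function(object) {
  cat("IsomerCountTensor:", dim(object@counts)[1], "isomers x",
      dim(object@counts)[2], "nodes",
      if (length(object@normalized)) "(normalized)" else "(raw)", "\n")
})

#' @rdname GimdaResult-class
#' @param x,object a `GimdaResult`.
#' @export
gimdaScores <- function(x) x@scores

#' @rdname GimdaResult-class
#' @param side "mirna" or "disease".
#' @export
isomerWeights <- function(x, side = c("mirna", "disease")) {
  side <- match.arg(side)
  if (side == "mirna") x@weightsMirna else x@weightsDisease
}

#' @rdname GimdaResult-class
#' @export
knownMask <- function(x) x@known

setMethod("show", "GimdaResult", function(object) {
  cat("GimdaResult:", nrow(object@scores), "diseases x",
      ncol(object@scores), "miRNAs; lambda =", object@lambda, "\n")
  cat("  score range:", signif(min(object@scores), 4), "..",
      signif(max(object@scores), 4), "\n")
})

#' @rdname CVResult-class
#' @param x,object a `CVResult`.
#' @export
cvAuc <- function(x) x@auc

#' @rdname CVResult-class
#' @export
rocPoints <- function(x) x@roc

setMethod("show", "CVResult", function(object) {
  cat("CVResult [", object@mode,
      if (!is.na(object@k)) paste0(", k = ", object@k), "]: AUC = ",
      signif(object@auc, 4),
      if (!is.na(object@aucSd)) paste0(" +/- ", signif(object@aucSd, 4)),
      " (", length(object@ranks), " test samples)\n", sep = "")
})
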