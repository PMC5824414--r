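#' @import methods
NULL

#' Binary disease x miRNA association matrix
#'
#' Wraps the known-association adjacency matrix A: rows are diseases,
#' columns are miRNAs, A[i, j] = 1 iff disease i and miRNA j have an
#' experimentally confirmed association. Row and column names are the
#' entity ID registries; all other matrices in a GIMDA run are aligned
#' to them.
#'
#' @slot assoc numeric matrix with entries in {0, 1}; rownames are
#'   disease IDs, colnames are miRNA IDs, both unique.
#' @export
setClass("AssociationMatrix", representation(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  a <- object@assoc
  msg <- character(0)
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "assoc must have disease rownames and miRNA colnames")
  else {
    if (anyDuplicated(rownames(a))) msg <- c(msg, "duplicate disease IDs")
    if (anyDuplicated(colnames(a))) msg <- c(msg, "duplicate miRNA IDs")
  }
  if (!all(a %in% c(0, 1))) msg <- c(msg, "assoc entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Symmetric similarity matrix for one entity class
#'
#' Square symmetric matrix of pairwise similarities among diseases or
#' among miRNAs, values in [0, 1]. The `kind` slot records which of the
#' similarity constructions produced it.
#'
#' @slot values numeric square matrix, symmetric, entries in [0, 1],
#'   with identical row and column names (the entity IDs).
#' @slot kind character; one of "semantic1", "semantic2", "gip_disease",
#'   "gip_mirna", "functional", "integrated_disease", "integrated_mirna".
#' @export
setClass("SimilarityMatrix",
         representation(values = "matrix", kind = "character"))

.sim_kinds <- c("semantic1", "semantic2", "gip_disease", "gip_mirna",
                "functional", "integrated_disease", "integrated_mirna")

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column names must be identical entity IDs")
  if (nrow(v) > 0 && max(abs(v - t(v))) > 1e-9)
    msg <- c(msg, "values must be symmetric within 1e-9")
  if (any(v < -1e-12 | v > 1 + 1e-12))
    msg <- c(msg, "values must lie in [0, 1]")
  if (length(object@kind) != 1L || !(object@kind %in% .sim_kinds))
    msg <- c(msg, paste("kind must be one of:", paste(.sim_kinds, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-disease ancestor DAG
#'
#' MeSH-style directed acyclic graph of a disease: the disease itself
#' plus its ancestor terms, with edges from parents to children. Every
#' node has a directed path down to the root disease.
#'
#' @slot root character(1), the disease the DAG describes.
#' @slot nodes character, all terms in the DAG (includes `root`).
#' @slot edges character matrix with columns "parent", "child"; may have
#'   zero rows (singleton DAG).
#' @export
setClass("DiseaseDAG",
         representation(root = "character", nodes = "character",
                        edges = "matrix"))

setValidity("DiseaseDAG", function(object) {
  msg <- character(0)
  if (length(object@root) != 1L) msg <- c(msg, "root must be a single label")
  if (!(object@root %in% object@nodes)) msg <- c(msg, "root must be a node")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  else if (nrow(e) > 0) {
    if (!all(e %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (.dagHasCycle(object@nodes, e))
      msg <- c(msg, "edges contain a cycle")
    else if (!all(.dagReaches(object@nodes, e, object@root)))
      msg <- c(msg, "every node must have a directed path to the root disease")
  }
  if (length(msg)) msg else TRUE
})

#' Catalog of graphlets, automorphism orbits and interaction isomers
#'
#' Exhaustive enumeration of the connected non-isomorphic undirected
#' graphs on 2-4 nodes (9 graphlets), their automorphism orbits (15),
#' and the ordered orbit-pair interaction templates between two nodes of
#' one graphlet (28 isomers; exchanging the two nodes gives a different
#' isomer).
#'
#' @slot graphlets list of 0/1 adjacency matrices in canonical form.
#' @slot orbits data.frame with columns orbit, graphlet, node (a
#'   representative node position) and degree.
#' @slot isomers list of templates; each has elements graphlet, size,
#'   adj (adjacency over slots: slot 1 = source, slot 2 = target,
#'   remaining slots auxiliary), sourceOrbit, targetOrbit, symmetry
#'   (size of the automorphism stabilizer of the ordered (source,
#'   target) pair) and label.
#' @export
setClass("IsomerCatalog",
         representation(graphlets = "list", orbits = "data.frame",
                        isomers = "list"))

#' Weighted graphlet-interaction isomer counts
#'
#' 3-d array of isomer counts N[k, i, j]: the weighted number of
#' occurrences of interaction isomer k from node i to node j of a
#' weighted similarity graph, optionally row-normalized over targets.
#'
#' @slot counts numeric array (isomers x nodes x nodes); self pairs are 0.
#' @slot normalized numeric array of the same shape (each source row
#'   divided by its total over targets; all-zero rows stay zero), or an
#'   empty array if normalization has not been applied.
#' @slot ids character, node IDs.
#' @export
setClass("IsomerCountTensor",
         representation(counts = "array", normalized = "array",
                        ids = "character"))

setValidity("IsomerCountTensor", function(object) {
  d <- dim(object@counts)
  msg <- character(0)
  if (length(d) != 3L || d[2] != d[3])
    msg <- c(msg, "counts must be an isomer x node x node array")
  else if (d[2] != length(object@ids))
    msg <- c(msg, "ids must match the node dimension")
  if (any(object@counts < -1e-9)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Fitted GIMDA model and prediction scores
#'
#' Holds the per-graph score matrices (miRNA graph and disease graph),
#' their average (the final association score), the two fitted 28-long
#' isomer weight vectors, and the known-association mask.
#'
#' @slot scores numeric matrix (diseases x miRNAs), the combined score.
#' @slot scoresMirna,scoresDisease numeric matrices, per-graph scores.
#' @slot weightsMirna,weightsDisease numeric vectors (one weight per
#'   interaction isomer).
#' @slot known logical matrix flagging the training associations.
#' @slot lambda numeric(1), ridge regularizer used in the fit.
#' @export
setClass("GimdaResult",
         representation(scores = "matrix", scoresMirna = "matrix",
                        scoresDisease = "matrix", weightsMirna = "numeric",
                        weightsDisease = "numeric", known = "matrix",
                        lambda = "numeric"))

setValidity("GimdaResult", function(object) {
  msg <- character(0)
  dm <- dim(object@scores)
  if (!identical(dm, dim(object@scoresMirna)) ||
      !identical(dm, dim(object@scoresDisease)) ||
      !identical(dm, dim(object@known)))
    msg <- c(msg, "all score matrices and the known mask must share a shape")
  else if (max(abs(object@scores -
                   (object@scoresMirna + object@scoresDisease) / 2)) > 1e-9)
    msg <- c(msg, "scores must equal (scoresMirna + scoresDisease) / 2")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' @slot mode character(1): "global_loocv", "local_loocv" or "kfold".
#' @slot k integer(1), fold count (NA for LOOCV).
#' @slot auc numeric(1), (mean) area under the ROC curve.
#' @slot aucSd numeric(1), SD over repeats (NA when repeats == 1 or LOOCV).
#' @slot aucs numeric, per-repeat AUCs.
#' @slot ranks numeric, per-test-sample percentile ranks in [0, 1].
#' @slot roc data.frame with columns fpr, tpr.
#' @slot repeats integer(1).
#' @export
setClass("CVResult",
         representation(mode = "character", k = "integer", auc = "numeric",
                        aucSd = "numeric", aucs = "numeric", ranks = "numeric",
                        roc = "data.frame", repeats = "integer"))

setValidity("CVResult", function(object) {
  msg <- character(0)
  if (!(object@mode %in% c("global_loocv", "local_loocv", "kfold")))
    msg <- c(msg, "unknown mode")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must lie in [0, 1]")
  r <- object@roc
  if (nrow(r) > 0) {
    if (!all(c("fpr", "tpr") %in% names(r)))
      msg <- c(msg, "roc must have fpr and tpr columns")
    else if (is.unsorted(r$fpr) || is.unsorted(r$tpr))
      msg <- c(msg, "roc must be monotone nondecreasing")
  }
  if (length(msg)) msg else TRUE
})
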