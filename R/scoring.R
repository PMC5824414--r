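# Feature assembly, isomer-weight regression and association scoring.

#' Graphlet-interaction feature matrix
#'
#' For the miRNA side, the feature column of candidate pair (d(i),
#' m(j)) holds, for each isomer k, the sum over the miRNAs p already
#' known for disease i of the normalized isomer-k count from p to j in
#' the miRNA similarity graph. The disease side is symmetric, summing
#' over the diseases known for miRNA j. A pair whose partner set is
#' empty yields a zero column.
#'
#' @param tensor a normalized \linkS4class{IsomerCountTensor} built on
#'   the similarity graph matching `side`.
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param side "mirna" (graph over miRNAs, partner sets P(i)) or
#'   "disease" (graph over diseases, partner sets Q(j)).
#' @return list with `features` (isomers x pairs matrix, pairs in
#'   column-major disease x miRNA order) and `pairIndex` (data.frame of
#'   disease, mirna).
#' @export
buildFeatureMatrix <- function(tensor, assoc, side = c("mirna", "disease")) {
  side <- match.arg(side)
  a <- assocMatrix(assoc)
  norm <- normalizedCounts(tensor)
  nk <- dim(norm)[1]
  expect <- if (side == "mirna") mirnaIds(assoc) else diseaseIds(assoc)
  if (!identical(tensor@ids, expect))
    stop("tensor IDs do not match the association ", side, " registry")
  feats <- matrix(0, nk, nrow(a) * ncol(a))
  for (k in seq_len(nk)) {
    nk_mat <- norm[k, , , drop = TRUE]
    f <- if (side == "mirna") a %*% nk_mat else t(nk_mat) %*% a
    feats[k, ] <- as.vector(f)
  }
  list(features = feats,
       pairIndex = data.frame(
         disease = rep(diseaseIds(assoc), times = ncol(a)),
         mirna = rep(mirnaIds(assoc), each = nrow(a))))
}

#' Fit isomer weights by (ridge) linear regression
#'
#' Closed-form normal-equation fit of the per-isomer weights: V =
#' (X X^T + lambda I)^(-1) X s, where X is the feature matrix (one row
#' per isomer, one column per training pair) and s the training labels.
#' With lambda = 0 and a full-rank system this is the exact unpenalized
#' least-squares solution.
#'
#' @param features isomers x pairs numeric matrix (the `features`
#'   element of [buildFeatureMatrix()]).
#' @param labels numeric vector aligned with the feature columns
#'   (binary association labels when training on known associations).
#' @param lambda ridge regularizer, >= 0 (default 1e-6; the normal
#'   equations are frequently singular on small graphs).
#' @return numeric weight vector, one entry per isomer.
#' @export
fitWeights <- function(features, labels, lambda = 1e-6) {
  stopifnot(ncol(features) == length(labels), lambda >= 0)
  g <- tcrossprod(features) + diag(lambda, nrow(features))
  rhs <- features %*% labels
  v <- tryCatch(solve(g, rhs), error = function(e)
    stop("normal equations are singular at lambda = ", lambda,
         "; refit with lambda > 0", call. = FALSE))
  as.numeric(v)
}

#' Combine per-graph scores
#'
#' The final association score is the average of the miRNA-graph and
#' disease-graph scores.
#'
#' @param sm,sd numeric scalars/matrices of per-graph scores.
#' @return their elementwise average.
#' @export
combineScores <- function(sm, sd) (sm + sd) / 2

#' Fit GIMDA and score every disease-miRNA pair
#'
#' Assembles the two feature matrices from the normalized isomer count
#' tensors of the miRNA and disease similarity graphs, fits one global
#' 28-long weight vector per graph against the known-association
#' labels, and scores all pairs; the final score is the average of the
#' two per-graph scores. For a new disease (empty P(i)) the miRNA-graph
#' side is zero and the within-disease ranking is driven entirely by
#' the disease graph (and symmetrically for new miRNAs).
#'
#' @param assoc an \linkS4class{AssociationMatrix} (training data).
#' @param smTensor,sdTensor normalized \linkS4class{IsomerCountTensor}s
#'   of the integrated miRNA and disease similarity graphs.
#' @param lambda ridge regularizer passed to [fitWeights()].
#' @return a \linkS4class{GimdaResult}.
#' @export
gimdaFit <- function(assoc, smTensor, sdTensor, lambda = 1e-6) {
  a <- assocMatrix(assoc)
  fm <- buildFeatureMatrix(smTensor, assoc, "mirna")
  fd <- buildFeatureMatrix(sdTensor, assoc, "disease")
  labels <- as.vector(a)
  vm <- fitWeights(fm$features, labels, lambda)
  vd <- fitWeights(fd$features, labels, lambda)
  sm <- matrix(crossprod(fm$features, vm), nrow(a), ncol(a),
               dimnames = dimnames(a))
  sd <- matrix(crossprod(fd$features, vd), nrow(a), ncol(a),
               dimnames = dimnames(a))
  new("GimdaResult", scores = combineScores(sm, sd), scoresMirna = sm,
      scoresDisease = sd, weightsMirna = vm, weightsDisease = vd,
      known = a == 1, lambda = lambda)
}

#' Rank candidate miRNAs for a disease
#'
#' Returns the miRNAs without a known association to the disease,
#' ordered by descending predicted score; ties are broken
#' lexicographically by miRNA ID so the ordering is deterministic.
#'
#' @param result a \linkS4class{GimdaResult}.
#' @param disease a disease ID present in the result.
#' @param n optional cap on the number of candidates returned.
#' @return data.frame with columns mirna and score.
#' @export
rankCandidates <- function(result, disease, n = NULL) {
  s <- gimdaScores(result)
  if (!disease %in% rownames(s)) stop("unknown disease: ", disease)
  cand <- !knownMask(result)[disease, ]
  df <- data.frame(mirna = colnames(s)[cand], score = s[disease, cand])
  df <- df[order(-df$score, df$mirna), ]
  rownames(df) <- NULL
  if (!is.null(n)) df <- utils::head(df, n)
  df
}
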