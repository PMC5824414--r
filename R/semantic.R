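#' Disease semantic value, model 1
#'
#' Contribution of each ancestor term to a disease's semantic value
#' under exponential decay: the disease itself contributes 1, and any
#' other term contributes `delta` times the largest contribution among
#' its children, i.e. delta^(shortest directed path length down to the
#' disease). The semantic value DV1 is the sum of all contributions.
#'
#' @param dag a \linkS4class{DiseaseDAG}.
#' @param delta semantic contribution decay factor in (0, 1).
#' @return list with elements `contributions` (named numeric over DAG
#'   nodes) and `value` (DV1).
#' @export
semanticValue1 <- function(dag, delta = 0.5) {
  stopifnot(delta > 0, delta < 1)
  kids <- .dagChildren(dag)
  contrib <- stats::setNames(rep(NA_real_, length(dag@nodes)), dag@nodes)
  contrib[dag@root] <- 1
  # sweep to fixpoint; DAG depth bounds the number of useful sweeps
  repeat {
    progressed <- FALSE
    for (v in dag@nodes[is.na(contrib)]) {
      ck <- contrib[kids[[v]]]
      if (length(ck) && !anyNA(ck)) {
        contrib[v] <- delta * max(ck)
        progressed <- TRUE
      }
    }
    if (!anyNA(contrib)) break
    if (!progressed)
      stop("node(s) with no path to the root disease: ",
           paste(dag@nodes[is.na(contrib)], collapse = ", "))
  }
  list(contributions = contrib, value = sum(contrib))
}

#' Disease semantic similarity, model 1
#'
#' Shared-ancestor similarity: the summed model-1 contributions of the
#' terms common to both DAGs, relative to the two semantic values.
#'
#' @param dagI,dagJ \linkS4class{DiseaseDAG} objects.
#' @param delta semantic contribution decay factor in (0, 1).
#' @return similarity in [0, 1].
#' @export
semanticSimilarity1 <- function(dagI, dagJ, delta = 0.5) {
  svI <- semanticValue1(dagI, delta)
  svJ <- semanticValue1(dagJ, delta)
  shared <- intersect(dagNodes(dagI), dagNodes(dagJ))
  if (length(shared) == 0) return(0)
  sum(svI$contributions[shared] + svJ$contributions[shared]) /
    (svI$value + svJ$value)
}

#' Corpus-frequency term contributions (model 2)
#'
#' Model 2 weights a term by its specificity across the whole DAG
#' corpus: contribution(d) = -log(number of corpus DAGs containing d /
#' number of diseases in the corpus). Terms appearing in every DAG
#' contribute 0; rarer terms contribute more. The choice of logarithm
#' base cancels in the model-2 similarity ratio.
#'
#' @param dagCorpus named list of \linkS4class{DiseaseDAG} objects.
#' @param base logarithm base (default natural log).
#' @return named numeric vector of contributions over all corpus terms.
#' @export
semanticContributions2 <- function(dagCorpus, base = exp(1)) {
  stopifnot(length(dagCorpus) > 0)
  terms <- table(unlist(lapply(dagCorpus, dagNodes)))
  -log(as.numeric(terms) / length(dagCorpus), base = base) |>
    stats::setNames(names(terms))
}

#' Disease semantic value, model 2
#'
#' @param dag a \linkS4class{DiseaseDAG}.
#' @param contributions2 output of [semanticContributions2()].
#' @return list with `contributions` and `value` (DV2).
#' @export
semanticValue2 <- function(dag, contributions2) {
  missing <- setdiff(dagNodes(dag), names(contributions2))
  if (length(missing))
    stop("term(s) absent from the DAG corpus: ",
         paste(missing, collapse = ", "))
  contrib <- contributions2[dagNodes(dag)]
  list(contributions = contrib, value = sum(contrib))
}

#' Disease semantic similarity, model 2
#'
#' Same shared-ancestor ratio as model 1 but with corpus-specificity
#' contributions. Identical DAGs have similarity 1 (returned directly
#' when the ratio is 0/0, i.e. all shared terms occur in every DAG).
#'
#' @param dagI,dagJ \linkS4class{DiseaseDAG} objects.
#' @param dagCorpus named list of all DAGs (both arguments' terms must
#'   appear in it).
#' @return similarity value, clipped to [0, 1] with a warning if a
#'   corpus pathology pushes it above 1.
#' @export
semanticSimilarity2 <- function(dagI, dagJ, dagCorpus) {
  c2 <- semanticContributions2(dagCorpus)
  svI <- semanticValue2(dagI, c2)
  svJ <- semanticValue2(dagJ, c2)
  shared <- intersect(dagNodes(dagI), dagNodes(dagJ))
  if (length(shared) == 0) return(0)
  den <- svI$value + svJ$value
  if (den <= 0) {
    # all terms occur in every corpus DAG; identical DAGs are still
    # maximally similar, any other pair carries no signal
    return(if (setequal(dagNodes(dagI), dagNodes(dagJ))) 1 else 0)
  }
  s <- sum(svI$contributions[shared] + svJ$contributions[shared]) / den
  if (s > 1) {
    warning("model-2 similarity ", signif(s, 4), " clipped to 1")
    s <- 1
  }
  s
}

#' Semantic similarity matrices over a DAG corpus
#'
#' Evaluates both semantic models for every disease pair in the corpus.
#' Diagonals are 1 by definition.
#'
#' @param dagCorpus named list of \linkS4class{DiseaseDAG} objects.
#' @param delta model-1 decay factor.
#' @return list with \linkS4class{SimilarityMatrix} elements `ss1` and
#'   `ss2` (IDs in corpus order).
#' @export
semanticSimilarityMatrices <- function(dagCorpus, delta = 0.5) {
  ids <- names(dagCorpus)
  n <- length(ids)
  sv1 <- lapply(dagCorpus, semanticValue1, delta = delta)
  c2 <- semanticContributions2(dagCorpus)
  sv2 <- lapply(dagCorpus, semanticValue2, contributions2 = c2)
  ss1 <- ss2 <- diag(1, n)
  dimnames(ss1) <- dimnames(ss2) <- list(ids, ids)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- intersect(dagNodes(dagCorpus[[i]]), dagNodes(dagCorpus[[j]]))
    if (length(shared)) {
      ss1[i, j] <- ss1[j, i] <-
        sum(sv1[[i]]$contributions[shared] + sv1[[j]]$contributions[shared]) /
        (sv1[[i]]$value + sv1[[j]]$value)
      den2 <- sv2[[i]]$value + sv2[[j]]$value
      v2 <- if (den2 <= 0) {
        if (setequal(dagNodes(dagCorpus[[i]]), dagNodes(dagCorpus[[j]]))) 1 else 0
      } else {
        min(1, sum(sv2[[i]]$contributions[shared] +
                   sv2[[j]]$contributions[shared]) / den2)
      }
      ss2[i, j] <- ss2[j, i] <- v2
    }
  }
  list(ss1 = SimilarityMatrix(ss1, "semantic1"),
       ss2 = SimilarityMatrix(ss2, "semantic2"))
}
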