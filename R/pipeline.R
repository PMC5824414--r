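#' GIMDA run configuration
#'
#' Bundles the tunable parameters of a run. `delta` is the semantic
#' contribution decay factor, `gammaDPrime`/`gammaMPrime` the original
#' GIP kernel bandwidths for the disease and miRNA sides, `lambda` the
#' ridge regularizer of the weight regression, `minWeight` an optional
#' sparsification threshold on similarity edges (similarities at or
#' below it are treated as absent; default 0 keeps every positive
#' similarity, as no threshold is part of the model).
#'
#' @param delta decay factor in (0, 1), default 0.5.
#' @param gammaDPrime,gammaMPrime original bandwidths > 0, default 1.
#' @param lambda ridge regularizer >= 0, default 1e-6.
#' @param minWeight edge sparsification threshold in [0, 1), default 0.
#' @param seed integer seed recorded for provenance.
#' @return a named list of class "gimdaConfig".
#' @export
gimdaConfig <- function(delta = 0.5, gammaDPrime = 1, gammaMPrime = 1,
                        lambda = 1e-6, minWeight = 0, seed = 1L) {
  stopifnot(delta > 0, delta < 1, gammaDPrime > 0, gammaMPrime > 0,
            lambda >= 0, minWeight >= 0, minWeight < 1)
  structure(list(delta = delta, gammaDPrime = gammaDPrime,
                 gammaMPrime = gammaMPrime, lambda = lambda,
                 minWeight = minWeight, seed = as.integer(seed)),
            class = "gimdaConfig")
}

# similarity matrix -> census edge weights: zero diagonal, optional
# sparsification threshold
.simToWeights <- function(sim, minWeight = 0) {
  w <- simValues(sim)
  diag(w) <- 0
  if (minWeight > 0) w[w <= minWeight] <- 0
  w
}

#' Integrated similarity matrices for a GIMDA run
#'
#' Computes the GIP kernels from the association matrix, the two
#' semantic models from the DAG corpus, and integrates them with the
#' functional similarity into the final disease and miRNA similarity
#' matrices. Diseases without a DAG fall back to the disease GIP
#' kernel; miRNAs absent from the functional similarity matrix fall
#' back to the miRNA GIP kernel. Entities present in the similarity
#' sources but absent from the association matrix are dropped (with a
#' message reporting the count).
#'
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param mirnaSim functional \linkS4class{SimilarityMatrix} over (a
#'   subset of) the miRNAs, or NULL to use the GIP kernel alone.
#' @param dags named list of \linkS4class{DiseaseDAG}s, or NULL to use
#'   the GIP kernel alone.
#' @param config a [gimdaConfig()].
#' @param semantic optional precomputed result of
#'   [semanticSimilarityMatrices()] on `dags` (cache; the semantic
#'   models do not depend on the association matrix).
#' @return list with elements sm, sd (integrated
#'   \linkS4class{SimilarityMatrix}), kd, km, ss1, ss2 and the
#'   semantic cache.
#' @export
gimdaSimilarities <- function(assoc, mirnaSim = NULL, dags = NULL,
                              config = gimdaConfig(), semantic = NULL) {
  a <- assocMatrix(assoc)
  kd <- gipKernel(a, config$gammaDPrime, "gip_disease")
  km <- gipKernel(t(a), config$gammaMPrime, "gip_mirna")
  if (!is.null(dags)) {
    dropped <- setdiff(names(dags), diseaseIds(assoc))
    if (length(dropped))
      message(length(dropped),
              " disease DAG(s) not in the association matrix dropped")
    dags <- dags[intersect(names(dags), diseaseIds(assoc))]
    if (is.null(semantic) && length(dags))
      semantic <- semanticSimilarityMatrices(dags, config$delta)
  }
  if (!is.null(semantic) && !is.null(semantic$ss1)) {
    sd <- integrateDiseaseSimilarity(semantic$ss1, semantic$ss2, kd)
  } else {
    sd <- SimilarityMatrix(simValues(kd), "integrated_disease")
  }
  if (!is.null(mirnaSim)) {
    dropped <- setdiff(simIds(mirnaSim), mirnaIds(assoc))
    if (length(dropped))
      message(length(dropped),
              " similarity miRNA(s) not in the association matrix dropped")
    keep <- intersect(simIds(mirnaSim), mirnaIds(assoc))
    fs <- SimilarityMatrix(simValues(mirnaSim)[keep, keep, drop = FALSE],
                           "functional")
    sm <- integrateMirnaSimilarity(fs, km)
  } else {
    sm <- SimilarityMatrix(simValues(km), "integrated_mirna")
  }
  list(sm = sm, sd = sd, kd = kd, km = km,
       ss1 = semantic$ss1, ss2 = semantic$ss2, semantic = semantic)
}

#' Run the full GIMDA pipeline
#'
#' similarity integration -> weighted isomer census on both graphs ->
#' normalization -> feature assembly -> weight regression -> scores.
#'
#' @inheritParams gimdaSimilarities
#' @param catalog an \linkS4class{IsomerCatalog}; built once and reused
#'   when running repeatedly.
#' @param censusM,censusD optional precomputed normalized count tensors
#'   for the miRNA / disease graphs (exact reuse when the similarity
#'   graphs are unchanged, e.g. across cross-validation folds with full
#'   semantic and functional coverage).
#' @return a \linkS4class{GimdaResult}.
#' @examples
#' w <- generatePlantedWorld(plantedWorldParams(nDiseases = 8, nMirnas = 8,
#'                                              seed = 1))
#' res <- gimdaScore(w$assoc, w$mirnaSim, w$dags)
#' rankCandidates(res, diseaseIds(w$assoc)[1], n = 3)
#' @export
gimdaScore <- function(assoc, mirnaSim = NULL, dags = NULL,
                       config = gimdaConfig(), catalog = buildIsomerCatalog(),
                       semantic = NULL, censusM = NULL, censusD = NULL) {
  sims <- gimdaSimilarities(assoc, mirnaSim, dags, config, semantic)
  if (is.null(censusM))
    censusM <- normalizeCounts(
      countIsomers(.simToWeights(sims$sm, config$minWeight), catalog))
  if (is.null(censusD))
    censusD <- normalizeCounts(
      countIsomers(.simToWeights(sims$sd, config$minWeight), catalog))
  gimdaFit(assoc, censusM, censusD, config$lambda)
}
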