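# Cross-validation machinery: global/local LOOCV, k-fold CV, ROC/AUC.

#' Area under the ROC curve
#'
#' Mann-Whitney statistic scaled to [0, 1] with midrank tie handling:
#' the probability that a random positive scores above a random
#' negative, counting ties one half. Identical score distributions give
#' exactly 0.5.
#'
#' @param positiveScores,negativeScores non-empty numeric vectors.
#' @return AUC in [0, 1].
#' @export
computeAuc <- function(positiveScores, negativeScores) {
  stopifnot(length(positiveScores) > 0, length(negativeScores) > 0)
  r <- rank(c(positiveScores, negativeScores))  # midranks for ties
  np <- length(positiveScores)
  nn <- length(negativeScores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs over all score thresholds, starting at (0, 0) and
#' ending at (1, 1); tied scores collapse into a single point, so the
#' trapezoidal area equals the midrank Mann-Whitney AUC.
#'
#' @inheritParams computeAuc
#' @return data.frame with columns fpr, tpr.
#' @export
rocCurve <- function(positiveScores, negativeScores) {
  scores <- c(positiveScores, negativeScores)
  labels <- rep(c(1, 0), c(length(positiveScores), length(negativeScores)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  keep <- !duplicated(scores, fromLast = TRUE)  # last index of each tie block
  tpr <- cumsum(labels)[keep] / sum(labels)
  fpr <- cumsum(1 - labels)[keep] / sum(1 - labels)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# percentile of a test score within candidate scores, ties counted half
.percentileRank <- function(testScore, candScores) {
  (sum(candScores < testScore) + 0.5 * sum(candScores == testScore)) /
    length(candScores)
}

# rescore the association matrix with one or more positives hidden.
# Exact reuse of census tensors is possible when the similarity graphs
# do not depend on A (full semantic + functional coverage).
.rescoreHolding <- function(assoc, hide, mirnaSim, dags, config, catalog,
                            semantic, censusM, censusD, fastApprox,
                            fullSims) {
  a <- assocMatrix(assoc)
  a[hide] <- 0
  if (sum(a) == 0) stop("holding out these associations empties the matrix")
  trainAssoc <- AssociationMatrix(values = a)
  if (fastApprox) {
    # approximation: reuse full-data similarity graphs (and hence census)
    gimdaFit(trainAssoc, censusM, censusD, config$lambda)
  } else {
    gimdaScore(trainAssoc, mirnaSim, dags, config, catalog,
               semantic = semantic, censusM = censusM, censusD = censusD)
  }
}

# TRUE when SM and SD are A-independent: every miRNA has functional
# similarity and every disease has a DAG
.fullCoverage <- function(assoc, mirnaSim, dags) {
  !is.null(mirnaSim) && !is.null(dags) &&
    all(mirnaIds(assoc) %in% simIds(mirnaSim)) &&
    all(diseaseIds(assoc) %in% names(dags))
}

.cvPrecompute <- function(assoc, mirnaSim, dags, config, catalog, fastApprox) {
  dagsUse <- if (!is.null(dags)) dags[intersect(names(dags),
                                                diseaseIds(assoc))]
  semantic <- if (!is.null(dagsUse) && length(dagsUse))
    semanticSimilarityMatrices(dagsUse, config$delta)
  full <- .fullCoverage(assoc, mirnaSim, dags)
  censusM <- censusD <- NULL
  if (full || fastApprox) {
    sims <- gimdaSimilarities(assoc, mirnaSim, dags, config, semantic)
    censusM <- normalizeCounts(
      countIsomers(.simToWeights(sims$sm, config$minWeight), catalog))
    censusD <- normalizeCounts(
      countIsomers(.simToWeights(sims$sd, config$minWeight), catalog))
  }
  list(semantic = semantic, censusM = censusM, censusD = censusD)
}

#' Leave-one-out cross-validation
#'
#' Each known association is in turn hidden from the training matrix,
#' the model is refitted, and the hidden pair's score is ranked against
#' the candidate pairs: all pairs without a known association (global
#' mode) or the unknown miRNAs of the same disease (local mode). The
#' AUC is the mean percentile rank of the test samples (midrank ties),
#' equivalently the Mann-Whitney statistic of test-vs-candidate
#' comparisons.
#'
#' Hidden associations are removed before the GIP kernels, partner sets
#' and features are computed, so no information leaks from the test
#' pair. When every disease has a DAG and every miRNA has functional
#' similarity, the similarity graphs do not depend on the association
#' matrix and the isomer census is computed once (exact). With
#' `fastApprox = TRUE` the full-data GIP similarities are reused even
#' without full coverage - an approximation of the strict protocol for
#' large inputs.
#'
#' @inheritParams gimdaScore
#' @param mode "global" or "local".
#' @param fastApprox reuse full-data similarities (default FALSE).
#' @return a \linkS4class{CVResult}.
#' @export
gimdaLoocv <- function(assoc, mirnaSim = NULL, dags = NULL,
                       config = gimdaConfig(),
                       catalog = buildIsomerCatalog(),
                       mode = c("global", "local"), fastApprox = FALSE) {
  mode <- match.arg(mode)
  a <- assocMatrix(assoc)
  pos <- which(a == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) stop("need at least 2 known associations")
  pre <- .cvPrecompute(assoc, mirnaSim, dags, config, catalog, fastApprox)
  ranks <- numeric(0)
  testScores <- numeric(0)
  candScoresAll <- list()
  for (t in seq_len(nrow(pos))) {
    i <- pos[t, 1]; j <- pos[t, 2]
    if (mode == "local" && sum(a[i, ] == 0) == 0) {
      warning("disease '", rownames(a)[i],
              "' has no candidate miRNAs in local mode; skipped")
      next
    }
    res <- .rescoreHolding(assoc, cbind(i, j), mirnaSim, dags, config,
                           catalog, pre$semantic, pre$censusM, pre$censusD,
                           fastApprox, NULL)
    s <- gimdaScores(res)
    if (mode == "global") {
      cand <- s[a == 0]
    } else {
      cand <- s[i, a[i, ] == 0]
    }
    ranks <- c(ranks, .percentileRank(s[i, j], cand))
    testScores <- c(testScores, s[i, j])
    candScoresAll[[length(candScoresAll) + 1L]] <- cand
  }
  if (length(ranks) == 0) stop("no testable associations")
  # pooled ROC over percentile ranks: each test sample's rank against a
  # uniform candidate reference
  roc <- rocCurve(ranks, seq(0, 1, length.out = 201))
  new("CVResult", mode = paste0(mode, "_loocv"), k = NA_integer_,
      auc = mean(ranks), aucSd = NA_real_, aucs = mean(ranks),
      ranks = ranks, roc = roc, repeats = 1L)
}

#' Repeated k-fold cross-validation
#'
#' The known associations are partitioned uniformly at random into k
#' near-equal parts; each part is hidden in turn, the model refitted on
#' the rest, and the hidden associations are ranked against all pairs
#' without known associations. Test-sample percentile ranks are pooled
#' over the k folds into one AUC per repeat; the mean and SD over
#' repeats are reported.
#'
#' @inheritParams gimdaLoocv
#' @param k fold count (>= 2, <= number of positives).
#' @param repeats number of random re-partitions (the reference
#'   protocol uses 100; scale down for desk-size experiments).
#' @param seed integer seed for the fold partitions.
#' @return a \linkS4class{CVResult}.
#' @export
gimdaKfoldCv <- function(assoc, mirnaSim = NULL, dags = NULL,
                         config = gimdaConfig(),
                         catalog = buildIsomerCatalog(), k = 5,
                         repeats = 100, seed = 1L, fastApprox = FALSE) {
  a <- assocMatrix(assoc)
  pos <- which(a == 1, arr.ind = TRUE)
  if (k < 2) stop("k must be at least 2")
  if (nrow(pos) < k) stop("k exceeds the number of known associations")
  pre <- .cvPrecompute(assoc, mirnaSim, dags, config, catalog, fastApprox)
  rng <- .seededRng(seed)
  aucs <- numeric(repeats)
  allRanks <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), nrow(pos)))
    ranks <- numeric(0)
    for (f in seq_len(k)) {
      hide <- pos[fold == f, , drop = FALSE]
      res <- .rescoreHolding(assoc, hide, mirnaSim, dags, config, catalog,
                             pre$semantic, pre$censusM, pre$censusD,
                             fastApprox, NULL)
      s <- gimdaScores(res)
      cand <- s[a == 0]
      ranks <- c(ranks, vapply(seq_len(nrow(hide)), function(t)
        .percentileRank(s[hide[t, 1], hide[t, 2]], cand), numeric(1)))
    }
    aucs[r] <- mean(ranks)
    allRanks <- c(allRanks, ranks)
  }
  rng$restore()
  roc <- rocCurve(allRanks, seq(0, 1, length.out = 201))
  new("CVResult", mode = "kfold", k = as.integer(k), auc = mean(aucs),
      aucSd = if (repeats > 1) stats::sd(aucs) else NA_real_, aucs = aucs,
      ranks = allRanks, roc = roc, repeats = as.integer(repeats))
}

# scoped RNG: set a seed, hand back a restore() to reinstate the
# caller's RNG state
.seededRng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}
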