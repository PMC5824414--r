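# Block-structured synthetic benchmark: similarities and associations
# share a latent block assignment, emulating the premise that
# functionally related miRNAs associate with phenotypically similar
# diseases. A fraction of the planted positives is hidden as
# recoverable ground truth.

#' Parameters of a planted benchmark world
#'
#' @param nDiseases,nMirnas entity counts (default 30 x 30).
#' @param nBlocks number of latent blocks shared by both sides
#'   (default 2).
#' @param withinBlockSim,betweenBlockSim expected similarity inside /
#'   across blocks; similarities are Beta-distributed around these
#'   means with concentration 6, i.e. Beta(5, 1) and Beta(1, 5) at the
#'   defaults 5/6 and 1/6.
#' @param assocDensity probability that a block-aligned (disease,
#'   miRNA) pair is a true association at noise 0 (default 0.8). This
#'   density sets the Bayes ceiling of held-out recovery: hidden
#'   positives are statistically indistinguishable from aligned pairs
#'   that were never drawn positive, so with 2 equal blocks no
#'   predictor can exceed AUC = 1 - (1 - rho) / (2 * (2 - rho)). The
#'   default dense regime keeps that ceiling near 1 so the measured
#'   AUC reflects method quality.
#' @param noise in [0, 1]: 0 gives clean block structure; 1 makes
#'   similarities i.i.d. and associations uniform with matching
#'   expected count.
#' @param hiddenFraction fraction of planted positives hidden from the
#'   visible association matrix as ground truth (default 0.2).
#' @param dagDepth,dagBranching shape of the synthetic MeSH-like
#'   ancestor DAGs (default depth 3, branching 2); all DAGs share a
#'   global root and same-block diseases share their ancestor chain.
#' @param seed integer seed; the world is deterministic given it.
#' @return a named parameter list.
#' @export
plantedWorldParams <- function(nDiseases = 30, nMirnas = 30, nBlocks = 2,
                               withinBlockSim = 5 / 6,
                               betweenBlockSim = 1 / 6,
                               assocDensity = 0.8, noise = 0,
                               hiddenFraction = 0.2, dagDepth = 3,
                               dagBranching = 2, seed = 1L) {
  stopifnot(nDiseases > 0, nMirnas > 0, nBlocks > 0,
            nBlocks <= min(nDiseases, nMirnas),
            withinBlockSim > 0, withinBlockSim < 1,
            betweenBlockSim > 0, betweenBlockSim < 1,
            assocDensity > 0, assocDensity <= 1,
            noise >= 0, noise <= 1,
            hiddenFraction >= 0, hiddenFraction < 1, dagDepth >= 0)
  list(nDiseases = nDiseases, nMirnas = nMirnas, nBlocks = nBlocks,
       withinBlockSim = withinBlockSim, betweenBlockSim = betweenBlockSim,
       assocDensity = assocDensity, noise = noise,
       hiddenFraction = hiddenFraction, dagDepth = dagDepth,
       dagBranching = dagBranching, seed = as.integer(seed))
}

# Beta draw with mean m and concentration c, elementwise
.betaAround <- function(n, m, c = 6) stats::rbeta(n, c * m, c * (1 - m))

# symmetric block similarity matrix with unit diagonal
.blockSimilarity <- function(ids, blocks, within, between, noise) {
  n <- length(ids)
  sameBlock <- outer(blocks, blocks, "==")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- upper.tri(m)
  nUt <- sum(ut)
  blockDraw <- ifelse(sameBlock[ut], .betaAround(nUt, within),
                      .betaAround(nUt, between))
  m[ut] <- (1 - noise) * blockDraw + noise * stats::runif(nUt)
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Generate a random MeSH-like DAG corpus
#'
#' Builds a random rooted category tree (global root, `branching`
#' children per internal node, `depth` levels) and attaches each
#' disease as a leaf under a chain of the tree; the disease's DAG is
#' its ancestor chain up to the global root. Diseases attached under
#' the same chain share ancestor prefixes, so semantic similarity
#' reflects the attachment. With `blocks` given, same-block diseases
#' attach under the same branch (up to `noise` random reassignment).
#'
#' @param diseaseIds character vector of disease labels.
#' @param depth number of ancestor terms above each disease: 0 gives
#'   singleton DAGs, 1 only the shared global root, and larger values
#'   add a block-specific chain below the root.
#' @param branching children per internal tree node.
#' @param blocks optional integer block assignment per disease.
#' @param noise probability of attaching a disease under a random
#'   branch instead of its block's branch.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return named list of \linkS4class{DiseaseDAG} objects.
#' @export
generateRandomDagCorpus <- function(diseaseIds, depth = 3, branching = 2,
                                    blocks = NULL, noise = 0, seed = NULL) {
  if (!is.null(seed)) {
    rng <- .seededRng(seed)
    on.exit(rng$restore())
  }
  nBranches <- max(branching, if (is.null(blocks)) 1 else max(blocks))
  dags <- list()
  for (d in seq_along(diseaseIds)) {
    branch <- if (!is.null(blocks) && stats::runif(1) >= noise)
      blocks[d] else sample.int(nBranches, 1)
    chain <- c(if (depth >= 1) "root",
               if (depth >= 2)
                 paste0("b", branch, "_l", seq_len(depth - 1)),
               diseaseIds[d])
    edges <- if (length(chain) > 1)
      cbind(parent = chain[-length(chain)], child = chain[-1])
    else matrix(character(0), 0, 2)
    dags[[diseaseIds[d]]] <- DiseaseDAG(root = diseaseIds[d], edges = edges)
  }
  dags
}

#' Generate a planted benchmark world
#'
#' Draws block-structured miRNA and disease similarities, a
#' block-aligned binary association matrix, and a block-consistent DAG
#' corpus, then hides a fraction of the positives as recoverable
#' ground truth. Deterministic given the seed in `params`.
#'
#' @param params a [plantedWorldParams()] list.
#' @return list with elements `assoc` (visible
#'   \linkS4class{AssociationMatrix}), `mirnaSim` and `diseaseSim`
#'   (\linkS4class{SimilarityMatrix}), `dags`, `truth` (two-column
#'   matrix of hidden disease/miRNA ID pairs), `diseaseBlocks`,
#'   `mirnaBlocks` and `params`.
#' @export
generatePlantedWorld <- function(params = plantedWorldParams()) {
  p <- params
  rng <- .seededRng(p$seed)
  on.exit(rng$restore())
  dids <- sprintf("d%03d", seq_len(p$nDiseases))
  mids <- sprintf("m%03d", seq_len(p$nMirnas))
  dBlocks <- rep_len(seq_len(p$nBlocks), p$nDiseases)
  mBlocks <- rep_len(seq_len(p$nBlocks), p$nMirnas)

  mirnaSim <- SimilarityMatrix(
    .blockSimilarity(mids, mBlocks, p$withinBlockSim, p$betweenBlockSim,
                     p$noise), "functional")
  diseaseSim <- SimilarityMatrix(
    .blockSimilarity(dids, dBlocks, p$withinBlockSim, p$betweenBlockSim,
                     p$noise), "integrated_disease")

  aligned <- outer(dBlocks, mBlocks, "==")
  prob <- p$assocDensity *
    ((1 - p$noise) * aligned + p$noise / p$nBlocks)
  a <- matrix(stats::rbinom(length(prob), 1, prob), nrow(prob),
              dimnames = list(dids, mids))
  # guarantee a connected training problem: at least one association
  # per disease and per miRNA in the visible matrix
  for (i in which(rowSums(a) == 0)) {
    cand <- which(mBlocks == dBlocks[i])
    a[i, cand[sample.int(length(cand), 1)]] <- 1
  }
  for (j in which(colSums(a) == 0)) {
    cand <- which(dBlocks == mBlocks[j])
    a[cand[sample.int(length(cand), 1)], j] <- 1
  }

  pos <- which(a == 1, arr.ind = TRUE)
  # hide only positives that leave their disease and miRNA with at
  # least one other known association
  hideable <- pos[rowSums(a)[pos[, 1]] > 1 & colSums(a)[pos[, 2]] > 1, ,
                  drop = FALSE]
  nHide <- floor(p$hiddenFraction * nrow(pos))
  nHide <- min(nHide, nrow(hideable))
  truth <- matrix(character(0), 0, 2,
                  dimnames = list(NULL, c("disease", "mirna")))
  if (nHide > 0) {
    sel <- hideable[sample.int(nrow(hideable), nHide), , drop = FALSE]
    a[sel] <- 0
    truth <- cbind(disease = dids[sel[, 1]], mirna = mids[sel[, 2]])
  }

  dags <- generateRandomDagCorpus(dids, depth = p$dagDepth,
                                  branching = p$dagBranching,
                                  blocks = dBlocks, noise = p$noise)
  list(assoc = AssociationMatrix(values = a), mirnaSim = mirnaSim,
       diseaseSim = diseaseSim, dags = dags, truth = truth,
       diseaseBlocks = dBlocks, mirnaBlocks = mBlocks, params = p)
}

#' Write a planted world to disk
#'
#' Emits the association TSV, miRNA similarity TSV, DAG TSV and hidden
#' truth TSV in the formats the readers expect.
#'
#' @param world output of [generatePlantedWorld()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writePlantedWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAssociations(world$assoc, file.path(dir, "associations.tsv"))
  writeSimilarityMatrix(world$mirnaSim, file.path(dir, "mirna_similarity.tsv"))
  rows <- do.call(rbind, lapply(world$dags, function(dag) {
    e <- dagEdges(dag)
    if (nrow(e) == 0) cbind(dagRoot(dag), "", "")
    else cbind(dagRoot(dag), e[, 1], e[, 2])
  }))
  utils::write.table(rows, file.path(dir, "disease_dags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(world$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Score the hidden positives of a planted world
#'
#' Runs the full pipeline on the visible association matrix and
#' computes the AUC of the hidden planted positives against all
#' remaining unknown pairs.
#'
#' @param world output of [generatePlantedWorld()].
#' @param config a [gimdaConfig()].
#' @param catalog an \linkS4class{IsomerCatalog}.
#' @return list with `auc` and the fitted \linkS4class{GimdaResult}.
#' @export
evaluatePlantedWorld <- function(world, config = gimdaConfig(),
                                 catalog = buildIsomerCatalog()) {
  if (nrow(world$truth) == 0) stop("world has no hidden truth to recover")
  res <- gimdaScore(world$assoc, world$mirnaSim, world$dags, config, catalog)
  s <- gimdaScores(res)
  a <- assocMatrix(world$assoc)
  truthIdx <- cbind(match(world$truth[, 1], rownames(s)),
                    match(world$truth[, 2], colnames(s)))
  isTruth <- matrix(FALSE, nrow(s), ncol(s))
  isTruth[truthIdx] <- TRUE
  posScores <- s[isTruth]
  negScores <- s[a == 0 & !isTruth]
  list(auc = computeAuc(posScores, negScores), result = res)
}
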