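#' Gaussian interaction-profile kernel similarity
#'
#' Each row of `profiles` is an entity's binary interaction profile (a
#' row of A for diseases, a column of A for miRNAs). The kernel
#' bandwidth is the supplied original bandwidth normalized by the mean
#' squared profile norm, and the similarity between entities i and j is
#' exp(-gamma * ||IP(i) - IP(j)||^2).
#'
#' @param profiles numeric matrix, one profile per row, rownames = IDs.
#' @param gammaPrime original bandwidth (> 0), default 1.
#' @param kind similarity kind recorded on the result (default
#'   "gip_disease").
#' @return a \linkS4class{SimilarityMatrix}; symmetric, unit diagonal,
#'   positive semi-definite.
#' @examples
#' p <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), NULL))
#' simValues(gipKernel(p))[1, 2]  # exp(-2)
#' @export
gipKernel <- function(profiles, gammaPrime = 1, kind = "gip_disease") {
  stopifnot(gammaPrime > 0, nrow(profiles) >= 1)
  norms2 <- rowSums(profiles^2)
  meanNorm2 <- mean(norms2)
  if (meanNorm2 == 0)
    stop("bandwidth undefined: all interaction profiles are zero")
  gamma <- gammaPrime / meanNorm2
  d2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numerical noise from the cross product
  k <- exp(-gamma * d2)
  diag(k) <- 1
  k <- (k + t(k)) / 2
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  SimilarityMatrix(k, kind = kind)
}

#' Integrated disease similarity
#'
#' For a disease pair where both members have a semantic similarity
#' (i.e. both own a DAG in the corpus), the integrated similarity is the
#' average of the two semantic models; otherwise it falls back to the
#' interaction-profile kernel value.
#'
#' @param ss1,ss2 semantic \linkS4class{SimilarityMatrix} objects
#'   (model 1 and 2), indexed by the diseases that own DAGs.
#' @param kd GIP kernel \linkS4class{SimilarityMatrix} over all diseases
#'   (defines the output ID order).
#' @param hasSemantic logical vector aligned with `kd` IDs; defaults to
#'   membership in `ss1`.
#' @return integrated \linkS4class{SimilarityMatrix}.
#' @export
integrateDiseaseSimilarity <- function(ss1, ss2, kd, hasSemantic = NULL) {
  ids <- simIds(kd)
  if (is.null(hasSemantic)) hasSemantic <- ids %in% simIds(ss1)
  stopifnot(length(hasSemantic) == length(ids),
            identical(simIds(ss1), simIds(ss2)))
  sd <- simValues(kd)
  both <- outer(hasSemantic, hasSemantic, "&")
  if (any(hasSemantic)) {
    sub <- ids[hasSemantic]
    sem <- (simValues(ss1)[sub, sub, drop = FALSE] +
            simValues(ss2)[sub, sub, drop = FALSE]) / 2
    sd[both] <- sem[cbind(match(ids[row(sd)[both]], sub),
                          match(ids[col(sd)[both]], sub))]
  }
  diag(sd) <- 1
  SimilarityMatrix(sd, "integrated_disease")
}

#' Integrated miRNA similarity
#'
#' Functional similarity where both miRNAs appear in the functional
#' similarity matrix, GIP kernel similarity otherwise.
#'
#' @param fs functional \linkS4class{SimilarityMatrix} (may cover a
#'   subset of the miRNAs).
#' @param km GIP kernel \linkS4class{SimilarityMatrix} over all miRNAs
#'   (defines the output ID order).
#' @param hasFunctional logical vector aligned with `km` IDs; defaults
#'   to membership in `fs`.
#' @return integrated \linkS4class{SimilarityMatrix}.
#' @export
integrateMirnaSimilarity <- function(fs, km, hasFunctional = NULL) {
  ids <- simIds(km)
  if (is.null(hasFunctional)) hasFunctional <- ids %in% simIds(fs)
  stopifnot(length(hasFunctional) == length(ids))
  sm <- simValues(km)
  both <- outer(hasFunctional, hasFunctional, "&")
  if (any(hasFunctional)) {
    sub <- ids[hasFunctional]
    f <- simValues(fs)[sub, sub, drop = FALSE]
    sm[both] <- f[cbind(match(ids[row(sm)[both]], sub),
                        match(ids[col(sm)[both]], sub))]
  }
  diag(sm) <- 1
  SimilarityMatrix(sm, "integrated_mirna")
}
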