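# Weighted graphlet-interaction isomer census.
#
# For template k and ordered node pair (i, j), the count is
#   N_ij(I_k) = (1 / sym_k) * sum over ordered tuples of distinct
#               auxiliary nodes (all != i, j) of the product over every
#               slot pair (s, t) of b_st,
# with b_st = a_st where the template has an edge and 1 - a_st where it
# does not (induced semantics: every pair among the participating slots
# carries a factor). sym_k is the automorphism stabilizer of the
# ordered (source, target) pair, so each unordered auxiliary
# configuration is counted once and unit-weight counts are integers.

.checkCensusWeights <- function(weights) {
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-9) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
}

# slot-pair factor matrices for a template: E[[s]][[t]] over nodes
.slotPairMatrix <- function(weights, tplAdj, s, t) {
  if (tplAdj[s, t] == 1) weights else 1 - weights
}

# fast census of one template over all ordered node pairs
.censusTemplate <- function(weights, tpl) {
  n <- nrow(weights)
  adj <- tpl$adj
  E12 <- .slotPairMatrix(weights, adj, 1, 2)
  if (tpl$size == 2) {
    N <- E12
    diag(N) <- 0
    return(N / tpl$symmetry)
  }
  E13 <- .slotPairMatrix(weights, adj, 1, 3)
  E23 <- .slotPairMatrix(weights, adj, 2, 3)
  if (tpl$size == 3) {
    C <- tcrossprod(E13, E23)                      # sum_l E13[i,l] E23[j,l]
    C <- C - matrix(diag(E13), n, n) * t(E23)      # drop l = i
    C <- C - E13 * matrix(diag(E23), n, n, byrow = TRUE)  # drop l = j
    N <- E12 * C
    diag(N) <- 0
    return(N / tpl$symmetry)
  }
  E14 <- .slotPairMatrix(weights, adj, 1, 4)
  E24 <- .slotPairMatrix(weights, adj, 2, 4)
  E34 <- .slotPairMatrix(weights, adj, 3, 4)
  N <- matrix(0, n, n)
  d14 <- diag(E14)
  d24 <- diag(E24)
  for (l in seq_len(n)) {
    w <- E34[l, ]
    # S[i,j] = sum_m E14[i,m] w[m] E24[j,m], m over all nodes ...
    S <- tcrossprod(E14 * matrix(w, n, n, byrow = TRUE), E24)
    # ... minus m = i, m = j and m = l
    S <- S - matrix(d14 * w, n, n) * t(E24)
    S <- S - E14 * matrix(w * d24, n, n, byrow = TRUE)
    S <- S - w[l] * outer(E14[, l], E24[, l])
    contrib <- E12 * outer(E13[, l], E23[, l]) * S
    contrib[l, ] <- 0
    contrib[, l] <- 0
    N <- N + contrib
  }
  diag(N) <- 0
  N / tpl$symmetry
}

#' Weighted graphlet-interaction isomer census
#'
#' Counts, for every ordered node pair (i, j) of a weighted similarity
#' graph, the weighted number of occurrences of each interaction isomer
#' in the catalog. Edge weights contribute their similarity value,
#' template non-edges contribute one minus it; with 0/1 weights the
#' counts are classical induced-subgraph occurrence counts. Self pairs
#' are stored as 0. The fast path contracts per-template products of
#' weight matrices (one matrix product per auxiliary node), so its cost
#' is O(templates * n) matrix multiplications.
#'
#' @param weights symmetric numeric matrix in [0, 1] with zero diagonal
#'   (a similarity matrix with self-similarities removed).
#' @param catalog an \linkS4class{IsomerCatalog} from
#'   [buildIsomerCatalog()].
#' @return an \linkS4class{IsomerCountTensor} (not yet normalized).
#' @export
countIsomers <- function(weights, catalog = buildIsomerCatalog()) {
  .checkCensusWeights(weights)
  n <- nrow(weights)
  tensor <- array(0, c(nIsomers(catalog), n, n))
  for (k in seq_len(nIsomers(catalog)))
    tensor[k, , ] <- .censusTemplate(weights, isomers(catalog)[[k]])
  tensor[tensor < 0 & tensor > -1e-12] <- 0  # clip tiny negative round-off
  new("IsomerCountTensor", counts = tensor,
      normalized = array(0, c(0, 0, 0)),
      ids = rownames(weights) %||% as.character(seq_len(n)))
}

#' Brute-force isomer census oracle
#'
#' Independent verification path for the weighted census: enumerates
#' every ordered tuple of distinct auxiliary nodes explicitly and
#' multiplies the slot-pair factors directly, with no algebraic
#' shortcuts. The (source, target) stabilizer used for symmetry
#' division is recomputed here by brute-force permutation enumeration
#' of the template, independently of the catalog's stored factor.
#' Guarded to at most 15 nodes.
#'
#' @inheritParams countIsomers
#' @return an \linkS4class{IsomerCountTensor}.
#' @export
countIsomersOracle <- function(weights, catalog = buildIsomerCatalog()) {
  .checkCensusWeights(weights)
  n <- nrow(weights)
  if (n > 15) stop("oracle is limited to 15 nodes")
  tensor <- array(0, c(nIsomers(catalog), n, n))
  for (k in seq_len(nIsomers(catalog))) {
    tpl <- isomers(catalog)[[k]]
    adj <- tpl$adj
    sz <- tpl$size
    # stabilizer of slots (1, 2), recomputed from scratch
    perms <- .allPerms(sz)
    stab <- sum(apply(perms, 1, function(p)
      p[1] == 1 && p[2] == 2 && identical(adj[p, p], adj)))
    # factor between node u and a vector of nodes v under slot pair (s, t)
    b <- function(u, v, s, t)
      if (adj[s, t] == 1) weights[u, v] else 1 - weights[u, v]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      others <- setdiff(seq_len(n), c(i, j))
      if (sz == 2) {
        total <- b(i, j, 1, 2)
      } else if (sz == 3) {
        total <- b(i, j, 1, 2) * sum(b(i, others, 1, 3) * b(j, others, 2, 3))
      } else {
        no <- length(others)
        l <- rep(others, times = no)
        m <- rep(others, each = no)
        keep <- l != m
        l <- l[keep]; m <- m[keep]
        lm <- weights[cbind(l, m)]
        f34 <- if (adj[3, 4] == 1) lm else 1 - lm
        total <- b(i, j, 1, 2) *
          sum(b(i, l, 1, 3) * b(j, l, 2, 3) *
              b(i, m, 1, 4) * b(j, m, 2, 4) * f34)
      }
      tensor[k, i, j] <- total / stab
    }
  }
  new("IsomerCountTensor", counts = tensor,
      normalized = array(0, c(0, 0, 0)),
      ids = rownames(weights) %||% as.character(seq_len(n)))
}

#' Normalize isomer counts over targets
#'
#' Divides each (isomer, source) row by its total count over all
#' targets other than the source; rows with a zero total stay all-zero.
#' After normalization every row sums to 1 or 0.
#'
#' @param tensor an \linkS4class{IsomerCountTensor}.
#' @return the tensor with the `normalized` slot filled.
#' @export
normalizeCounts <- function(tensor) {
  counts <- tensor@counts
  norm <- counts
  for (k in seq_len(dim(counts)[1])) {
    rs <- rowSums(counts[k, , , drop = TRUE])  # diagonal already 0
    rs[rs == 0] <- Inf                         # all-zero rows stay zero
    norm[k, , ] <- counts[k, , ] / rs
  }
  tensor@normalized <- norm
  tensor
}

`%||%` <- function(a, b) if (is.null(a)) b else a
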