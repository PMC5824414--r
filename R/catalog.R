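# Exhaustive enumeration of the 2-4 node graphlet catalog, the
# automorphism orbits and the ordered orbit-pair interaction isomers.
# Everything here is brute force over vertex permutations: the largest
# graphlet has 4 nodes, so the permutation groups have at most 24
# elements and exhaustive enumeration is both exact and instant.

# all permutations of 1..k as a matrix, one permutation per row
.allPerms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .allPerms(k - 1L)
  out <- NULL
  for (pos in seq_len(k)) {
    block <- cbind(sub, k)[, append(seq_len(k - 1L), k, after = pos - 1L),
                           drop = FALSE]
    out <- rbind(out, block)
  }
  out
}

# canonical code of an adjacency matrix: lexicographically smallest
# upper-triangle string over all vertex relabelings
.canonicalForm <- function(adj) {
  k <- nrow(adj)
  perms <- .allPerms(k)
  best <- NULL
  bestPerm <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    a <- adj[p, p]
    code <- paste(a[upper.tri(a)], collapse = "")
    if (is.null(best) || code < best) {
      best <- code
      bestPerm <- p
    }
  }
  list(code = best, adj = adj[bestPerm, bestPerm])
}

.isConnected <- function(adj) {
  k <- nrow(adj)
  seen <- c(TRUE, rep(FALSE, k - 1))
  repeat {
    newSeen <- seen | (adj %*% seen > 0)
    if (identical(newSeen, seen)) break
    seen <- newSeen
  }
  all(seen)
}

# automorphism group of adj: permutation matrix rows p with adj[p,p] == adj
.automorphisms <- function(adj) {
  perms <- .allPerms(nrow(adj))
  keep <- apply(perms, 1, function(p) identical(adj[p, p], adj))
  perms[keep, , drop = FALSE]
}

#' Build the graphlet interaction catalog
#'
#' Enumerates all connected undirected graphs on 2, 3 and 4 labeled
#' nodes, reduces them by isomorphism to the canonical graphlets,
#' derives the automorphism orbits of node positions, and constructs
#' the ordered (source, target) interaction templates: orbits of
#' ordered node pairs under the graphlet's automorphism group.
#' Exchanging source and target yields a different isomer. The catalog
#' ordering is deterministic: graphlets by (node count, edge count,
#' canonical code), orbits by canonical position, isomers by (graphlet,
#' source orbit, target orbit, template code).
#'
#' Each template stores the automorphism stabilizer size of its ordered
#' (source, target) pair; dividing ordered auxiliary-tuple sums by it
#' makes unit-weight counts equal induced-occurrence counts.
#'
#' @return an \linkS4class{IsomerCatalog} with 9 graphlets, 15 orbits
#'   and 28 isomers.
#' @examples
#' cat28 <- buildIsomerCatalog()
#' length(graphlets(cat28)); nrow(orbits(cat28)); nIsomers(cat28)
#' @export
buildIsomerCatalog <- function() {
  glist <- list()
  for (k in 2:4) {
    pairIdx <- utils::combn(k, 2)
    np <- ncol(pairIdx)
    seen <- character(0)
    for (mask in seq_len(2^np - 1)) {
      adj <- matrix(0L, k, k)
      sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
      for (e in sel) {
        adj[pairIdx[1, e], pairIdx[2, e]] <- 1L
        adj[pairIdx[2, e], pairIdx[1, e]] <- 1L
      }
      if (!.isConnected(adj)) next
      canon <- .canonicalForm(adj)
      key <- paste(k, canon$code)
      if (key %in% seen) next
      seen <- c(seen, key)
      glist[[length(glist) + 1L]] <- list(size = k, adj = canon$adj,
                                          code = canon$code,
                                          edges = sum(adj) / 2)
    }
  }
  ord <- order(vapply(glist, `[[`, 1L, "size"),
               vapply(glist, `[[`, 1, "edges"),
               vapply(glist, `[[`, "", "code"))
  glist <- glist[ord]

  orbitRows <- list()
  isomerList <- list()
  orbitIdOfNode <- list()  # per graphlet: node position -> global orbit id
  nextOrbit <- 0L
  for (g in seq_along(glist)) {
    adj <- glist[[g]]$adj
    k <- glist[[g]]$size
    aut <- .automorphisms(adj)
    # node orbits: images of each node under the automorphism group
    nodeOrbit <- integer(k)
    assigned <- rep(FALSE, k)
    ids <- integer(0)
    for (v in seq_len(k)) {
      if (assigned[v]) next
      image <- sort(unique(aut[, v]))
      nextOrbit <- nextOrbit + 1L
      nodeOrbit[image] <- nextOrbit
      assigned[image] <- TRUE
      orbitRows[[nextOrbit]] <- data.frame(orbit = nextOrbit - 1L,
                                           graphlet = g - 1L, node = v,
                                           degree = sum(adj[v, ]))
    }
    orbitIdOfNode[[g]] <- nodeOrbit

    # orbits of ordered node pairs under the automorphism group
    pairSeen <- matrix(FALSE, k, k)
    for (u in seq_len(k)) for (v in seq_len(k)) {
      if (u == v || pairSeen[u, v]) next
      images <- unique(cbind(aut[, u], aut[, v]))
      pairSeen[images] <- TRUE
      aux <- setdiff(seq_len(k), c(u, v))
      slots <- c(u, v, aux)
      tplAdj <- adj[slots, slots, drop = FALSE]
      stab <- sum(aut[, u] == u & aut[, v] == v)
      isomerList[[length(isomerList) + 1L]] <- list(
        graphlet = g - 1L, size = k, adj = tplAdj,
        sourceOrbit = nodeOrbit[u] - 1L, targetOrbit = nodeOrbit[v] - 1L,
        symmetry = stab,
        code = paste(tplAdj[upper.tri(tplAdj)], collapse = ""))
    }
  }

  iord <- order(vapply(isomerList, `[[`, 0L, "graphlet"),
                vapply(isomerList, `[[`, 0L, "sourceOrbit"),
                vapply(isomerList, `[[`, 0L, "targetOrbit"),
                vapply(isomerList, `[[`, "", "code"))
  isomerList <- isomerList[iord]
  for (i in seq_along(isomerList))
    isomerList[[i]]$label <- paste0("I", i)

  new("IsomerCatalog",
      graphlets = lapply(glist, `[[`, "adj"),
      orbits = do.call(rbind, orbitRows),
      isomers = isomerList)
}
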