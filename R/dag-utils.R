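# Internal helpers on parent -> child edge lists.

# TRUE if the directed edge set contains a cycle (Kahn's algorithm).
.dagHasCycle <- function(nodes, edges) {
  if (nrow(edges) == 0) return(FALSE)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges[, 2])
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; removed <- removed + 1L
    out <- edges[edges[, 1] == v, 2]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  removed < length(nodes)
}

# Logical vector over nodes: does a directed path node -> ... -> target exist?
# (target itself counts as reaching.)
.dagReaches <- function(nodes, edges, target) {
  reach <- stats::setNames(nodes == target, nodes)
  if (nrow(edges) == 0) return(reach)
  repeat {
    # parent reaches if any of its children does
    newly <- reach
    hit <- reach[edges[, 2]]
    if (any(hit)) newly[edges[hit, 1]] <- TRUE
    if (identical(newly, reach)) break
    reach <- newly
  }
  reach
}

# children of each node within one DAG, as a named list
.dagChildren <- function(dag) {
  kids <- stats::setNames(vector("list", length(dag@nodes)), dag@nodes)
  e <- dag@edges
  if (nrow(e)) for (r in seq_len(nrow(e)))
    kids[[e[r, 1]]] <- c(kids[[e[r, 1]]], e[r, 2])
  kids
}

# normalize entity labels: trim whitespace, lower-case (naming drifts
# between association and similarity sources are the dominant failure mode)
.normalizeIds <- function(x) tolower(trimws(x))
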