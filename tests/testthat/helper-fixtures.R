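# Shared fixtures, built in code at test time.

# the catalog is deterministic; build it once per test run
sharedCatalog <- buildIsomerCatalog()

# random symmetric census weight matrix (zero diagonal)
randomWeights <- function(n, binary = FALSE, density = 0.5, ids = NULL) {
  w <- if (binary) matrix(rbinom(n * n, 1, density), n)
       else matrix(runif(n * n), n)
  w <- (w + t(w)) / 2
  if (binary) w <- 1 * (w > 0.5)  # symmetric 0/1
  diag(w) <- 0
  if (!is.null(ids)) dimnames(w) <- list(ids, ids)
  w
}

# adjacency of a named small graph on labelled nodes
namedGraph <- function(nodes, edgeList) {
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in edgeList) {
    w[e[1], e[2]] <- 1
    w[e[2], e[1]] <- 1
  }
  w
}

# find catalog isomers by the structure of their template
findIsomer <- function(catalog, size, edgeSlots) {
  adj <- matrix(0L, size, size)
  for (e in edgeSlots) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  hits <- which(vapply(isomers(catalog), function(iso)
    iso$size == size && identical(iso$adj, adj), logical(1)))
  stopifnot(length(hits) == 1)
  hits
}

# a tiny worked example: 4 diseases x 5 miRNAs with two disease groups,
# full functional-similarity coverage and complete DAG coverage
tinyWorld <- function() {
  assoc <- AssociationMatrix(pairs = rbind(
    c("colon ca", "mir-a"), c("colon ca", "mir-b"),
    c("rectal ca", "mir-a"), c("rectal ca", "mir-c"),
    c("glioma", "mir-d"), c("glioma", "mir-e"),
    c("astrocytoma", "mir-d")))
  mids <- mirnaIds(assoc)
  fs <- diag(1, 5)
  dimnames(fs) <- list(mids, mids)
  fs[upper.tri(fs)] <- c(0.8, 0.7, 0.1, 0.6, 0.2, 0.1, 0.15, 0.1, 0.2, 0.9)
  fs <- (fs + t(fs)); diag(fs) <- 1
  dags <- list(
    "astrocytoma" = DiseaseDAG("astrocytoma",
      rbind(c("neoplasms", "cns ca"), c("cns ca", "glioma"),
            c("glioma", "astrocytoma"))),
    "colon ca" = DiseaseDAG("colon ca",
      rbind(c("neoplasms", "gi ca"), c("gi ca", "colon ca"))),
    "glioma" = DiseaseDAG("glioma",
      rbind(c("neoplasms", "cns ca"), c("cns ca", "glioma"))),
    "rectal ca" = DiseaseDAG("rectal ca",
      rbind(c("neoplasms", "gi ca"), c("gi ca", "rectal ca"))))
  list(assoc = assoc, mirnaSim = SimilarityMatrix(fs, "functional"),
       dags = dags)
}

# write the tiny world to TSV files in a temp dir; returns the paths
tinyWorldFiles <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tw <- tinyWorld()
  writeAssociations(tw$assoc, file.path(dir, "associations.tsv"))
  writeSimilarityMatrix(tw$mirnaSim, file.path(dir, "mirna_sim.tsv"))
  rows <- do.call(rbind, lapply(tw$dags, function(dag) {
    e <- dagEdges(dag)
    cbind(dagRoot(dag), e[, 1], e[, 2])
  }))
  write.table(rows, file.path(dir, "dags.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(dir = dir,
       associations = file.path(dir, "associations.tsv"),
       mirnaSim = file.path(dir, "mirna_sim.tsv"),
       dags = file.path(dir, "dags.tsv"))
}

# all permutations of 1..k (test-local; independent of the package's
# internal enumeration)
allPermutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1, function(p) append(p, k, after = pos - 1L)))
  }))
}
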