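#' Read a disease-miRNA association list
#'
#' Reads a two-column tab-separated file of (disease ID, miRNA ID) pairs
#' and materializes the binary adjacency matrix A with lexicographically
#' sorted ID registries. Duplicate pairs are dropped with a warning.
#'
#' @param path path to a headerless two-column TSV.
#' @param normalizeIds lower-case and trim labels (default TRUE).
#' @return an \linkS4class{AssociationMatrix}.
#' @export
readAssociations <- function(path, normalizeIds = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no associations in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("malformed association row at line ", bad[1], " of ", path)
  pairs <- do.call(rbind, parts)
  AssociationMatrix(pairs = pairs, normalizeIds = normalizeIds)
}

#' Write a disease-miRNA association list
#'
#' @param x an \linkS4class{AssociationMatrix}.
#' @param path output TSV path.
#' @export
writeAssociations <- function(x, path) {
  idx <- which(assocMatrix(x) == 1, arr.ind = TRUE)
  df <- data.frame(disease = diseaseIds(x)[idx[, 1]],
                   mirna = mirnaIds(x)[idx[, 2]])
  df <- df[order(df$disease, df$mirna), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-disease ancestor DAGs
#'
#' Reads a three-column tab-separated file of (disease, parent, child)
#' triples and builds one \linkS4class{DiseaseDAG} per disease. A row
#' whose parent and child fields are both empty (or "-") declares a
#' disease with a singleton DAG; diseases listed in `diseases` but
#' absent from the file also get singleton DAGs.
#'
#' @param path path to the TSV.
#' @param diseases optional character vector of disease IDs that must
#'   each receive a DAG.
#' @param normalizeIds lower-case and trim labels (default TRUE).
#' @return a named list of \linkS4class{DiseaseDAG} objects.
#' @export
readDiseaseDags <- function(path, diseases = NULL, normalizeIds = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) > 3L)
  if (length(bad))
    stop("malformed DAG row at line ", bad[1], " of ", path)
  rows <- lapply(parts, function(p) c(p, character(3L - length(p))))
  tab <- do.call(rbind, rows)
  if (normalizeIds) tab[] <- .normalizeIds(tab)
  tab[tab == "-"] <- ""
  halfEdge <- xor(nzchar(tab[, 2]), nzchar(tab[, 3]))
  if (any(halfEdge))
    stop("malformed DAG row at line ", which(halfEdge)[1], " of ", path)
  dags <- list()
  for (d in unique(tab[, 1])) {
    sub <- tab[tab[, 1] == d, , drop = FALSE]
    sub <- sub[nzchar(sub[, 2]) & nzchar(sub[, 3]), , drop = FALSE]
    edges <- unique(sub[, 2:3, drop = FALSE])
    nodes <- unique(c(d, as.vector(edges)))
    if (nrow(edges) && .dagHasCycle(nodes, edges))
      stop("cycle detected in DAG of disease '", d, "'")
    if (nrow(edges) && !all(.dagReaches(nodes, edges, d)))
      stop("DAG of disease '", d,
           "' has a node with no directed path to the disease")
    dags[[d]] <- DiseaseDAG(root = d, edges = edges, nodes = nodes)
  }
  if (!is.null(diseases)) {
    if (normalizeIds) diseases <- .normalizeIds(diseases)
    for (d in setdiff(diseases, names(dags)))
      dags[[d]] <- DiseaseDAG(root = d)
  }
  dags
}

#' Read a square similarity matrix
#'
#' Reads a tab-separated square matrix whose first row and first column
#' are entity IDs. Mild asymmetry is repaired by averaging with the
#' transpose (warning above 1e-6); values are clipped to [0, 1] with a
#' warning.
#'
#' @param path path to the TSV.
#' @param kind similarity kind stored in the result (default
#'   "functional").
#' @param normalizeIds lower-case and trim labels (default TRUE).
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
readSimilarityMatrix <- function(path, kind = "functional",
                                 normalizeIds = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("similarity matrix is not square: ", nrow(m), " x ", ncol(m))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("NaN/NA similarity at row ", idx[1], ", column ", idx[2])
  }
  if (normalizeIds) {
    rownames(m) <- .normalizeIds(rownames(m))
    colnames(m) <- .normalizeIds(colnames(m))
  }
  if (anyDuplicated(rownames(m))) stop("duplicate IDs in similarity header")
  if (!identical(rownames(m), colnames(m)))
    m <- m[, rownames(m), drop = FALSE]  # align column order to rows
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    warning("similarity matrix asymmetric (max ", signif(asym, 3),
            "); symmetrized by averaging")
  m <- (m + t(m)) / 2
  if (any(m < 0 | m > 1)) {
    warning("similarity values outside [0, 1] clipped")
    m[m < 0] <- 0
    m[m > 1] <- 1
  }
  SimilarityMatrix(m, kind = kind)
}

#' Write a similarity matrix as TSV
#'
#' First row and first column carry the entity IDs, matching the format
#' `readSimilarityMatrix()` expects.
#'
#' @param x a \linkS4class{SimilarityMatrix}.
#' @param path output path.
#' @export
writeSimilarityMatrix <- function(x, path) {
  utils::write.table(simValues(x), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Write prediction scores
#'
#' Writes the combined scores both in long form (disease, miRNA, score,
#' known flag; sorted by disease then descending score) and, optionally,
#' as a square-format TSV matrix.
#'
#' @param result a \linkS4class{GimdaResult}.
#' @param path output path for the long-form TSV.
#' @param matrixPath optional output path for the matrix form.
#' @export
writeScores <- function(result, path, matrixPath = NULL) {
  s <- gimdaScores(result)
  df <- data.frame(disease = rep(rownames(s), times = ncol(s)),
                   mirna = rep(colnames(s), each = nrow(s)),
                   score = as.vector(s),
                   known = as.integer(as.vector(knownMask(result))))
  df <- df[order(df$disease, -df$score, df$mirna), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrixPath))
    utils::write.table(s, matrixPath, sep = "\t", quote = FALSE,
                       col.names = NA)
  invisible(path)
}
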