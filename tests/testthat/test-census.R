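edgeIso <- findIsomer(sharedCatalog, 2, list(c(1, 2)))
# both ends of a 3-node path: source and target are the non-adjacent ends
pathEndsIso <- findIsomer(sharedCatalog, 3, list(c(1, 3), c(2, 3)))
# opposite corners of a 4-cycle: source-target non-adjacent, both aux
# adjacent to both, aux pair non-adjacent
c4OppositeIso <- findIsomer(sharedCatalog, 4,
                            list(c(1, 3), c(1, 4), c(2, 3), c(2, 4)))

test_that("hand-checkable graphs give the expected isomer counts", {
  # single edge: one edge isomer occurrence, nothing with auxiliaries
  w <- namedGraph(c("i", "j"), list(c("i", "j")))
  counts <- isomerCounts(countIsomers(w, sharedCatalog))
  expect_equal(counts[edgeIso, 1, 2], 1)
  sizes <- vapply(isomers(sharedCatalog), `[[`, 0L, "size")
  expect_true(all(counts[sizes > 2, , ] == 0))

  # path a-b-c: b is the unique midpoint between the ends
  w <- namedGraph(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  counts <- isomerCounts(countIsomers(w, sharedCatalog))
  expect_equal(counts[pathEndsIso, 1, 3], 1)
  expect_equal(counts[pathEndsIso, 3, 1], 1)
  expect_equal(counts[pathEndsIso, 1, 2], 0)

  # triangle: the path-ends template requires the closing edge absent
  w <- namedGraph(c("a", "b", "c"),
                  list(c("a", "b"), c("b", "c"), c("a", "c")))
  counts <- isomerCounts(countIsomers(w, sharedCatalog))
  expect_true(all(counts[pathEndsIso, , ] == 0))

  # 4-cycle: one occurrence across opposite corners after dividing the
  # two auxiliary orderings by the symmetry factor
  w <- namedGraph(c("a", "b", "c", "d"),
                  list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  counts <- isomerCounts(countIsomers(w, sharedCatalog))
  expect_equal(counts[c4OppositeIso, 1, 3], 1)
  expect_equal(counts[c4OppositeIso, 2, 4], 1)
  expect_equal(counts[c4OppositeIso, 1, 2], 0)
})

test_that("fast census equals the brute-force oracle", {
  set.seed(101)
  for (rep in 1:6) {
    n <- sample(4:9, 1)
    w <- randomWeights(n, binary = rep %% 2 == 0)
    fast <- isomerCounts(countIsomers(w, sharedCatalog))
    slow <- isomerCounts(countIsomersOracle(w, sharedCatalog))
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
})

test_that("binary weights give integral counts matching subgraph counts", {
  set.seed(55)
  w <- randomWeights(8, binary = TRUE)
  counts <- isomerCounts(countIsomers(w, sharedCatalog))
  expect_lt(max(abs(counts - round(counts))), 1e-9)
  # triangle isomer totals: each triangle is seen from 6 ordered pairs
  triIso <- findIsomer(sharedCatalog, 3,
                       list(c(1, 2), c(1, 3), c(2, 3)))
  nTriangles <- sum(diag(w %*% w %*% w)) / 6
  expect_equal(sum(counts[triIso, , ]), 6 * nTriangles)
  # edge isomer total counts every ordered adjacent pair once
  expect_equal(sum(counts[edgeIso, , ]), sum(w))
})

test_that("relabeling nodes permutes the count tensor identically", {
  set.seed(7)
  w <- randomWeights(6)
  perm <- sample(6)
  base <- isomerCounts(countIsomers(w, sharedCatalog))
  relabeled <- isomerCounts(countIsomers(w[perm, perm], sharedCatalog))
  expect_equal(relabeled, base[, perm, perm])
})

test_that("counts are multilinear in each edge weight", {
  set.seed(12)
  w <- randomWeights(6)
  lo <- hi <- mid <- w
  lo[2, 5] <- lo[5, 2] <- 0.1
  hi[2, 5] <- hi[5, 2] <- 0.9
  mid[2, 5] <- mid[5, 2] <- 0.5
  cLo <- isomerCounts(countIsomers(lo, sharedCatalog))
  cHi <- isomerCounts(countIsomers(hi, sharedCatalog))
  cMid <- isomerCounts(countIsomers(mid, sharedCatalog))
  expect_equal(cMid, (cLo + cHi) / 2, tolerance = 1e-12)
})

test_that("invalid census weights are rejected", {
  w <- randomWeights(4)
  bad <- w; bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(countIsomers(bad, sharedCatalog), "symmetric")
  bad <- w; diag(bad) <- 1
  expect_error(countIsomers(bad, sharedCatalog), "diagonal")
  bad <- w; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(countIsomers(bad, sharedCatalog), "\\[0, 1\\]")
  expect_error(countIsomersOracle(randomWeights(16), sharedCatalog),
               "15 nodes")
})

test_that("normalization divides by the row total over other targets", {
  # star: p adjacent to exactly two targets with equal counts
  w <- namedGraph(c("p", "t1", "t2"), list(c("p", "t1"), c("p", "t2")))
  tensor <- normalizeCounts(countIsomers(w, sharedCatalog))
  norm <- normalizedCounts(tensor)
  expect_equal(norm[edgeIso, 1, 2], 0.5)
  expect_equal(norm[edgeIso, 1, 3], 0.5)
  # every row sums to 1 or 0 after normalization
  set.seed(31)
  tensor <- normalizeCounts(countIsomers(randomWeights(7), sharedCatalog))
  sums <- apply(normalizedCounts(tensor), c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9 | abs(sums) < 1e-12))
  # isolated source: all-zero row stays zero
  w <- namedGraph(c("a", "b", "z"), list(c("a", "b")))
  norm <- normalizedCounts(normalizeCounts(countIsomers(w, sharedCatalog)))
  expect_true(all(norm[, 3, ] == 0))
})
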