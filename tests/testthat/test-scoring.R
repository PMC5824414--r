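# small deterministic setup shared by the scoring tests
scoringSetup <- function(seed = 20) {
  set.seed(seed)
  assoc <- AssociationMatrix(values = {
    a <- matrix(rbinom(30, 1, 0.4), 5, 6,
                dimnames = list(paste0("d", 1:5), paste0("m", 1:6)))
    a[1, ] <- 0            # d1 is a new disease: empty P(1)
    a[2, 1] <- 1           # keep every miRNA and remaining disease linked
    a[cbind(3:5, 2:4)] <- 1
    a[2, 5] <- 1; a[3, 6] <- 1
    a
  })
  wM <- randomWeights(6, ids = mirnaIds(assoc))
  wD <- randomWeights(5, ids = diseaseIds(assoc))
  list(assoc = assoc,
       tM = normalizeCounts(countIsomers(wM, sharedCatalog)),
       tD = normalizeCounts(countIsomers(wD, sharedCatalog)))
}

test_that("feature columns sum normalized counts over known partners", {
  s <- scoringSetup()
  fm <- buildFeatureMatrix(s$tM, s$assoc, "mirna")
  norm <- normalizedCounts(s$tM)
  a <- assocMatrix(s$assoc)
  # new disease: empty partner set, zero column
  col_d1_m2 <- fm$features[, which(fm$pairIndex$disease == "d1" &
                                   fm$pairIndex$mirna == "m2")]
  expect_true(all(col_d1_m2 == 0))
  # generic pair: direct evaluation of the partner sum
  P3 <- which(a["d3", ] == 1)
  col <- fm$features[, which(fm$pairIndex$disease == "d3" &
                             fm$pairIndex$mirna == "m5")]
  expect_equal(col, apply(norm[, P3, 5, drop = FALSE], 1, sum))
  # single-partner disease: the column is that partner's row
  aSingle <- assocMatrix(s$assoc)
  aSingle["d2", ] <- 0; aSingle["d2", "m3"] <- 1
  fs <- buildFeatureMatrix(s$tM, AssociationMatrix(values = aSingle),
                           "mirna")
  col <- fs$features[, which(fs$pairIndex$disease == "d2" &
                             fs$pairIndex$mirna == "m6")]
  expect_equal(col, norm[, 3, 6])
})

test_that("features are additive over the known partner set", {
  s <- scoringSetup()
  a1 <- a2 <- both <- matrix(0, 5, 6,
                             dimnames = dimnames(assocMatrix(s$assoc)))
  a1["d2", c(1, 2)] <- 1
  a2["d2", c(4, 5)] <- 1
  both["d2", c(1, 2, 4, 5)] <- 1
  # keep registries identical (other cells irrelevant to d2's column)
  f <- function(a) buildFeatureMatrix(s$tM, AssociationMatrix(values = a),
                                      "mirna")$features
  j <- which(rep(paste0("d", 1:5), times = 6) == "d2" &
             rep(paste0("m", 1:6), each = 5) == "m3")
  expect_equal(f(both)[, j], f(a1)[, j] + f(a2)[, j])
})

test_that("disease-side features mirror the miRNA side through Q(j)", {
  s <- scoringSetup()
  fd <- buildFeatureMatrix(s$tD, s$assoc, "disease")
  norm <- normalizedCounts(s$tD)
  a <- assocMatrix(s$assoc)
  Q5 <- which(a[, "m5"] == 1)
  col <- fd$features[, which(fd$pairIndex$disease == "d4" &
                             fd$pairIndex$mirna == "m5")]
  expect_equal(col, apply(norm[, Q5, 4, drop = FALSE], 1, sum))
  expect_error(buildFeatureMatrix(s$tM, s$assoc, "disease"),
               "registry")
})

test_that("closed-form regression recovers planted weights exactly", {
  set.seed(3)
  X <- matrix(runif(28 * 120), 28)
  vStar <- rnorm(28)
  labels <- as.numeric(crossprod(X, vStar))
  expect_lt(max(abs(fitWeights(X, labels, lambda = 0) - vStar)), 1e-8)
  # one-hot features pick out the matching label entry
  I <- diag(28)
  expect_equal(fitWeights(I, c(1, rep(0, 27)), lambda = 0),
               c(1, rep(0, 27)))
  # refitting on the model's own predictions is idempotent
  yHat <- as.numeric(crossprod(X, fitWeights(X, labels, lambda = 0)))
  expect_lt(max(abs(fitWeights(X, yHat, lambda = 0) - vStar)), 1e-8)
})

test_that("ridge shrinks weights monotonically and rescues singular fits", {
  set.seed(4)
  X <- matrix(runif(28 * 120), 28)
  labels <- rbinom(120, 1, 0.3)
  norms <- vapply(c(0, 1, 10, 1e3, 1e6),
                  function(l) sqrt(sum(fitWeights(X, labels, l)^2)), 1)
  expect_true(all(diff(norms) < 0))
  Xsing <- X
  Xsing[2, ] <- Xsing[1, ]          # rank-deficient
  expect_error(fitWeights(Xsing, labels, lambda = 0), "lambda")
  expect_silent(fitWeights(Xsing, labels, lambda = 1e-6))
})

test_that("combined scores average the two graph scores", {
  expect_equal(combineScores(0.4, 0.6), 0.5)
  s <- scoringSetup()
  res <- gimdaFit(s$assoc, s$tM, s$tD)
  expect_equal(gimdaScores(res),
               (res@scoresMirna + res@scoresDisease) / 2)
  # per-graph scores are the weight-feature inner products
  fm <- buildFeatureMatrix(s$tM, s$assoc, "mirna")
  expect_equal(as.vector(res@scoresMirna),
               as.numeric(crossprod(fm$features, isomerWeights(res, "mirna"))))
})

test_that("a new disease is ranked purely by the disease graph", {
  s <- scoringSetup()
  res <- gimdaFit(s$assoc, s$tM, s$tD)
  expect_true(all(res@scoresMirna["d1", ] == 0))
  expect_equal(gimdaScores(res)["d1", ], res@scoresDisease["d1", ] / 2)
  expect_equal(order(-gimdaScores(res)["d1", ]),
               order(-res@scoresDisease["d1", ]))
})

test_that("candidate ranking excludes known pairs and breaks ties
           deterministically", {
  s <- scoringSetup()
  res <- gimdaFit(s$assoc, s$tM, s$tD)
  rc <- rankCandidates(res, "d3")
  known <- knownMirnas(s$assoc, "d3")
  expect_false(any(rc$mirna %in% known))
  expect_equal(nrow(rc), 6 - length(known))
  expect_true(all(diff(rc$score) <= 0))
  expect_error(rankCandidates(res, "nosuch"), "unknown disease")

  # forced ties resolve lexicographically
  tied <- res
  tied@scores[] <- 0.5
  rcTied <- rankCandidates(tied, "d1")
  expect_identical(rcTied$mirna, sort(rcTied$mirna))
  expect_equal(nrow(rankCandidates(res, "d3", n = 2)), 2)
})
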