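test_that("AUC equals the exhaustive Mann-Whitney count", {
  expect_equal(computeAuc(c(2, 3), c(0, 1)), 1)
  expect_equal(computeAuc(rep(1, 5), rep(1, 7)), 0.5)
  # enumerate the 4 comparisons: 0.9>0.6, 0.9>0.1, 0.4<0.6, 0.4>0.1
  expect_equal(computeAuc(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
  brute <- function(p, q) {
    cmp <- outer(p, q, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(88)
  for (i in 1:5) {
    p <- sample(round(runif(9), 1), 9, replace = TRUE)
    q <- sample(round(runif(11), 1), 11, replace = TRUE)
    expect_equal(computeAuc(p, q), brute(p, q))
  }
  expect_error(computeAuc(numeric(0), 1), "length")
})

test_that("trapezoidal ROC area equals the midrank AUC", {
  set.seed(17)
  p <- round(runif(20), 1)     # heavy ties on purpose
  q <- round(runif(30), 1)
  roc <- rocCurve(p, q)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(!is.unsorted(roc$fpr) && !is.unsorted(roc$tpr))
  trapz <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trapz, computeAuc(p, q))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  p <- runif(15); q <- runif(20)
  base <- computeAuc(p, q)
  expect_equal(computeAuc(exp(3 * p), exp(3 * q)), base)
  expect_equal(computeAuc(-1 / (1 + p), -1 / (1 + q)), base)
})

cvWorld <- function(seed = 2, n = 9) {
  generatePlantedWorld(plantedWorldParams(
    nDiseases = n, nMirnas = n, assocDensity = 0.6, hiddenFraction = 0,
    seed = seed))
}

test_that("LOOCV ranks held-out associations without leakage", {
  w <- cvWorld()
  g <- gimdaLoocv(w$assoc, w$mirnaSim, w$dags, catalog = sharedCatalog,
                  mode = "global")
  l <- gimdaLoocv(w$assoc, w$mirnaSim, w$dags, catalog = sharedCatalog,
                  mode = "local")
  nPos <- sum(assocMatrix(w$assoc))
  expect_equal(length(g@ranks), nPos)
  expect_true(all(g@ranks >= 0 & g@ranks <= 1))
  expect_gt(cvAuc(g), 0.5)     # block structure is recoverable
  expect_gt(cvAuc(l), 0.5)
  expect_equal(g@mode, "global_loocv")
  expect_equal(l@mode, "local_loocv")
  # deterministic: identical reruns
  g2 <- gimdaLoocv(w$assoc, w$mirnaSim, w$dags, catalog = sharedCatalog,
                   mode = "global")
  expect_equal(g@ranks, g2@ranks)
})

test_that("LOOCV leakage control recomputes kernels without the test pair", {
  # without functional/DAG coverage the similarity graphs depend on A,
  # so the strict and fast-approx protocols must differ
  w <- cvWorld(seed = 5, n = 7)
  strict <- gimdaLoocv(w$assoc, NULL, NULL, catalog = sharedCatalog)
  fast <- gimdaLoocv(w$assoc, NULL, NULL, catalog = sharedCatalog,
                     fastApprox = TRUE)
  expect_false(isTRUE(all.equal(strict@ranks, fast@ranks)))
})

test_that("k-fold CV partitions exactly and is seed-deterministic", {
  w <- cvWorld()
  nPos <- sum(assocMatrix(w$assoc))
  k1 <- gimdaKfoldCv(w$assoc, w$mirnaSim, w$dags, catalog = sharedCatalog,
                     k = 5, repeats = 2, seed = 7)
  expect_equal(length(k1@ranks), 2 * nPos)  # every positive tested per repeat
  expect_equal(length(k1@aucs), 2)
  k2 <- gimdaKfoldCv(w$assoc, w$mirnaSim, w$dags, catalog = sharedCatalog,
                     k = 5, repeats = 2, seed = 7)
  expect_identical(k1@aucs, k2@aucs)
  expect_error(gimdaKfoldCv(w$assoc, w$mirnaSim, w$dags,
                            catalog = sharedCatalog, k = nPos + 1,
                            repeats = 1), "exceeds")
  # k = number of positives degenerates to a LOOCV-like schedule
  kl <- gimdaKfoldCv(w$assoc, w$mirnaSim, w$dags, catalog = sharedCatalog,
                     k = nPos, repeats = 1, seed = 1)
  expect_equal(length(kl@ranks), nPos)
  expect_true(is.na(kl@aucSd))
})

test_that("CV on a null world is uninformative", {
  w <- generatePlantedWorld(plantedWorldParams(
    nDiseases = 9, nMirnas = 9, noise = 1, assocDensity = 0.6,
    hiddenFraction = 0, seed = 3))
  g <- gimdaLoocv(w$assoc, w$mirnaSim, w$dags, catalog = sharedCatalog)
  expect_gt(cvAuc(g), 0.2)
  expect_lt(cvAuc(g), 0.8)
})

test_that("midrank AUC agrees with an established ROC implementation", {
  set.seed(23)
  p <- runif(25); q <- runif(40)
  ours <- computeAuc(p, q)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(25, 40)), predictor = c(p, q),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref)
})
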