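test_that("the planted world is deterministic and internally consistent", {
  p <- plantedWorldParams(nDiseases = 12, nMirnas = 14, seed = 21)
  w1 <- generatePlantedWorld(p)
  w2 <- generatePlantedWorld(p)
  expect_identical(assocMatrix(w1$assoc), assocMatrix(w2$assoc))
  expect_identical(simValues(w1$mirnaSim), simValues(w2$mirnaSim))
  expect_identical(w1$truth, w2$truth)

  # hidden truth and visible associations are disjoint
  a <- assocMatrix(w1$assoc)
  idx <- cbind(match(w1$truth[, 1], rownames(a)),
               match(w1$truth[, 2], colnames(a)))
  expect_true(all(a[idx] == 0))
  expect_gt(nrow(w1$truth), 0)
  # every disease and miRNA keeps at least one visible association
  expect_true(all(rowSums(a) >= 1))
  expect_true(all(colSums(a) >= 1))
})

test_that("block similarities separate within from between blocks", {
  w <- generatePlantedWorld(plantedWorldParams(nDiseases = 20,
                                               nMirnas = 20, seed = 31))
  v <- simValues(w$mirnaSim)
  same <- outer(w$mirnaBlocks, w$mirnaBlocks, "==") & upper.tri(v)
  diff <- !outer(w$mirnaBlocks, w$mirnaBlocks, "==") & upper.tri(v)
  expect_gt(mean(v[same]), mean(v[diff]))
})

test_that("generated worlds round-trip through the readers", {
  w <- generatePlantedWorld(plantedWorldParams(nDiseases = 8, nMirnas = 8,
                                               seed = 13))
  dir <- withr::local_tempdir()
  writePlantedWorld(w, dir)
  a <- readAssociations(file.path(dir, "associations.tsv"))
  expect_identical(assocMatrix(a), assocMatrix(w$assoc))
  s <- readSimilarityMatrix(file.path(dir, "mirna_similarity.tsv"))
  expect_equal(simValues(s), simValues(w$mirnaSim), tolerance = 1e-9)
  dags <- readDiseaseDags(file.path(dir, "disease_dags.tsv"),
                          diseases = diseaseIds(a))
  expect_setequal(names(dags), names(w$dags))
  for (d in names(dags))
    expect_setequal(dagNodes(dags[[d]]), dagNodes(w$dags[[d]]))
})

test_that("DAG corpus depth controls shared ancestry", {
  ids <- paste0("d", 1:4)
  blocks <- c(1L, 1L, 2L, 2L)
  # depth 0: singleton DAGs, identity semantic similarity
  flat <- generateRandomDagCorpus(ids, depth = 0, seed = 1)
  expect_true(all(vapply(flat, function(d) length(dagNodes(d)) == 1,
                         logical(1))))
  ss1 <- simValues(semanticSimilarityMatrices(flat)$ss1)
  expect_equal(unname(ss1), diag(4))
  # identical ancestor chains give similarity 1 in both models
  twin <- list(a = DiseaseDAG("x", rbind(c("r", "p"), c("p", "x"))),
               b = DiseaseDAG("x", rbind(c("r", "p"), c("p", "x"))))
  expect_equal(semanticSimilarity1(twin$a, twin$b), 1)
  # deeper shared prefixes increase within-block similarity
  within <- vapply(2:5, function(depth) {
    corpus <- generateRandomDagCorpus(ids, depth = depth, blocks = blocks,
                                      seed = 3)
    simValues(semanticSimilarityMatrices(corpus)$ss1)["d1", "d2"]
  }, numeric(1))
  expect_true(all(diff(within) > 0))
  # same-block pairs are more semantically similar than cross-block
  corpus <- generateRandomDagCorpus(ids, depth = 3, blocks = blocks,
                                    seed = 3)
  ss <- simValues(semanticSimilarityMatrices(corpus)$ss1)
  expect_gt(ss["d1", "d2"], ss["d1", "d3"])
})

test_that("stronger block contrast yields better recovery", {
  gaps <- list(c(0.45, 0.40), c(0.70, 0.25), c(5 / 6, 1 / 6))
  mean_auc <- vapply(gaps, function(gp) {
    mean(vapply(1:10, function(s) {
      w <- generatePlantedWorld(plantedWorldParams(
        nDiseases = 16, nMirnas = 16, withinBlockSim = gp[1],
        betweenBlockSim = gp[2], seed = s))
      evaluatePlantedWorld(w, catalog = sharedCatalog)$auc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) > 0))
})

test_that("degenerate world parameters are rejected", {
  expect_error(plantedWorldParams(nDiseases = 0))
  expect_error(plantedWorldParams(noise = 1.5))
  expect_error(plantedWorldParams(nBlocks = 40, nDiseases = 10,
                                  nMirnas = 10))
  w <- generatePlantedWorld(plantedWorldParams(nDiseases = 8, nMirnas = 8,
                                               hiddenFraction = 0,
                                               seed = 1))
  expect_error(evaluatePlantedWorld(w, catalog = sharedCatalog),
               "no hidden truth")
})
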