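test_that("the step schedule starts at the fourth root of 0.01", {
  sched <- trainingSchedule()
  expect_equal(sched[1], 0.01^(1 / 4))
  expect_equal(sched[1], 0.1^(1 / 2))
  expect_equal(sched[-1], c(0.1, 0.03, 0.01))
  expect_true(all(diff(sched) < 0))
})

test_that("hill climbing stays in [0,1] and never loses RPO", {
  ## constant objective: any point is a plateau local optimum
  set.seed(89)
  flat <- function(w) c(rpo = 3, ea = 0)
  res <- hillClimb(c(a = 0.4, b = 0.9, EAW = 0.1), flat)
  expect_true(all(res$weights >= 0 & res$weights <= 1))
  expect_equal(res$value[["rpo"]], 3)

  ## 1-D objective maximized at weight 1, reachable by + steps
  ramp <- function(w) c(rpo = -round(abs(w[["a"]] - 1) / 0.01), ea = 0)
  set.seed(97)
  res2 <- hillClimb(c(a = 0.33), ramp)
  expect_equal(unname(res2$weights[["a"]]), 1, tolerance = 0.011)

  ## RPO of the returned point is never below the start, random objectives
  set.seed(101)
  for (rep in 1:5) {
    tab <- stats::setNames(sample(0:5, 11, replace = TRUE), seq(0, 1, 0.1))
    bumpy <- function(w)
      c(rpo = tab[[as.character(round(round(w[["a"]] / 0.1) * 0.1, 1))]], ea = 0)
    start <- c(a = sample(seq(0.1, 0.9, 0.1), 1))
    res3 <- hillClimb(start, bumpy, schedule = c(0.1))
    expect_gte(res3$value[["rpo"]], bumpy(start)[["rpo"]])
  }
  expect_error(hillClimb(c(a = 1.5), flat), "\\[0,1\\]")
  expect_error(hillClimb(c(a = 0.5), flat, schedule = c(0.1, 0.1)),
               "decreasing")
})

test_that("training is reproducible and ranks restarts by RPO then EA", {
  scn <- syntheticScenario(nDomains = 4, nLigands = 12, rewireProb = 0,
                           vertexLossProb = 0, nNoiseFeatures = 1,
                           featureNoise = 0.02, seed = 5)
  sim <- generatePair(scn)
  r1 <- trainWeights(sim$features@features, sim$net1, sim$net2,
                     sim$orthology, restarts = 2, seed = 7)
  r2 <- trainWeights(sim$features@features, sim$net1, sim$net2,
                     sim$orthology, restarts = 2, seed = 7)
  expect_identical(r1@history, r2@history)
  expect_identical(r1@best@weights, r2@best@weights)
  h <- r1@history
  best <- h[order(-h$rpo, -h$ea, h$restart)[1], ]
  expect_equal(unname(unlist(best[c("informative", "noise1", "EAW")])),
               unname(c(r1@best@weights[c("informative", "noise1")],
                        r1@best@eaw)))
  expect_error(trainWeights(sim$features@features, sim$net1, sim$net2,
                            sim$orthology, restarts = 0), "restarts")
})

test_that("a perfectly informative feature is trained to recover max RPO", {
  scn <- syntheticScenario(nDomains = 5, nLigands = 16, rewireProb = 0.05,
                           vertexLossProb = 0, featureNoise = 0,
                           nNoiseFeatures = 2, seed = 19)
  sim <- generatePair(scn)
  run <- trainWeights(sim$features@features, sim$net1, sim$net2,
                      sim$orthology, restarts = 4, seed = 3)
  mx <- metricMaxima(sim$net1, sim$net2, sim$orthology)
  expect_equal(max(run@history$rpo), unname(mx["max_rpo"]))
})

test_that("redundant features are removed by Euclidean closeness", {
  ids1 <- c("A,1,5", "B,1,5"); ids2 <- c("C,1,5", "D,1,5")
  mk <- function(x, name) FeatureMatrix(name, "domain",
                                        matrix(x, 2, 2,
                                               dimnames = list(ids1, ids2)))
  f1 <- mk(c(0.1, 0.9, 0.4, 0.6), "f1")
  dup <- mk(c(0.1, 0.9, 0.4, 0.6), "dup")          # exact duplicate of f1
  far <- mk(c(0.9, 0.1, 0.8, 0.05), "far")
  out <- reduceRedundant(list(f1, dup, far), threshold = 0.10)
  kept <- vapply(out, featureName, "")
  expect_equal(length(out), 2L)                    # exactly one copy removed
  expect_true("far" %in% kept)
  expect_equal(sum(c("f1", "dup") %in% kept), 1L)
  ## all-orthogonal features survive untouched
  out2 <- reduceRedundant(list(f1, far), threshold = 0.10)
  expect_equal(length(out2), 2L)
  ## of two near-identical features, the one closer to the rest is dropped
  a <- mk(c(0.50, 0.50, 0.50, 0.50), "a")
  b <- mk(c(0.52, 0.50, 0.50, 0.50), "b")          # near-duplicate of a
  c2 <- mk(c(0.45, 0.45, 0.45, 0.45), "c2")        # closer to a than to b
  out3 <- reduceRedundant(list(a, b, c2), threshold = 0.10)
  expect_false("a" %in% vapply(out3, featureName, ""))
  ## single feature: unchanged
  expect_equal(length(reduceRedundant(list(f1))), 1L)
})

test_that("iterative reduction removes noise but keeps the essential feature", {
  scn <- syntheticScenario(nDomains = 4, nLigands = 10, rewireProb = 0,
                           vertexLossProb = 0, featureNoise = 0,
                           nNoiseFeatures = 1, seed = 23)
  sim <- generatePair(scn)
  ## add an all-zero (uninformative) feature on each side
  zero_feats <- lapply(c("domain", "ligand"), function(side) {
    tmpl <- Filter(function(f) featureSide(f) == side, sim$features@features)[[1]]
    FeatureMatrix("deadweight", side, featureScores(tmpl) * 0)
  })
  feats <- c(sim$features@features, zero_feats)
  red <- reduceIterative(feats, sim$net1, sim$net2, sim$orthology,
                         topK = 5, restarts = 3, seed = 29)
  kept <- unique(vapply(red$features, featureName, ""))
  expect_true("informative" %in% kept)            # essential: never removed
  expect_true(length(kept) < length(unique(vapply(feats, featureName, ""))))
  ## output preserves the best achievable RPO
  expect_equal(max(red$run@history$rpo),
               unname(metricMaxima(sim$net1, sim$net2, sim$orthology)["max_rpo"]))
})

test_that("the feature-distance diagnostic reports distances and PCA", {
  ids1 <- c("A,1,5", "B,1,5"); ids2 <- c("C,1,5", "D,1,5")
  mk <- function(x, name) FeatureMatrix(name, "domain",
                                        matrix(x, 2, 2,
                                               dimnames = list(ids1, ids2)))
  set.seed(31)
  fs <- lapply(1:4, function(k) mk(round(stats::runif(4), 2), paste0("f", k)))
  rep <- featureDistanceReport(fs, "domain")
  expect_s3_class(rep$pca, "prcomp")
  expect_equal(attr(rep$distances, "Size"), 4L)
})
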