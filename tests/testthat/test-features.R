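test_that("topological scores match hand computations on a path and 4-cycle", {
  p <- mk_iin("b", c("a", "c"), c("b-a", "b-c"))
  expect_equal(unname(topoVertexScores(p, "degree")["b,1,20"]), 2)
  expect_equal(unname(topoVertexScores(p, "betweenness")["b,1,20"]), 1)
  expect_equal(unname(topoVertexScores(p, "closeness")["b,1,20"]), 1)
  cyc <- mk_iin(c("d1", "d2"), c("l1", "l2"),
                c("d1-l1", "d1-l2", "d2-l1", "d2-l2"))
  expect_equal(unname(topoVertexScores(cyc, "eccentricity")), rep(2, 4))
  expect_equal(unname(topoVertexScores(cyc, "neighbourhood_connectivity")),
               rep(2, 4))
})

test_that("all nine topological features equal the brute-force oracle", {
  feats <- c("degree", "avg_shortest_path", "betweenness", "closeness",
             "eccentricity", "neighbourhood_connectivity", "radiality",
             "stress", "topological_coefficient")
  set.seed(23)
  for (rep in 1:6) {
    net <- rand_iin(sample(2:4, 1), sample(3:6, 1), p = 0.45)
    for (f in feats) {
      got <- topoVertexScores(net, f)
      want <- oracle_topo(net, f)
      expect_equal(got[names(want)], want, tolerance = 1e-10,
                   info = paste("feature", f))
    }
  }
})

test_that("isolated vertices score zero on distance-based features", {
  net <- mk_iin(c("d1", "d2"), "l1", "d1-l1")   # d2 isolated
  for (f in c("closeness", "avg_shortest_path", "eccentricity", "radiality"))
    expect_equal(unname(topoVertexScores(net, f)["d2,1,20"]), 0)
})

test_that("log normalization maps equal scores to 1 and extreme pairs to 0", {
  s1 <- c(a = 0, b = 10)
  s2 <- c(x = 0, y = 10)
  fm <- normalizeFeature(s1, s2)
  m <- featureScores(fm)
  expect_equal(m["a", "x"], 1)
  expect_equal(m["b", "y"], 1)
  expect_equal(m["a", "y"], 0)
  expect_equal(m["b", "x"], 0)
  ## all-equal scores: degenerate M = 0 maps everything to 1
  expect_true(all(featureScores(normalizeFeature(c(v = 3), c(w = 3))) == 1))
  ## shift and negation invariance, range containment
  set.seed(5)
  for (rep in 1:10) {
    a <- stats::setNames(stats::rnorm(4), paste0("a", 1:4))
    b <- stats::setNames(stats::rnorm(3), paste0("b", 1:3))
    m0 <- featureScores(normalizeFeature(a, b))
    expect_true(all(m0 >= 0 & m0 <= 1))
    expect_equal(featureScores(normalizeFeature(a + 7, b + 7)), m0)
    expect_equal(featureScores(normalizeFeature(-a, -b)), m0)
  }
})

test_that("Smith-Waterman matches spec examples and the exhaustive oracle", {
  expect_equal(smithWaterman("PPP", "PPP"), 21)   # three P-P at BLOSUM62 7
  expect_equal(smithWaterman("PPP", ""), 0)
  expect_equal(smithWaterman("", "KR"), 0)
  expect_equal(smithWaterman("AKW", "WKA"), smithWaterman("WKA", "AKW"))

  data(BLOSUM62, package = "Biostrings", envir = environment())
  alphabet <- c("A", "R", "P", "G", "W")
  set.seed(31)
  for (rep in 1:12) {
    s1 <- paste(sample(alphabet, sample(2:6, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(alphabet, sample(2:6, 1), replace = TRUE), collapse = "")
    expect_equal(smithWaterman(s1, s2),
                 oracle_sw(s1, s2, BLOSUM62),
                 info = paste(s1, s2))
  }
})

test_that("pairwise score rescaling handles both modes and rejects negatives", {
  m <- matrix(c(0, 3, 9, 9), 2, 2,
              dimnames = list(c("a1", "a2"), c("b1", "b2")))
  lin <- featureScores(pairwiseScoresToFeature(m, "linear_max"))
  expect_equal(unname(lin[1, 1]), 0)
  expect_equal(unname(lin[2, 1]), 1 / 3)
  expect_equal(unname(lin[1, 2]), 1)
  lg <- featureScores(pairwiseScoresToFeature(m, "log"))
  expect_equal(unname(lg[1, 1]), 0)
  expect_equal(unname(lg[1, 2]), 1)
  ## constant positive scores all map to 1 (linear mode)
  cm <- matrix(5, 2, 2, dimnames = list(c("a1", "a2"), c("b1", "b2")))
  expect_true(all(featureScores(pairwiseScoresToFeature(cm)) == 1))
  ## all-zero input stays zero
  zm <- cm * 0
  expect_true(all(featureScores(pairwiseScoresToFeature(zm)) == 0))
  m[1, 1] <- -1
  expect_error(pairwiseScoresToFeature(m), "non-negative")
})

test_that("protein-level scores broadcast to constant within-protein blocks", {
  net1 <- IIN(data.frame(id = c("P,1,20", "P,30,50", "R,1,20"),
                         kind = "domain"), NULL)
  net2 <- IIN(data.frame(id = c("Q,5,25", "S,1,20"), kind = "domain"), NULL)
  ps <- data.frame(id1 = "P", id2 = "Q", score = 0.8)
  fm <- liftProteinFeature(ps, net1, net2, "domain")
  m <- featureScores(fm)
  expect_equal(unname(m["P,1,20", "Q,5,25"]), 0.8)
  expect_equal(unname(m["P,30,50", "Q,5,25"]), 0.8)
  expect_equal(unname(m["R,1,20", "Q,5,25"]), 0)     # absent pair -> 0
  expect_equal(unname(m["P,1,20", "S,1,20"]), 0)
  ## block structure on a random instance
  set.seed(13)
  scores <- expand.grid(id1 = c("P", "R"), id2 = c("Q", "S"),
                        stringsAsFactors = FALSE)
  scores$score <- round(stats::runif(4), 3)
  fm2 <- liftProteinFeature(scores, net1, net2, "domain")
  m2 <- featureScores(fm2)
  for (r in rownames(m2)) for (cc in colnames(m2)) {
    pr <- parseInterfaceId(r)$protein; pc <- parseInterfaceId(cc)$protein
    expect_equal(unname(m2[r, cc]),
                 scores$score[scores$id1 == pr & scores$id2 == pc])
  }
})

test_that("assembleStack forms weighted sums per side and checks coverage", {
  ids1 <- c("A,1,5", "B,1,5"); ids2 <- c("C,1,5", "D,1,5")
  mk <- function(x, name) FeatureMatrix(name, "domain",
                                        matrix(x, 2, 2,
                                               dimnames = list(ids1, ids2)))
  f1 <- mk(1, "one"); f0 <- mk(0, "zero")
  ## single feature, weight 1: identity
  b <- assembleStack(list(f1), WeightVector(c(one = 1), eaw = 0))
  expect_equal(b$domain, featureScores(f1))
  ## convex combination: features scoring (1, 0) with weights 0.4/0.6
  b2 <- assembleStack(list(f1, f0), WeightVector(c(one = 0.4, zero = 0.6),
                                                 eaw = 0))
  expect_true(all(b2$domain == 0.4))
  ## 29 equal weights = mean of matrices
  set.seed(3)
  fs <- lapply(1:29, function(k)
    mk(round(stats::runif(4), 3), paste0("f", k)))
  w <- WeightVector(stats::setNames(rep(1 / 29, 29), paste0("f", 1:29)),
                    eaw = 0)
  b3 <- assembleStack(fs, w)
  mean_m <- Reduce(`+`, lapply(fs, featureScores)) / 29
  expect_equal(b3$domain, mean_m, tolerance = 1e-12)
  ## unknown / missing weights are errors
  expect_error(assembleStack(list(f1), WeightVector(c(nope = 1), eaw = 0)),
               "unknown feature")
  expect_error(assembleStack(list(f1, f0), WeightVector(c(one = 1), eaw = 0)),
               "missing a weight")
})

test_that("sequence feature scores ligand pairs and skips missing sequences", {
  v1 <- data.frame(id = c("D,1,60", "P,1,3"), kind = c("domain", "ligand"),
                   protein = c("D", "P"), start = c(1L, 1L), end = c(60L, 3L),
                   sequence = c(NA, "PPP"))
  v2 <- data.frame(id = c("E,1,60", "Q,1,3", "R,1,3"),
                   kind = c("domain", "ligand", "ligand"),
                   protein = c("E", "Q", "R"), start = 1L, end = c(60L, 3L, 3L),
                   sequence = c(NA, "PPP", NA))
  net1 <- IIN(v1, NULL); net2 <- IIN(v2, NULL)
  fm <- sequenceFeature(net1, net2)
  m <- featureScores(fm)
  expect_equal(unname(m["P,1,3", "Q,1,3"]), 1)   # 21/21 after linear_max
  expect_equal(unname(m["P,1,3", "R,1,3"]), 0)   # missing sequence -> 0
})
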