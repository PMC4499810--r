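test_that("pure greedy aligns in descending score order", {
  net1 <- mk_iin(c("A", "B"), character())
  net2 <- mk_iin(c("X", "Y"), character())
  base <- list(domain = matrix(c(0.9, 0.8, 0.8, 0.1), 2, 2, byrow = TRUE,
                               dimnames = list(c("A,1,20", "B,1,20"),
                                               c("X,1,20", "Y,1,20"))))
  tr <- greedyAlign(net1, net2, base)
  p <- tracePairs(tr)
  expect_equal(p$u, c("A,1,20", "B,1,20"))
  expect_equal(p$v, c("X,1,20", "Y,1,20"))
  expect_equal(p$base_score, c(0.9, 0.1))
})

test_that("the Fig-10-style fixture flips its third pair with the EAW", {
  fx <- fig10Fixture()
  expect_true(igraph::is_connected(asIgraph(fx$net1)))
  expect_true(igraph::is_connected(asIgraph(fx$net2)))
  t1 <- tracePairs(greedyPlusAlign(fx$net1, fx$net2, fx$base, eaw = 1))
  expect_equal(t1$u[1], "A,1,15"); expect_equal(t1$v[1], "1,1,15")
  expect_equal(t1$u[3], "C,1,20"); expect_equal(t1$v[3], "3,1,20")
  expect_equal(t1$bonus_count[3], 2L)   # boosted by both earlier alignments
  t0 <- tracePairs(greedyPlusAlign(fx$net1, fx$net2, fx$base, eaw = 0))
  expect_equal(t0$u[3], "E,1,20"); expect_equal(t0$v[3], "3,1,20")
})

test_that("eaw = 0 GreedyPlus reproduces the greedy baseline exactly", {
  set.seed(53)
  for (rep in 1:25) {
    net1 <- rand_iin(sample(2:4, 1), sample(3:6, 1), p = 0.4, prefix = "A")
    net2 <- rand_iin(sample(2:4, 1), sample(3:6, 1), p = 0.4, prefix = "B")
    base <- rand_base(net1, net2)
    a <- tracePairs(greedyPlusAlign(net1, net2, base, eaw = 0))
    b <- tracePairs(greedyAlign(net1, net2, base))
    expect_identical(a[, c("u", "v", "side")], b[, c("u", "v", "side")])
  }
})

test_that("alignment size equals the sum of the smaller partition sides", {
  set.seed(59)
  for (rep in 1:10) {
    net1 <- rand_iin(sample(1:4, 1), sample(2:6, 1), p = 0.4, prefix = "A")
    net2 <- rand_iin(sample(1:4, 1), sample(2:6, 1), p = 0.4, prefix = "B")
    base <- rand_base(net1, net2)
    want <- min(length(domainVertices(net1)), length(domainVertices(net2))) +
      min(length(ligandVertices(net1)), length(ligandVertices(net2)))
    expect_equal(nrow(tracePairs(greedyPlusAlign(net1, net2, base, 0.5))), want)
    expect_equal(nrow(tracePairs(greedyAlign(net1, net2, base))), want)
    expect_lte(nrow(tracePairs(seedExtendAlign(net1, net2, base))), want)
  }
})

test_that("GreedyPlus replays identically on a naive full-rescan simulator", {
  set.seed(61)
  for (rep in 1:12) {
    net1 <- rand_iin(sample(2:4, 1), sample(3:4, 1), p = 0.45, prefix = "A")
    net2 <- rand_iin(sample(2:4, 1), sample(3:4, 1), p = 0.45, prefix = "B")
    base <- rand_base(net1, net2)
    eaw <- sample(c(0.25, 0.5, 1), 1)    # dyadic: bonus arithmetic is exact
    got <- tracePairs(greedyPlusAlign(net1, net2, base, eaw = eaw))
    want <- oracle_greedyplus(net1, net2, base, eaw)
    expect_equal(got$u, want$u)
    expect_equal(got$v, want$v)
    expect_equal(got$bonus_count, want$bonus)
  }
})

test_that("isomorphic 4-cycles align onto the isomorphism with full EA", {
  net1 <- mk_iin(c("d1", "d2"), c("l1", "l2"),
                 c("d1-l1", "d1-l2", "d2-l1", "d2-l2"))
  net2 <- mk_iin(c("e1", "e2"), c("m1", "m2"),
                 c("e1-m1", "e1-m2", "e2-m1", "e2-m2"))
  base <- list(
    domain = matrix(c(1, 0, 0, 1), 2, 2,
                    dimnames = list(c("d1,1,20", "d2,1,20"),
                                    c("e1,1,20", "e2,1,20"))),
    ligand = matrix(c(1, 0, 0, 1), 2, 2,
                    dimnames = list(c("l1,1,15", "l2,1,15"),
                                    c("m1,1,15", "m2,1,15"))))
  for (eaw in c(0, 0.5, 2)) {
    tr <- greedyPlusAlign(net1, net2, base, eaw = eaw)
    expect_equal(oracle_ea(tr, net1, net2), 4L)
  }
})

test_that("seed-and-extend grows only along aligned edges and dead-ends", {
  ## K1,3 vs K1,3 with centers top-scoring: centers then all leaves, EA = 3
  s1 <- mk_iin("c", c("x", "y", "z"), c("c-x", "c-y", "c-z"))
  s2 <- mk_iin("d", c("p", "q", "r"), c("d-p", "d-q", "d-r"))
  base <- list(
    domain = matrix(0.9, 1, 1, dimnames = list("c,1,20", "d,1,20")),
    ligand = matrix(c(0.5, 0.1, 0.1, 0.1, 0.5, 0.1, 0.1, 0.1, 0.5), 3, 3,
                    byrow = TRUE,
                    dimnames = list(c("x,1,15", "y,1,15", "z,1,15"),
                                    c("p,1,15", "q,1,15", "r,1,15"))))
  tr <- seedExtendAlign(s1, s2, base)
  p <- tracePairs(tr)
  expect_equal(nrow(p), 4L)
  expect_equal(p$u[1], "c,1,20")
  expect_equal(oracle_ea(tr, s1, s2), 3L)

  ## seed on a degree-0 vertex: immediate dead end, alignment of size 1
  i1 <- mk_iin(c("a", "b"), "l", "b-l")
  i2 <- mk_iin(c("u", "v"), "m", "v-m")
  base2 <- list(
    domain = matrix(c(0.99, 0.1, 0.1, 0.2), 2, 2, byrow = TRUE,
                    dimnames = list(c("a,1,20", "b,1,20"),
                                    c("u,1,20", "v,1,20"))),
    ligand = matrix(0.5, 1, 1, dimnames = list("l,1,15", "m,1,15")))
  expect_equal(nrow(tracePairs(seedExtendAlign(i1, i2, base2))), 1L)

  ## every non-seed step aligns at least one edge pair
  set.seed(67)
  for (rep in 1:10) {
    net1 <- rand_iin(sample(2:4, 1), sample(3:5, 1), p = 0.5, prefix = "A")
    net2 <- rand_iin(sample(2:4, 1), sample(3:5, 1), p = 0.5, prefix = "B")
    tr <- seedExtendAlign(net1, net2, rand_base(net1, net2))
    audit <- traceEdgeExtension(tr, net1, net2)
    if (nrow(audit) > 1L)
      expect_true(all(audit$selected_extending[-1]))
  }
})

test_that("a larger EAW never demotes a bonus-dependent pair", {
  fx <- fig10Fixture()
  ## (C,3) is third at eaw = 1; raising eaw keeps it third or promotes it
  pos <- vapply(c(1, 2, 5, 20), function(e) {
    p <- tracePairs(greedyPlusAlign(fx$net1, fx$net2, fx$base, eaw = e))
    which(p$u == "C,1,20" & p$v == "3,1,20")
  }, numeric(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("infinite EAW always extends an edge when possible, then resumes", {
  set.seed(71)
  for (rep in 1:15) {
    net1 <- rand_iin(sample(2:4, 1), sample(3:6, 1), p = 0.4, prefix = "A")
    net2 <- rand_iin(sample(2:4, 1), sample(3:6, 1), p = 0.4, prefix = "B")
    base <- rand_base(net1, net2)
    tr <- greedyPlusAlign(net1, net2, base, eaw = Inf)
    audit <- traceEdgeExtension(tr, net1, net2)
    expect_true(all(audit$selected_extending[audit$candidate_existed]))
    ## still aligns the full smaller sides (resumes after dead frontiers)
    want <- min(length(domainVertices(net1)), length(domainVertices(net2))) +
      min(length(ligandVertices(net1)), length(ligandVertices(net2)))
    expect_equal(nrow(tracePairs(tr)), want)
    ## and the infinite-mode trace matches the naive simulator
    sim <- oracle_greedyplus(net1, net2, base, Inf)
    expect_equal(tracePairs(tr)$u, sim$u)
    expect_equal(tracePairs(tr)$v, sim$v)
  }
})

test_that("aligning networks with one empty side still aligns the other", {
  net1 <- mk_iin(c("a", "b"), character())
  net2 <- mk_iin(c("u", "v"), character())
  base <- list(domain = matrix(c(0.6, 0.2, 0.3, 0.5), 2, 2, byrow = TRUE,
                               dimnames = list(c("a,1,20", "b,1,20"),
                                               c("u,1,20", "v,1,20"))))
  expect_equal(nrow(tracePairs(greedyPlusAlign(net1, net2, base, 0.5))), 2L)
})
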