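test_that("expected quartet CFs follow the coalescent closed form", {
  # star limit: zero internal branch gives (1/3, 1/3, 1/3)
  net0 <- parseExtendedNewick("(((A:1,B:1):0,C:1):1,D:2);", "coalescent")
  cf0 <- expectedQuartetCF(net0, c("A", "B", "C", "D"))
  expect_equal(unname(cf0), rep(1 / 3, 3), tolerance = 1e-9)

  # long internal branch: major CF approaches 1
  net10 <- parseExtendedNewick("(((A:1,B:1):10,C:11):1,D:12);", "coalescent")
  cf10 <- expectedQuartetCF(net10, c("A", "B", "C", "D"))
  expect_gt(cf10[1], 0.9999)

  # t = 1: (1 - (2/3)e^-1, e^-1/3, e^-1/3)
  net1 <- parseExtendedNewick("(((A:1,B:1):1,C:2):1,D:3);", "coalescent")
  cf1 <- expectedQuartetCF(net1, c("A", "B", "C", "D"))
  expect_equal(unname(cf1), c(1 - 2 / 3 * exp(-1), exp(-1) / 3, exp(-1) / 3),
               tolerance = 1e-12)
  expect_equal(sum(cf1), 1)
})

test_that("one-hybrid expected CFs are the gamma mixture of displayed trees", {
  base <- parseExtendedNewick("((((A:1,B:1):1,C:2):1,D:3):1,O:4);", "coalescent")
  net <- addHybridEdge(base, donor = "C", recipient = "B", at = 0.5, gamma = 0.3)
  cf <- expectedQuartetCF(net, c("A", "B", "C", "D"))
  dts <- displayedTrees(net)
  cfT <- lapply(dts, function(dt) {
    n1 <- phyloToNetwork(dt$phylo, "coalescent")
    expectedQuartetCF(n1, c("A", "B", "C", "D"))
  })
  mix <- Reduce(`+`, Map(function(c_, dt) dt$prob * c_, cfT, dts))
  expect_equal(unname(cf), unname(mix), tolerance = 1e-12)
})

test_that("observed CFs count informative resolving trees only", {
  t1 <- parseNewick("((a:1,b:1):1,(c:1,d:1):1);")
  cf <- observedQuartetCF(rep(list(t1), 10))
  expect_equal(unname(unlist(cf[1, c("cf1", "cf2", "cf3")])), c(1, 0, 0))
  expect_equal(cf$n, 10)

  # trees missing a taxon do not contribute
  t2 <- parseNewick("((a:1,b:1):1,c:1);")
  cf2 <- observedQuartetCF(list(t1, t2), taxa = c("a", "b", "c", "d"))
  expect_equal(cf2$n, 1)

  # star quartets are uninformative
  t3 <- parseNewick("(a:1,b:1,c:1,d:1);")
  cf3 <- observedQuartetCF(list(t1, t3))
  expect_equal(cf3$n, 1)

  # proportions sum to one wherever defined
  net <- randomNetwork(7, h = 1, seed = 41)
  sim <- simulateGeneTrees(simConfig(net, nLoci = 200, seed = 1, mTax = 0.2))
  cfs <- observedQuartetCF(sim$coalTrees)
  rs <- rowSums(cfs[, c("cf1", "cf2", "cf3")])
  expect_true(all(abs(rs[cfs$n > 0] - 1) < 1e-9))
})

test_that("the pseudolikelihood is linear in counts and order-invariant", {
  net <- randomNetwork(6, h = 1, seed = 42)
  sim <- simulateGeneTrees(simConfig(net, nLoci = 300, seed = 2))
  cf <- observedQuartetCF(sim$coalTrees)
  s1 <- pseudoLoglik(net, cf)
  cf2 <- cf; cf2$n <- cf2$n * 2
  expect_equal(pseudoLoglik(net, cf2), 2 * s1, tolerance = 1e-9)
  cf3 <- cf[rev(seq_len(nrow(cf))), ]
  expect_equal(pseudoLoglik(net, cf3), s1, tolerance = 1e-9)
})

test_that("a perfectly fitting network is a local optimum over branch lengths", {
  net <- parseExtendedNewick("(((A:1,B:1):1,C:2):1,D:3);", "coalescent")
  cf <- expectedQuartetCFTable(net)
  cfTab <- data.frame(cf[, c("t1", "t2", "t3", "t4")],
                      cf1 = cf$ecf1, cf2 = cf$ecf2, cf3 = cf$ecf3, n = 100)
  s0 <- pseudoLoglik(net, cfTab)
  for (delta in c(-0.2, 0.2)) {
    pert <- net
    ed <- pert@edges
    internal <- which(ed$child > nTips(net))
    ed$length[internal[1]] <- ed$length[internal[1]] + delta
    pert@edges <- ed
    expect_lt(pseudoLoglik(pert, cfTab), s0)
  }
})

test_that("support classes follow the printed thresholds", {
  expect_equal(classifySupport(95, 100), "strong")      # delta 5
  expect_equal(classifySupport(90, 100), "strong")      # delta 10 (boundary)
  expect_equal(classifySupport(85, 100), "moderate")    # delta 15
  expect_equal(classifySupport(80, 100), "moderate")    # delta 20 (boundary)
  expect_equal(classifySupport(75, 100), "poor")        # delta 25
  expect_equal(classifySupport(70, 100), "excluded_delta")  # delta 30
  expect_equal(classifySupport(60, 100), "excluded_delta")
  expect_equal(classifySupport(105, 100), "strong")     # better than reference
})

test_that("candidates with outgroup reticulations are excluded", {
  base <- parseExtendedNewick("(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,O:5);",
                              "coalescent")
  inner <- addHybridEdge(base, donor = "D", recipient = "B", at = 0.5, gamma = 0.3)
  og <- addHybridEdge(base, donor = "O", recipient = "E", at = 0.5, gamma = 0.2)
  og2 <- addHybridEdge(base, donor = "C", recipient = "O", at = 0.5, gamma = 0.2)
  ex <- excludeOutgroupReticulations(list(inner, og, og2, base), "O")
  expect_equal(ex$flags, c(FALSE, TRUE, TRUE, FALSE))
  expect_length(ex$retained, 2L)
  expect_error(excludeOutgroupReticulations(list(base), "nope"), "not a leaf")
})

test_that("prevailing-network selection follows the majority and >=2 rules", {
  mkEv <- function(res, h, topo, cls, score) {
    data.frame(resampling = res, h = h, topology = topo, score = score,
               delta = 0, class = cls, stringsAsFactors = FALSE)
  }
  # one topology strong in 4 of 5 resamplings: selected alone
  ev <- rbind(mkEv(1:5, 0L, "T0", "strong", -100),
              mkEv(1:4, 1L, "N1", "strong", -90),
              mkEv(5, 1L, "N2", "strong", -95))
  sel <- selectPrevailing(ev)
  expect_equal(sel$topology, "N1")
  expect_equal(sel$h, 1L)
  expect_equal(sel$nSupporting, 4L)

  # two topologies at the same h, strong in 3 and 2: both, in that order
  ev2 <- rbind(mkEv(1:5, 0L, "T0", "strong", -100),
               mkEv(1:3, 1L, "N1", "strong", -90),
               mkEv(4:5, 1L, "N2", "moderate", -92))
  sel2 <- selectPrevailing(ev2)
  expect_equal(sel2$topology, c("N1", "N2"))
  expect_equal(sel2$nSupporting, c(3L, 2L))

  # a topology supported once is not selected
  ev3 <- rbind(mkEv(1:5, 0L, "T0", "strong", -100),
               mkEv(1, 1L, "N1", "strong", -90))
  sel3 <- selectPrevailing(ev3)
  expect_equal(sel3$topology, "T0")
  expect_equal(sel3$h, 0L)

  # higher h wins over lower h when both have majority support
  ev4 <- rbind(mkEv(1:5, 0L, "T0", "strong", -100),
               mkEv(1:5, 1L, "N1", "strong", -90),
               mkEv(1:4, 2L, "N3", "moderate", -85))
  expect_equal(selectPrevailing(ev4)$topology, "N3")

  # excluded classes never contribute
  ev5 <- rbind(mkEv(1:2, 0L, "T0", "strong", -100),
               mkEv(1:2, 1L, "N1", "excluded_delta", -80),
               mkEv(1:2, 1L, "N2", "excluded_outgroup", -70))
  expect_equal(selectPrevailing(ev5)$topology, "T0")

  # nothing supported twice anywhere: fallback with a warning
  ev6 <- rbind(mkEv(1, 0L, "T0", "strong", -100),
               mkEv(2, 0L, "T1", "strong", -101))
  expect_warning(sel6 <- selectPrevailing(ev6), "two resamplings")
  expect_equal(sel6$topology, "T0")
})

test_that("candidate evaluation classifies against the per-h reference", {
  base <- parseExtendedNewick("(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,O:5);",
                              "coalescent")
  truth <- addHybridEdge(base, donor = "D", recipient = "B", at = 0.5, gamma = 0.3)
  wrong <- addHybridEdge(base, donor = "E", recipient = "A", at = 0.5, gamma = 0.3)
  og <- addHybridEdge(base, donor = "O", recipient = "E", at = 0.5, gamma = 0.2)
  sim <- simulateGeneTrees(simConfig(truth, nLoci = 2000, seed = 77))
  cf <- observedQuartetCF(sim$coalTrees)
  ev <- evaluateCandidates(list(truth, wrong, og, base), cf, outgroup = "O")
  expect_equal(ev$class[3], "excluded_outgroup")
  expect_equal(ev$delta[1], 0)           # truth is the h = 1 reference
  expect_equal(ev$class[4], "strong")    # lone h = 0 candidate
  expect_gt(ev$score[1], ev$score[2])
  expect_gt(ev$score[1], ev$score[4])
})
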