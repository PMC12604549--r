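test_that("plain newick parsing preserves lengths and distances", {
  tr <- parseNewick("(A:1.0,B:1.0);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 1))

  tr2 <- parseNewick("((A:1,B:1):0.5,C:1.5);")
  D <- ape::cophenetic.phylo(tr2)
  expect_equal(D["A", "C"], 3.0)

  expect_error(parseNewick("((A:1,B:1):0.5,C:1.5"), "unclosed")
  expect_error(parseNewick("(A:1,B:1));"), "character 10")
})

test_that("extended newick parses hybrids with inheritance probabilities", {
  net <- parseExtendedNewick("((A:1,(B:1)#H1:0.5::0.6):1,(#H1:0.5::0.4,C:1):1);")
  expect_s4_class(net, "SpeciesNetwork")
  expect_equal(nHybrids(net), 1L)
  expect_equal(sort(unname(inheritanceProbs(net)[[1]])), c(0.4, 0.6))

  # gamma on one parent inferred as the complement
  net2 <- parseExtendedNewick("((A:1,(B:1)#H1:0.5::0.6):1,(#H1:0.5,C:1):1);")
  expect_equal(sort(unname(inheritanceProbs(net2)[[1]])), c(0.4, 0.6))

  # no hybrids: degenerate to a tree parse
  net3 <- parseExtendedNewick("((A:1,B:1):1,C:2);")
  expect_equal(nHybrids(net3), 0L)
  expect_equal(nTips(net3), 3L)

  expect_error(parseExtendedNewick("((A:1,(B:1)#H1:0.5::0.7):1,(#H1:0.5::0.4,C:1):1);"),
               "sum")
  expect_error(parseExtendedNewick("((A:1,(B:1)#H1:0.5::0.6):1,C:2);"),
               "appears 1")
})

test_that("extended newick round-trips topology, lengths and gamma", {
  for (s in 1:12) {
    net <- randomNetwork(6, h = s %% 3, seed = 100 + s)
    txt <- writeExtendedNewick(net)
    net2 <- parseExtendedNewick(txt, "coalescent")
    expect_identical(canonicalTopology(net2), canonicalTopology(net))
    D1 <- networkPairwiseDistances(net)
    D2 <- networkPairwiseDistances(net2)
    expect_lt(max(abs(D1 - D2[rownames(D1), colnames(D1)])), 1e-9)
    g1 <- sort(unlist(inheritanceProbs(net)))
    g2 <- sort(unlist(inheritanceProbs(net2)))
    expect_lt(max(c(0, abs(g1 - g2))), 1e-9)
  }
})

test_that("network distances reduce to patristic distances on trees", {
  tr <- parseExtendedNewick("((A:1,B:1):1,C:2);")
  D <- networkPairwiseDistances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  # independent oracle: ape patristic distances on random trees
  for (s in 1:5) {
    set.seed(s)
    phy <- ape::rcoal(8)
    net <- phyloToNetwork(phy, "coalescent")
    expect_lt(max(abs(networkPairwiseDistances(net) -
                        ape::cophenetic.phylo(phy)[tipLabels(net), tipLabels(net)])),
              1e-9)
  }
})

test_that("network distances are the gamma-weighted displayed-tree mixture", {
  net <- parseExtendedNewick("((A:1,(B:1)#H1:0.5::0.6):1,(#H1:0.5::0.4,C:1):1);")
  # hand enumeration: displayed tree 1 (gamma .6) has d(A,B) = 2.5,
  # displayed tree 2 (gamma .4) has d(A,B) = 4.5
  D <- networkPairwiseDistances(net)
  expect_equal(D["A", "B"], 0.6 * 2.5 + 0.4 * 4.5)
  expect_equal(D["B", "C"], 0.6 * 4.5 + 0.4 * 2.5)
  expect_equal(D["A", "C"], 4)

  # gamma = 1 on one hybrid edge: distances equal the single displayed tree
  net1 <- parseExtendedNewick("((A:1,(B:1)#H1:0.5::1):1,(#H1:0.5::0,C:1):1);")
  dts <- displayedTrees(net1)
  keep <- which(vapply(dts, `[[`, numeric(1), "prob") == 1)
  cd <- ape::cophenetic.phylo(dts[[keep]]$phylo)
  expect_lt(max(abs(networkPairwiseDistances(net1) -
                      cd[tipLabels(net1), tipLabels(net1)])), 1e-12)

  # consistency: mixture over displayed trees equals the matrix
  for (s in 1:8) {
    net <- randomNetwork(6, h = 1 + s %% 2, seed = 300 + s)
    dts <- displayedTrees(net)
    labs <- tipLabels(net)
    mix <- Reduce(`+`, lapply(dts, function(dt) {
      dt$prob * ape::cophenetic.phylo(dt$phylo)[labs, labs]
    }))
    expect_lt(max(abs(mix - networkPairwiseDistances(net))), 1e-9)
  }
})

test_that("displayed-tree probabilities sum to one", {
  net <- parseExtendedNewick("((A:1,(B:1)#H1:0.5::0.6):1,(#H1:0.5::0.4,C:1):1);")
  dts <- displayedTrees(net)
  expect_length(dts, 2L)
  expect_equal(sort(vapply(dts, `[[`, numeric(1), "prob")), c(0.4, 0.6))

  net0 <- parseExtendedNewick("((A:1,B:1):1,C:2);")
  expect_length(displayedTrees(net0), 1L)
  expect_equal(displayedTrees(net0)[[1]]$prob, 1)

  for (s in 1:40) {
    net <- randomNetwork(6 + s %% 4, h = 1 + s %% 3, seed = 500 + s)
    pr <- vapply(displayedTrees(net), `[[`, numeric(1), "prob")
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
})

test_that("missing edge lengths are reported, node times check consistency", {
  ed <- data.frame(parent = c(4, 4, 5, 5), child = c(1, 5, 2, 3),
                   length = c(2, NA, 1, 1), gamma = NA_real_)
  net <- speciesNetwork(ed, c("A", "B", "C"))
  expect_error(networkPairwiseDistances(net), "missing edge lengths")
  ed$length[2] <- 5  # A at depth 2, B/C at depth 6: fine for distances,
  net2 <- speciesNetwork(ed, c("A", "B", "C"))
  expect_error(nodeTimes(net2), "time-consistent")
})

test_that("validity catches malformed networks", {
  # gamma pair not summing to 1
  ed <- data.frame(parent = c(5, 5, 6, 6, 7, 7), child = c(6, 3, 1, 7, 2, 2),
                   length = 1, gamma = NA_real_)
  expect_error(speciesNetwork(ed, c("A", "B", "C")),
               "inheritance|root|in-degree|sum")
  # level-1 holds for the generator output
  for (s in 1:5) {
    net <- randomNetwork(7, h = 2, seed = 700 + s)
    expect_true(validObject(net, test = TRUE) == TRUE ||
                  isTRUE(validObject(net, test = TRUE)))
  }
})
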