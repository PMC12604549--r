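test_that("coalescence probability within an internal branch matches the exponential CDF", {
  net <- parseExtendedNewick("((A:1,B:1):1,C:2);", "coalescent")
  cfg <- simConfig(net, nLoci = 20000, seed = 42)
  sim <- simulateGeneTrees(cfg)
  # A and B meet at time 1; they coalesce within the length-1 internal
  # branch (before time 2) with probability 1 - exp(-1)
  tAB <- vapply(sim$coalTrees, function(tr) {
    ape::cophenetic.phylo(tr)["A", "B"] / 2
  }, numeric(1))
  expect_lt(abs(mean(tAB < 2) - (1 - exp(-1))), 0.01)
})

test_that("three-taxon minor topologies appear at (1/3)exp(-t)", {
  net <- parseExtendedNewick("((A:1,B:1):1,C:2);", "coalescent")
  sim <- simulateGeneTrees(simConfig(net, nLoci = 20000, seed = 43))
  top <- vapply(sim$coalTrees, function(tr) {
    D <- ape::cophenetic.phylo(tr)
    which.min(c(D["A", "B"], D["A", "C"], D["B", "C"]))
  }, numeric(1))
  expMinor <- exp(-1) / 3
  expect_lt(abs(mean(top == 2) - expMinor), 0.01)
  expect_lt(abs(mean(top == 3) - expMinor), 0.01)
})

test_that("gamma = 0 reproduces the edge-deleted network on the same stream", {
  base <- parseExtendedNewick("((((A:1,B:1):1,C:2):1,D:3):1,O:4);", "coalescent")
  net0 <- addHybridEdge(base, donor = "C", recipient = "B", at = 0.5, gamma = 0)
  # same network with the hybrid edge removed but its endpoints kept
  ed <- networkEdges(net0)
  hyb <- hybridNodes(net0)
  drop <- which(ed$child == hyb & !is.na(ed$gamma) & ed$gamma == 0)
  ed2 <- ed[-drop, ]
  ed2$gamma <- NA_real_
  netDel <- speciesNetwork(ed2, tipLabels(net0), lengthUnit = "coalescent")
  s1 <- simulateGeneTrees(simConfig(net0, nLoci = 300, seed = 9))
  s2 <- simulateGeneTrees(simConfig(netDel, nLoci = 300, seed = 9))
  expect_identical(ape::write.tree(s1$coalTrees), ape::write.tree(s2$coalTrees))
})

test_that("same seed gives byte-identical output, different seed does not", {
  net <- parseExtendedNewick("((A:1,B:1):1,C:2);", "coalescent")
  s1 <- simulateGeneTrees(simConfig(net, nLoci = 100, seed = 5))
  s2 <- simulateGeneTrees(simConfig(net, nLoci = 100, seed = 5))
  s3 <- simulateGeneTrees(simConfig(net, nLoci = 100, seed = 6))
  expect_identical(ape::write.tree(s1$coalTrees), ape::write.tree(s2$coalTrees))
  expect_false(identical(ape::write.tree(s1$coalTrees), ape::write.tree(s3$coalTrees)))
  # per-locus substreams: locus i does not depend on nLoci
  s4 <- simulateGeneTrees(simConfig(net, nLoci = 40, seed = 5))
  expect_identical(ape::write.tree(s1$coalTrees[1:40]), ape::write.tree(s4$coalTrees))
})

test_that("simulated trees are ultrametric in coalescent units", {
  net <- randomNetwork(6, h = 1, seed = 77)
  sim <- simulateGeneTrees(simConfig(net, nLoci = 50, seed = 7))
  expect_true(all(vapply(sim$coalTrees, ape::is.ultrametric, logical(1))))
})

test_that("rate scaling bookkeeping is exact and sigma is recovered", {
  net <- parseExtendedNewick("((A:1,B:1):1,C:2);", "coalescent")
  sim <- simulateGeneTrees(simConfig(net, nLoci = 5000, seed = 3, sigmaRate = 0.5))
  sim <- scaleToSubstitutions(sim)
  # recorded multiplier times coalescent length equals the emitted length
  for (i in c(1, 100, 5000)) {
    expect_equal(sim$subsTrees[[i]]$edge.length,
                 sim$coalTrees[[i]]$edge.length * sim$rateMultipliers[i])
  }
  expect_lt(abs(sd(log(sim$rateMultipliers)) - 0.5) / 0.5, 0.05)
  # sigma = 0: multipliers all equal the lognormal median
  sim0 <- scaleToSubstitutions(simulateGeneTrees(simConfig(net, nLoci = 10, seed = 3)))
  expect_equal(sim0$rateMultipliers, rep(1, 10))
  expect_error(scaleToSubstitutions(sim, sigmaRate = -1), ">= 0")
})

test_that("missing-taxon dropping produces gene trees of unequal size", {
  net <- randomNetwork(8, h = 0, seed = 12)
  sim <- simulateGeneTrees(simConfig(net, nLoci = 400, seed = 2, mTax = 0.2))
  sizes <- vapply(sim$coalTrees, function(t) length(t$tip.label), numeric(1))
  expect_true(any(sizes < 8))
  expect_true(all(sizes >= 2))
  expect_lt(abs(mean(sizes) - 8 * 0.8), 0.4)
})

test_that("SNP simulation follows the infinite-sites placement", {
  # mutation on a terminal branch: exactly one carrier
  net <- parseExtendedNewick("((A:1,B:1):1,C:2);", "coalescent")
  sim <- simulateGeneTrees(simConfig(net, nLoci = 200, seed = 8))
  # replace gene trees by star trees: all branches terminal, so every
  # site must be a singleton
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  sim$coalTrees <- structure(rep(list(star), 200), class = "multiPhylo")
  snp <- simulateSnpMatrix(sim)
  counts <- colSums(genotypes(snp), na.rm = TRUE)
  expect_true(all(counts == 1))
  expect_equal(nSites(snp), 200L)
  # no missing data at mGt = 0
  expect_false(anyNA(genotypes(snp)))
  # positions within [1, locusLength], strictly one site per locus
  expect_true(all(siteInfo(snp)$pos >= 1 & siteInfo(snp)$pos <= 300))
  expect_equal(anyDuplicated(siteInfo(snp)$locus), 0L)
})

test_that("genotype masking and determinism of the SNP matrix", {
  net <- randomNetwork(6, h = 0, seed = 30)
  sim <- simulateGeneTrees(simConfig(net, nLoci = 2000, seed = 4, mGt = 0.15))
  snp <- simulateSnpMatrix(sim)
  miss <- mean(is.na(genotypes(snp)))
  expect_lt(abs(miss - 0.15), 0.02)
  snp2 <- simulateSnpMatrix(sim)
  expect_identical(genotypes(snp), genotypes(snp2))
})

test_that("simConfig validates its inputs", {
  net <- parseExtendedNewick("((A:1,B:1):1,C:2);", "coalescent")
  expect_error(simConfig(net, nLoci = 10), "seed")
  expect_error(simConfig(net, nLoci = 0, seed = 1), "positive")
  expect_error(simConfig(net, nLoci = 10, seed = 1, sigmaRate = -1), ">= 0")
  expect_error(simConfig(net, nLoci = 10, seed = 1, mTax = 1), "\\[0, 1\\)")
})

test_that("trait simulation on a network recovers the generating rate", {
  net <- randomNetwork(10, h = 1, seed = 55)
  st <- simulateTraitsOnNetwork(net, alpha = 1, k = 2, nTraits = 150, seed = 6)
  expect_equal(dim(st$tipStates), c(10L, 150L))
  expect_true(all(st$tipStates %in% 1:2))
  fit <- fitErsm(net, st$tipStates)
  expect_lt(abs(fit$alpha - 1) / 1, 0.35)
  # determinism
  st2 <- simulateTraitsOnNetwork(net, alpha = 1, k = 2, nTraits = 150, seed = 6)
  expect_identical(st$tipStates, st2$tipStates)
})
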