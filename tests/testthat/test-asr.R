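test_that("the equal-rates transition matrix has the closed form", {
  P <- ersmTransition(3, 0.7, 0.9)
  expect_equal(rowSums(P), rep(1, 3))
  e <- exp(-3 * 0.7 * 0.9)
  expect_equal(P[1, 2], (1 - e) / 3)
  expect_equal(P[1, 1], 1 / 3 + (1 - 1 / 3) * e)
  expect_equal(ersmTransition(4, 1, 0), diag(4))
  expect_equal(ersmTransition(2, 1, 1e6), matrix(0.5, 2, 2))
  expect_error(ersmTransition(2, 0, 1), "> 0")
})

test_that("tree likelihoods equal exhaustive enumeration", {
  for (s in 1:10) {
    set.seed(3000 + s)
    k <- 2 + s %% 2
    tr <- ape::rcoal(4 + s %% 3)
    st <- setNames(sample.int(k, length(tr$tip.label), replace = TRUE),
                   tr$tip.label)
    a <- runif(1, 0.2, 2)
    net <- phyloToNetwork(tr, "coalescent")
    expect_equal(networkTraitLoglik(net, st, a, k),
                 bruteTraitLoglik(tr, st, k, a), tolerance = 1e-12)
  }
})

test_that("network likelihoods equal the displayed-tree mixture oracle", {
  for (s in 1:10) {
    k <- 2 + s %% 2
    net <- randomNetwork(5 + s %% 2, h = 1 + s %% 2, seed = 3100 + s)
    set.seed(s)
    st <- setNames(sample.int(k, nTips(net), replace = TRUE), tipLabels(net))
    a <- runif(1, 0.2, 2)
    dts <- displayedTrees(net)
    mix <- log(sum(vapply(dts, function(dt) {
      dt$prob * exp(bruteTraitLoglik(dt$phylo, st, k, a))
    }, numeric(1))))
    expect_equal(networkTraitLoglik(net, st, a, k), mix, tolerance = 1e-10)
  }
})

test_that("degenerate mixtures and limits behave", {
  base <- parseExtendedNewick("((((A:1,B:1):1,C:2):1,D:3):1,O:4);", "coalescent")
  net1 <- addHybridEdge(base, "C", "B", at = 0.5, gamma = 1)
  st <- setNames(c(1L, 2L, 2L, 1L, 1L), c("A", "B", "C", "D", "O"))
  dts <- displayedTrees(net1)
  keep <- which(vapply(dts, `[[`, numeric(1), "prob") == 1)
  expect_equal(networkTraitLoglik(net1, st, 0.4, 2),
               bruteTraitLoglik(dts[[keep]]$phylo, st, 2, 0.4),
               tolerance = 1e-12)
  # frozen chain: identical tips, alpha -> 0 gives log(1/k)
  same <- setNames(rep(1L, 5), c("A", "B", "C", "D", "O"))
  expect_equal(networkTraitLoglik(base, same, 1e-9, 2), log(1 / 2),
               tolerance = 1e-6)
})

test_that("the fitted rate is a local optimum and boundaries are flagged", {
  net <- randomNetwork(8, h = 1, seed = 3200)
  st <- simulateTraitsOnNetwork(net, alpha = 0.8, k = 2, nTraits = 30, seed = 1)
  fit <- fitErsm(net, st$tipStates)
  llAt <- function(a) {
    sum(vapply(seq_len(ncol(st$tipStates)), function(j) {
      networkTraitLoglik(net, st$tipStates[, j], a, 2)
    }, numeric(1)))
  }
  expect_gte(fit$loglik, llAt(fit$alpha * 2) - 1e-9)
  expect_gte(fit$loglik, llAt(fit$alpha / 2) - 1e-9)
  # two differing tips: rate finite and positive (likelihood plateaus)
  two <- phyloToNetwork(parseNewick("(A:1,B:1);"), "coalescent")
  f2 <- fitErsm(two, setNames(c(1L, 2L), c("A", "B")))
  expect_true(is.finite(f2$alpha) && f2$alpha > 0)
  # identical tips: lower boundary, flagged, no error
  f3 <- fitErsm(two, setNames(c(1L, 1L), c("A", "B")))
  expect_true(f3$boundary)
})

test_that("marginal posteriors match the enumeration oracle on trees", {
  for (s in 1:6) {
    set.seed(3300 + s)
    tr <- ape::rcoal(5)
    st <- setNames(sample.int(2, 5, replace = TRUE), tr$tip.label)
    a <- runif(1, 0.3, 1.5)
    net <- phyloToNetwork(tr, "coalescent")
    asr <- marginalAsr(net, st, a, k = 2)
    oracle <- bruteTraitMarginals(tr, st, 2, a)
    # network node ids equal the tree node ids under phyloToNetwork
    for (v in seq_len(net@nNodes)) {
      expect_equal(unname(asr$posterior[v, ]), oracle[v, ], tolerance = 1e-9)
    }
  }
})

test_that("posteriors are proper and tips are point masses", {
  net <- randomNetwork(8, h = 2, seed = 3400)
  set.seed(4)
  st <- setNames(sample.int(2, 8, replace = TRUE), tipLabels(net))
  asr <- marginalAsr(net, st, 0.6)
  expect_equal(rowSums(asr$posterior), rep(1, nrow(asr$posterior)),
               ignore_attr = TRUE, tolerance = 1e-9)
  for (i in seq_len(8)) {
    expect_equal(unname(asr$posterior[i, st[tipLabels(net)[i]]]), 1)
  }
  # unanimity: all tips in one state make it the modal state everywhere
  same <- setNames(rep(2L, 8), tipLabels(net))
  asr2 <- marginalAsr(net, same, 0.6, k = 2)
  expect_true(all(asr2$posterior[, 2] >= asr2$posterior[, 1]))
})

test_that("state relabeling permutes posteriors identically", {
  net <- randomNetwork(6, h = 1, seed = 3500)
  set.seed(5)
  st <- setNames(sample.int(3, 6, replace = TRUE), tipLabels(net))
  a <- 0.7
  asr1 <- marginalAsr(net, st, a, k = 3)
  relab <- c(2L, 3L, 1L)
  asr2 <- marginalAsr(net, setNames(relab[st], names(st)), a, k = 3)
  expect_equal(asr2$posterior[, relab], asr1$posterior, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("a short terminal branch pulls the parent toward the tip state", {
  mk <- function(len) {
    phyloToNetwork(parseNewick(sprintf("((A:%g,B:1):1,C:2);", len)), "coalescent")
  }
  st <- setNames(c(1L, 2L, 2L), c("A", "B", "C"))
  shortT <- marginalAsr(mk(0.001), st, 0.8, k = 2)
  # with a zero-ish branch the parent of A must carry A's state strongly
  longT <- marginalAsr(mk(1), st, 0.8, k = 2)
  pShort <- shortT$posterior["node5", 1]
  pLong <- longT$posterior["node5", 1]
  expect_gt(pShort, pLong)
})

test_that("reconstructAll runs the three traits and is deterministic", {
  sc <- studyScenario(21, nIngroup = 8)
  res <- reconstructAll(sc$network, sc$traits)
  expect_named(res$alpha, c("longevity", "fruit", "environment"))
  expect_equal(sort(unique(res$table$trait)),
               sort(c("longevity", "fruit", "environment")))
  post <- res$results$longevity$posterior
  expect_equal(rowSums(post), rep(1, nrow(post)), ignore_attr = TRUE,
               tolerance = 1e-9)
  # identical trait columns give identical reconstructions
  tt <- sc$traits
  tt$fruit <- tt$longevity
  res2 <- reconstructAll(sc$network, tt, traits = c("longevity", "fruit"))
  expect_equal(res2$results$fruit$posterior, res2$results$longevity$posterior)
  # permuting taxon rows leaves posteriors unchanged
  res3 <- reconstructAll(sc$network, sc$traits[rev(seq_len(nrow(sc$traits))), ])
  expect_equal(res3$results$longevity$posterior, res$results$longevity$posterior)
  # missing taxon states error in pre-flight fashion
  expect_error(reconstructAll(sc$network, sc$traits[-1, ]), "without a state")
})
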