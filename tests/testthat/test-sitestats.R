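mkSnp <- function(geno, locus = NULL, pos = NULL, ploidy = 1L) {
  n <- ncol(geno)
  if (is.null(locus)) locus <- rep("L1", n)
  if (is.null(pos)) pos <- seq_len(n)
  snpMatrix(geno, data.frame(locus = locus, pos = pos, ref = "A", alt = "T",
                             stringsAsFactors = FALSE), ploidy = ploidy)
}

test_that("SNP filtering drops monomorphic and high-missing sites, then thins", {
  g <- rbind(i1 = c(0L, 1L, 0L, NA, 1L),
             i2 = c(0L, 0L, 1L, 0L, NA),
             i3 = c(0L, 1L, 1L, 1L, 1L),
             i4 = c(0L, 0L, 0L, 1L, 0L),
             i5 = c(0L, 1L, 0L, 1L, 1L))
  x <- mkSnp(g, pos = c(1L, 2L, 3L, 4L, 5L))
  # site 1 monomorphic; sites 4 and 5 have exactly 20% missing at
  # maxMissing = 0.2 (strict: dropped)
  f <- filterSnps(x, maxMissing = 0.2, thinBp = 0)
  expect_equal(siteInfo(f)$pos, c(2L, 3L))
  # at a laxer threshold they come back
  f2 <- filterSnps(x, maxMissing = 0.21, thinBp = 0)
  expect_equal(siteInfo(f2)$pos, 2:5)
})

test_that("greedy thinning keeps one site per window from the left", {
  g <- matrix(c(0L, 1L), 2, 3, dimnames = list(c("i1", "i2"), NULL))
  x <- mkSnp(g, pos = c(1L, 50L, 101L))
  f <- filterSnps(x, maxMissing = 1, thinBp = 100L)
  expect_equal(siteInfo(f)$pos, c(1L, 101L))
  # gaps larger than the window leave the matrix unchanged
  x2 <- mkSnp(g, pos = c(1L, 150L, 300L))
  expect_equal(siteInfo(filterSnps(x2, maxMissing = 1, thinBp = 100L))$pos,
               c(1L, 150L, 300L))
  # thinning is per locus
  x3 <- mkSnp(g, locus = c("L1", "L1", "L2"), pos = c(1L, 50L, 1L))
  expect_equal(nSites(filterSnps(x3, maxMissing = 1, thinBp = 100L)), 2L)
})

test_that("one SNP per locus keeps a bijection with the loci", {
  g <- matrix(c(0L, 1L), 2, 6, dimnames = list(c("i1", "i2"), NULL))
  x <- mkSnp(g, locus = c("L1", "L1", "L1", "L1", "L1", "L2"),
             pos = c(1L, 2L, 3L, 4L, 5L, 1L))
  r <- oneSnpPerLocus(x)
  expect_equal(nSites(r), 2L)
  expect_equal(sort(unique(siteInfo(r)$locus)), c("L1", "L2"))
  r2 <- oneSnpPerLocus(x, method = "random", seed = 4)
  r3 <- oneSnpPerLocus(x, method = "random", seed = 4)
  expect_identical(siteInfo(r2), siteInfo(r3))
})

test_that("Patterson's D matches direct arithmetic on fixed patterns", {
  # 15 ABBA + 5 BABA haploid fixed sites: D = 10/20 = 0.5
  freq <- rbind(P1 = c(rep(0, 15), rep(1, 5)),
                P2 = c(rep(1, 15), rep(0, 5)),
                P3 = rep(1, 20),
                O  = rep(0, 20))
  d <- pattersonD(freq)
  expect_equal(d$D, 0.5)
  expect_equal(d$nSites, 20L)

  # symmetric counts: D = 0
  freqS <- rbind(P1 = c(0, 1), P2 = c(1, 0), P3 = c(1, 1), O = c(0, 0))
  expect_equal(pattersonD(freqS)$D, 0)

  # swapping P1 and P2 negates D exactly
  d2 <- pattersonD(freq[c(2, 1, 3, 4), ])
  expect_equal(d2$D, -d$D)
})

test_that("f4-ratio equals one for complete sharing and recovers gamma", {
  set.seed(2)
  p2 <- runif(50)
  freq <- rbind(P1 = round(runif(50)), P2 = p2, P3 = p2, O = rep(0, 50))
  expect_equal(f4Ratio(freq)$f, 1)
  # no gene flow: f compatible with zero within jackknife error
  net <- parseExtendedNewick("(((P1:1,P2:1):1,P3:2):1,O:3);", "coalescent")
  ex <- expandPopulations(net, 6, eps = 0.01)
  sim <- simulateGeneTrees(simConfig(ex$network, nLoci = 3000, seed = 14))
  snp <- simulateSnpMatrix(sim)
  fr <- popFreqs(snp, ex$popMap)
  f0 <- f4Ratio(fr$freq[c("P1", "P2", "P3", "O"), ])
  expect_lt(abs(f0$fRaw), 3 * f0$se + 0.02)
})

test_that("BH adjustment matches hand computation and is permutation-stable", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdrAdjust(0.2), 0.2)
  p <- c(0.001, 0.2, 0.013, 0.8, 0.04)
  q <- fdrAdjust(p)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(fdrAdjust(p[perm]), q[perm])
  expect_error(fdrAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("simple-matching similarity counts matches over comparable sites", {
  g <- rbind(a = c(0L, 1L, 0L, 1L),
             b = c(0L, 1L, 0L, 1L),
             c = c(1L, 0L, 1L, 0L),
             d = c(0L, 1L, 1L, NA))
  S <- simpleMatchingSimilarity(mkSnp(g))
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], 0)
  expect_equal(S["a", "d"], 2 / 3)
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, 4))
  # site order invariance
  S2 <- simpleMatchingSimilarity(mkSnp(g[, c(3, 1, 4, 2)]))
  expect_equal(S2, S)
  # pairs with no comparable sites are NA with a warning
  g2 <- rbind(a = c(0L, NA), b = c(NA, 1L))
  expect_warning(S3 <- simpleMatchingSimilarity(mkSnp(g2)), "comparable")
  expect_true(is.na(S3["a", "b"]))
})

test_that("f-branch reduces to the floored f4-ratio for singleton clades", {
  tree <- parseNewick("(((P1:1,P2:1):1,P3:2):1,O:3);")
  set.seed(3)
  freq <- rbind(P1 = round(runif(200)), P2 = round(runif(200)),
                P3 = round(runif(200)), O = rep(0, 200))
  fb <- fBranch(tree, list(freq = freq), outgroup = "O")
  f23 <- f4Ratio(freq[c("P1", "P2", "P3", "O"), ])
  expect_equal(fb$matrix["P2", "P3"], max(0, f23$fRaw))
  # P3 is sister to the (P1,P2) clade: cells where the candidate sits in
  # the branch or its sister are undefined
  expect_true(is.na(fb$matrix["P2", "P1"]))
  expect_true(is.na(fb$matrix["P1,P2", "P1"]))
  expect_error(fBranch(ape::unroot(tree), list(freq = freq), "O"), "rooted")
})

test_that("f-branch flags the true donor/recipient pair under introgression", {
  base <- parseExtendedNewick("((((P1:1,P2:1):1,P3:2):1,P4:3):1,O:4);",
                              "coalescent")
  ex <- expandPopulations(base, 4, eps = 0.01)
  net <- addHybridEdge(ex$network, donor = ex$popMap$P3,
                       recipient = ex$popMap$P2, at = 0.05, gamma = 0.3)
  sim <- simulateGeneTrees(simConfig(net, nLoci = 3000, seed = 15))
  snp <- simulateSnpMatrix(sim)
  fr <- popFreqs(snp, ex$popMap)
  sp <- parseNewick("((((P1:1,P2:1):1,P3:2):1,P4:3):1,O:4);")
  fb <- fBranch(sp, fr, outgroup = "O")
  top <- which(fb$matrix == max(fb$matrix, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(rownames(fb$matrix)[top[1]], "P2")
  expect_equal(colnames(fb$matrix)[top[2]], "P3")
  expect_lt(fb$q["P2", "P3"], 0.05)
})
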