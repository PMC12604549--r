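## Multispecies-coalescent simulation on a species network: gene trees,
## among-locus rate scaling, infinite-sites SNP matrices and discrete trait
## histories.  All randomness is driven by counter-derived per-locus
## substreams of a single root seed, so locus i is byte-reproducible
## independently of the number of loci simulated.

#' Simulation configuration
#'
#' Bundles the species network (edge lengths in coalescent units) with the
#' simulation parameters and validates them.
#'
#' @param network a time-consistent \linkS4class{SpeciesNetwork} in
#'   coalescent units.
#' @param nLoci number of loci.
#' @param seed integer root seed (mandatory).
#' @param sigmaRate standard deviation of log substitution-rate multipliers
#'   (lognormal; 0 = constant rate).
#' @param meanlogRate mean of the log multipliers.
#' @param mTax per-locus probability of dropping each taxon (gene trees of
#'   unequal size), in [0, 1).
#' @param mGt per-genotype missing rate for the SNP matrix, in [0, 1).
#' @param locusLength locus length in bp, used for SNP positioning.
#' @return an object of class \code{"simConfig"}.
#' @export
simConfig <- function(network, nLoci, seed, sigmaRate = 0, meanlogRate = 0,
                      mTax = 0, mGt = 0, locusLength = 300L) {
  stopifnot(is(network, "SpeciesNetwork"))
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (nLoci < 1) stop("nLoci must be positive")
  if (sigmaRate < 0) stop("sigmaRate must be >= 0")
  if (mTax < 0 || mTax >= 1) stop("mTax must lie in [0, 1)")
  if (mGt < 0 || mGt >= 1) stop("mGt must lie in [0, 1)")
  if (locusLength < 1) stop("locusLength must be >= 1")
  ed <- network@edges
  hyb <- hybridNodes(network)
  if (length(hyb)) {
    g <- ed$gamma[ed$child %in% hyb]
    if (any(is.na(g))) stop("inheritance probability (gamma) missing on a hybrid edge")
  }
  structure(list(network = network, nLoci = as.integer(nLoci),
                 seed = as.integer(seed), sigmaRate = sigmaRate,
                 meanlogRate = meanlogRate, mTax = mTax, mGt = mGt,
                 locusLength = as.integer(locusLength)),
            class = "simConfig")
}

# Per-locus parent tables for the C++ simulator.
.simTables <- function(net) {
  ed <- net@edges
  n <- net@nNodes
  times <- nodeTimes(net)
  parent1 <- integer(n); parent2 <- integer(n); probTo1 <- rep(1, n)
  for (v in seq_len(n)) {
    rows <- which(ed$child == v)
    if (length(rows) >= 1L) parent1[v] <- ed$parent[rows[1]]
    if (length(rows) == 2L) {
      parent2[v] <- ed$parent[rows[2]]
      probTo1[v] <- ed$gamma[rows[1]]
    }
  }
  # children must precede parents even at equal times (zero-length hybrid
  # edges): stable time sort of a topological (child-first) order
  kidsLeft <- tabulate(ed$parent, nbins = n)
  topo <- integer(0)
  queue <- which(kidsLeft == 0L & (seq_len(n) %in% c(ed$child, net@root)))
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    topo <- c(topo, v)
    for (p in c(parent1[v], parent2[v])) {
      if (p == 0L) next
      kidsLeft[p] <- kidsLeft[p] - 1L
      if (kidsLeft[p] == 0L) queue <- c(queue, p)
    }
  }
  # hybrid children count twice toward distinct parents; dedupe
  topo <- unique(topo)
  procOrder <- topo[order(times[topo])]
  root <- net@root
  procOrder <- c(setdiff(procOrder, root), root)
  list(procOrder = as.integer(procOrder), times = times,
       parent1 = parent1, parent2 = parent2, probTo1 = probTo1,
       hybrid = hybridNodes(net))
}

# Build an ape phylo from the C++ merger record (a, b, t), with internal
# nodes renumbered so the root is ntip + 1.
.mergersToPhylo <- function(a, b, t, tipLabels) {
  k <- length(tipLabels)
  nm <- k - 1L
  if (length(a) != nm) stop("incomplete coalescence record")
  if (k == 1L) stop("cannot build a tree with a single tip")
  ids <- function(x) ifelse(x <= k, x, k + (nm - (x - k)) + 1L)
  parentRaw <- rep(seq_len(nm) + k, each = 2L)
  childRaw <- as.integer(rbind(a, b))
  childTime <- c(rep(0, k), t)[childRaw]
  edge <- cbind(ids(parentRaw), ids(childRaw))
  storage.mode(edge) <- "integer"
  len <- rep(t, each = 2L) - childTime
  structure(list(edge = edge, edge.length = len, tip.label = tipLabels,
                 Nnode = nm), class = "phylo")
}

#' Simulate gene trees under the coalescent on a network
#'
#' Backward-in-time multispecies coalescent: within each network edge,
#' k lineages coalesce at rate k(k-1)/2 per coalescent unit; at a hybrid
#' node each lineage independently follows a parent edge with probability
#' \eqn{\gamma}; above the root, coalescence continues until a single
#' lineage remains.  Output trees are ultrametric in coalescent units.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return an object of class \code{"simResult"}: a list with
#'   \code{coalTrees} (multiPhylo, coalescent units), \code{tipSets}
#'   (taxa present per locus), \code{hybridArrivals}/\code{hybridToFirst}
#'   (per-locus lineage routing at each hybrid node) and \code{truth}
#'   (network, seed, config).
#' @export
simulateGeneTrees <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  net <- cfg$network
  tb <- .simTables(net)
  ntip <- nTips(net)
  tipSets <- vector("list", cfg$nLoci)
  for (i in seq_len(cfg$nLoci)) {
    keep <- seq_len(ntip)
    if (cfg$mTax > 0) {
      u <- .locusUniforms(cfg$seed, i, 101, ntip)
      keep <- which(u >= cfg$mTax)
      if (length(keep) < 2L) {
        # keep the two taxa with the largest draws so every locus yields a tree
        keep <- order(u, decreasing = TRUE)[1:2]
      }
    }
    tipSets[[i]] <- as.integer(keep)
  }
  raw <- .simCoalescentBatch(tb$procOrder, tb$times, tb$parent1, tb$parent2,
                             tb$probTo1, as.integer(tb$hybrid), tipSets,
                             as.double(cfg$seed), 0)
  labs <- tipLabels(net)
  trees <- vector("list", cfg$nLoci)
  for (i in seq_len(cfg$nLoci)) {
    rec <- raw$loci[[i]]
    trees[[i]] <- .mergersToPhylo(rec$a, rec$b, rec$t, labs[tipSets[[i]]])
  }
  class(trees) <- "multiPhylo"
  structure(list(coalTrees = trees,
                 tipSets = lapply(tipSets, function(k) labs[k]),
                 hybridArrivals = raw$hybridArrivals,
                 hybridToFirst = raw$hybridToFirst,
                 truth = list(network = net, seed = cfg$seed, config = cfg)),
            class = "simResult")
}

#' Scale coalescent-unit trees to substitution units
#'
#' Multiplies each tree's branch lengths by an i.i.d. lognormal rate
#' multiplier (one per locus), emulating among-locus substitution-rate
#' variation.  The true multipliers are recorded.
#'
#' @param sim a \code{"simResult"} (or a multiPhylo plus seed).
#' @param sigmaRate,meanlogRate lognormal parameters of the multipliers;
#'   with \code{sigmaRate = 0} every multiplier equals
#'   \code{exp(meanlogRate)} (the lognormal median).
#' @param seed root seed; defaults to the simulation seed.
#' @return the input object with \code{subsTrees} (multiPhylo) and
#'   \code{rateMultipliers} added.
#' @export
scaleToSubstitutions <- function(sim, sigmaRate = NULL, meanlogRate = NULL,
                                 seed = NULL) {
  stopifnot(inherits(sim, "simResult"))
  cfg <- sim$truth$config
  if (is.null(sigmaRate)) sigmaRate <- cfg$sigmaRate
  if (is.null(meanlogRate)) meanlogRate <- cfg$meanlogRate
  if (is.null(seed)) seed <- cfg$seed
  if (sigmaRate < 0) stop("sigmaRate must be >= 0")
  n <- length(sim$coalTrees)
  mult <- numeric(n)
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    z <- if (sigmaRate == 0) 0 else {
      u <- .locusUniforms(seed, i, 202, 2)
      sqrt(-2 * log(u[1])) * cos(2 * pi * u[2]) # Box-Muller standard normal
    }
    mult[i] <- exp(meanlogRate + sigmaRate * z)
    tr <- sim$coalTrees[[i]]
    tr$edge.length <- tr$edge.length * mult[i]
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"
  sim$subsTrees <- trees
  sim$rateMultipliers <- mult
  sim
}

#' Simulate a biallelic SNP matrix from gene trees
#'
#' Places one infinite-sites mutation per locus on a branch chosen with
#' probability proportional to branch length; tips below the branch carry
#' the derived allele.  Haploid genotypes are 0/1; positions are uniform in
#' [1, locusLength]; genotypes are masked to missing at rate \code{mGt}.
#' Loci whose gene tree has zero total length are skipped with a warning.
#'
#' @param sim a \code{"simResult"} from \code{\link{simulateGeneTrees}}.
#' @param mGt,locusLength,seed override the corresponding config values.
#' @return a \linkS4class{SNPMatrix} with one site per retained locus.
#' @export
simulateSnpMatrix <- function(sim, mGt = NULL, locusLength = NULL, seed = NULL) {
  stopifnot(inherits(sim, "simResult"))
  cfg <- sim$truth$config
  if (is.null(mGt)) mGt <- cfg$mGt
  if (is.null(locusLength)) locusLength <- cfg$locusLength
  if (is.null(seed)) seed <- cfg$seed
  inds <- tipLabels(sim$truth$network)
  n <- length(sim$coalTrees)
  geno <- matrix(NA_integer_, nrow = length(inds), ncol = n,
                 dimnames = list(inds, NULL))
  locus <- character(n); pos <- integer(n); keep <- logical(n)
  for (i in seq_len(n)) {
    tr <- sim$coalTrees[[i]]
    el <- tr$edge.length
    tot <- sum(el)
    if (!is.finite(tot) || tot <= 0) {
      warning(sprintf("locus %d skipped: zero total tree length", i))
      next
    }
    u <- .locusUniforms(seed, i, 303, 2 + length(inds))
    br <- findInterval(u[1] * tot, cumsum(el)) + 1L
    carriers <- .tipsBelow(tr, tr$edge[br, 2])
    g <- integer(length(tr$tip.label))
    g[carriers] <- 1L
    row <- setNames(rep(NA_integer_, length(inds)), inds)
    row[tr$tip.label] <- g
    if (mGt > 0) {
      mask <- u[-(1:2)][seq_along(inds)] < mGt
      row[mask] <- NA_integer_
    }
    geno[, i] <- row
    locus[i] <- sprintf("L%04d", i)
    pos[i] <- 1L + as.integer(floor(u[2] * locusLength))
    keep[i] <- TRUE
  }
  geno <- geno[, keep, drop = FALSE]
  sites <- data.frame(locus = locus[keep], pos = pmin(pos[keep], locusLength),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  new("SNPMatrix", genotypes = geno, sites = sites, ploidy = 1L)
}

# tip indices below a node (the node itself if a tip)
.tipsBelow <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Simulate discrete trait histories on a network
#'
#' For each trait, samples a displayed tree according to the
#' \eqn{\gamma} probabilities, draws the root state uniformly, and evolves
#' a k-state equal-rates Markov chain down the tree.
#'
#' @param net a calibrated (ultrametric) SpeciesNetwork.
#' @param alpha substitution rate of the equal-rates model.
#' @param k number of states.
#' @param nTraits number of independent traits.
#' @param seed integer seed.
#' @return list with \code{tipStates} (taxa x traits matrix of integer
#'   states 1..k) and \code{rootStates}.
#' @export
simulateTraitsOnNetwork <- function(net, alpha, k = 2L, nTraits = 1L, seed = 1L) {
  stopifnot(alpha > 0, k >= 2)
  dts <- displayedTrees(net)
  probs <- vapply(dts, `[[`, numeric(1), "prob")
  labs <- tipLabels(net)
  tips <- matrix(NA_integer_, length(labs), nTraits, dimnames = list(labs, NULL))
  roots <- integer(nTraits)
  for (j in seq_len(nTraits)) {
    u <- .locusUniforms(seed, j, 404, 2 + 2 * net@nNodes)
    ti <- findInterval(u[1] * sum(probs), cumsum(probs)) + 1L
    phy <- dts[[ti]]$phylo
    nn <- length(phy$tip.label) + phy$Nnode
    state <- integer(nn)
    root <- length(phy$tip.label) + 1L
    state[root] <- 1L + as.integer(floor(u[2] * k))
    ui <- 3L
    # cladewise edge order guarantees parents are assigned before children
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
      P <- ersmTransition(k, alpha, phy$edge.length[e])[state[p], ]
      state[c] <- findInterval(u[ui] * sum(P), cumsum(P)) + 1L
      ui <- ui + 1L
    }
    tips[phy$tip.label, j] <- state[seq_along(phy$tip.label)]
    roots[j] <- state[root]
  }
  list(tipStates = tips, rootStates = roots)
}

#' Expand network tips into population samples
#'
#' Replaces each tip of a species network by a clade of \code{n}
#' individuals named \code{<taxon>_1..<taxon>_n}, diverging at time
#' \code{eps} (a shallow within-population coalescent), so that
#' population allele frequencies can be simulated for the site-pattern
#' statistics.  Only tree tips below any hybrid attachment points may be
#' expanded, so expansion is applied to a tree before
#' \code{\link{addHybridEdge}}, or to a network whose reticulations
#' attach above time \code{eps}.
#'
#' @param net a time-consistent SpeciesNetwork.
#' @param n individuals per taxon (scalar or named vector per taxon).
#' @param eps within-population divergence time (default 0.01).
#' @return list with \code{network} (the expanded SpeciesNetwork) and
#'   \code{popMap} (named list: taxon -> individual ids), suitable for
#'   \code{\link{popFreqs}}.
#' @export
expandPopulations <- function(net, n, eps = 0.01) {
  labs <- tipLabels(net)
  if (length(n) == 1L) n <- setNames(rep(n, length(labs)), labs)
  if (!all(labs %in% names(n))) stop("n must name every taxon")
  times <- nodeTimes(net)
  ed <- net@edges
  ntipOld <- length(labs)
  newLabs <- character(0)
  popMap <- list()
  # new tip ids first: individuals of taxon i are consecutive
  for (tax in labs) {
    ids <- paste0(tax, "_", seq_len(n[tax]))
    popMap[[tax]] <- ids
    newLabs <- c(newLabs, ids)
  }
  ntipNew <- length(newLabs)
  shift <- ntipNew - ntipOld   # internal ids move up by this much
  mapOld <- function(v) ifelse(v <= ntipOld, NA_integer_, v + shift)
  ed2 <- data.frame(parent = mapOld(ed$parent), child = mapOld(ed$child),
                    length = ed$length, gamma = ed$gamma)
  # ancestor node of each population replaces the old tip id
  nextInternal <- net@nNodes + shift
  rows <- list()
  tipCursor <- 0L
  for (ti in seq_along(labs)) {
    k <- n[labs[ti]]
    oldRows <- which(ed$child == ti)
    if (k == 1L) {
      ed2$child[oldRows] <- tipCursor + 1L
    } else {
      nextInternal <- nextInternal + 1L
      anc <- nextInternal
      ed2$child[oldRows] <- anc
      ed2$length[oldRows] <- ed$length[oldRows] - eps
      if (any(ed2$length[oldRows] < 0)) {
        stop("eps exceeds the terminal branch length of taxon ", labs[ti])
      }
      for (j in seq_len(k)) {
        rows[[length(rows) + 1L]] <- data.frame(parent = anc,
                                                child = tipCursor + j,
                                                length = eps, gamma = NA_real_)
      }
    }
    tipCursor <- tipCursor + k
  }
  ed2 <- rbind(ed2, do.call(rbind, rows))
  out <- speciesNetwork(ed2, newLabs, lengthUnit = net@lengthUnit)
  validObject(out)
  list(network = out, popMap = popMap)
}
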