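# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: quartet topologies come from ape pruning, trait
# likelihoods from exhaustive state enumeration.

# Brute-force topology weights: prune every one-tip-per-group combination
# with ape::keep.tip and read the split off the pruned quartet.
bruteQuartetWeights <- function(tree, grouping) {
  gidx <- lapply(grouping@groups[1:4], function(g) intersect(g, tree$tip.label))
  if (any(vapply(gidx, length, 1L) == 0L)) return(rep(NA_real_, 3))
  combos <- expand.grid(gidx, stringsAsFactors = FALSE)
  w <- numeric(3)
  for (r in seq_len(nrow(combos))) {
    tips <- as.character(unlist(combos[r, ]))
    sub <- ape::keep.tip(tree, tips)
    sub <- ape::unroot(sub)
    if (sub$Nnode == 2L) {
      # resolved: find the cherry pairing around the internal edge
      inner <- which(sub$edge[, 2] > length(sub$tip.label))
      part <- sub$edge[sub$edge[, 1] == sub$edge[inner, 2], 2]
      part <- sub$tip.label[part[part <= length(sub$tip.label)]]
      if (length(part) != 2L) {
        part <- setdiff(sub$tip.label, part)
      }
      pos <- sort(match(part, tips))
      pairing <- if (identical(pos, c(1L, 2L)) || identical(pos, c(3L, 4L))) 1L
                 else if (identical(pos, c(1L, 3L)) || identical(pos, c(2L, 4L))) 2L
                 else 3L
      w[pairing] <- w[pairing] + 1
    } else {
      w <- w + 1 / 3
    }
  }
  w / nrow(combos)
}

# Exhaustive-likelihood oracle: sum over all internal-state assignments.
bruteTraitLoglik <- function(phy, tipStates, k, alpha) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  ints <- (ntip + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(ints))))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tipStates[phy$tip.label]
    st[ints] <- grid[r, ]
    p <- 1 / k
    for (e in seq_len(nrow(phy$edge))) {
      P <- ersmTransition(k, alpha, phy$edge.length[e])
      p <- p * P[st[phy$edge[e, 1]], st[phy$edge[e, 2]]]
    }
    tot <- tot + p
  }
  log(tot)
}

# Exhaustive marginal posteriors at every node.
bruteTraitMarginals <- function(phy, tipStates, k, alpha) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  ints <- (ntip + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(ints))))
  M <- matrix(0, nn, k)
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tipStates[phy$tip.label]
    st[ints] <- grid[r, ]
    p <- 1 / k
    for (e in seq_len(nrow(phy$edge))) {
      P <- ersmTransition(k, alpha, phy$edge.length[e])
      p <- p * P[st[phy$edge[e, 1]], st[phy$edge[e, 2]]]
    }
    M[cbind(seq_len(nn), st)] <- M[cbind(seq_len(nn), st)] + p
  }
  M / rowSums(M)
}

# Random level-1 time-consistent network built from a coalescent tree by
# adding hybrid edges between taxa whose terminal branches overlap in time.
randomNetwork <- function(ntax, h, seed, gammaRange = c(0.1, 0.5)) {
  set.seed(seed)
  h <- min(h, ntax %/% 3)
  for (attempt in 1:40) {
    tr <- ape::rcoal(ntax)
    tr$edge.length <- tr$edge.length * 2
    net <- phyloToNetwork(tr, "coalescent")
    ok <- TRUE
    for (j in seq_len(h)) {
      ed <- net@edges
      times <- nodeTimes(net)
      term <- which(ed$child <= nTips(net))
      added <- FALSE
      for (try2 in 1:30) {
        pick <- sample(term, 2)
        lo <- max(times[ed$child[pick]])
        hi <- min(times[ed$parent[pick]])
        if (hi - lo < 1e-3) next
        at <- runif(1, lo + 1e-4, hi - 1e-4)
        g <- runif(1, gammaRange[1], gammaRange[2])
        cand <- tryCatch(addHybridEdge(net, tipLabels(net)[ed$child[pick[1]]],
                                       tipLabels(net)[ed$child[pick[2]]],
                                       at = at, gamma = g),
                         error = function(e) NULL)
        if (!is.null(cand)) { net <- cand; added <- TRUE; break }
      }
      if (!added) { ok <- FALSE; break }
    }
    if (ok) return(net)
  }
  stop("could not build a random network")
}

# Random tree with polytomies and small taxon groups for weighting tests.
randomGroupedTree <- function(ntax, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntax)
  tr$edge.length <- pmax(tr$edge.length, 1e-3)
  if (runif(1) < 0.5) {
    tr$edge.length[sample(nrow(tr$edge), max(1, ntax %/% 4))] <- 0
    tr <- ape::di2multi(tr, tol = 1e-9)
  }
  tips <- sample(tr$tip.label)
  sizes <- pmin(1 + rpois(4, 0.8), 3)
  while (sum(sizes) > length(tips)) sizes <- pmax(sizes - 1, 1)
  idx <- split(tips[seq_len(sum(sizes))], rep(1:4, sizes))
  grouping <- groupingConfig(idx[[1]], idx[[2]], idx[[3]], idx[[4]])
  list(tree = tr, grouping = grouping)
}
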