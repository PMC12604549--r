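## Candidate-network scoring: expected and observed quartet concordance
## factors, multinomial pseudolikelihood, support classification, outgroup
## exclusion, and prevailing-network selection across resamplings.

# Quartet pairing convention (sorted taxa q1 < q2 < q3 < q4):
#   1 = q1q2|q3q4,  2 = q1q3|q2q4,  3 = q1q4|q2q3.

# CF triple of a single displayed tree for one quartet, from its patristic
# distances: the cherry pairing minimizes d(x,y)+d(z,w); the internal path
# length t gives CFs (1 - (2/3)exp(-t), (1/3)exp(-t), (1/3)exp(-t)).
.treeQuartetCF <- function(D, q) {
  s <- c(D[q[1], q[2]] + D[q[3], q[4]],
         D[q[1], q[3]] + D[q[2], q[4]],
         D[q[1], q[4]] + D[q[2], q[3]])
  topo <- which.min(s)
  t <- (max(s) - s[topo]) / 2
  if (abs(max(s) - min(s)) < 1e-12) t <- 0
  cf <- rep(exp(-t) / 3, 3)
  cf[topo] <- 1 - 2 / 3 * exp(-t)
  cf
}

#' Expected quartet concordance factors under the coalescent on a network
#'
#' Computed as the \eqn{\gamma}-weighted mixture of the displayed trees'
#' coalescent CFs: restricted to a quartet, a displayed tree with internal
#' path length t (coalescent units) yields CFs
#' \eqn{(1 - (2/3)e^{-t}, (1/3)e^{-t}, (1/3)e^{-t})}.  The mixture is exact
#' whenever, restricted to the quartet, lineages cannot coalesce between
#' the two hybrid-edge endpoints inside a reticulation cycle (in
#' particular when each hybrid subtends a single sampled taxon).
#'
#' @param net a \linkS4class{SpeciesNetwork} in coalescent units.
#' @param quartet character vector of 4 taxon names.
#' @param cache optional precomputed \code{\link{displayedTreeCache}}.
#' @return named numeric length-3 CF triple (pairing convention on the
#'   sorted quartet), summing to 1.
#' @export
expectedQuartetCF <- function(net, quartet, cache = NULL) {
  stopifnot(length(quartet) == 4L)
  q <- sort(quartet)
  if (is.null(cache)) cache <- displayedTreeCache(net)
  cf <- numeric(3)
  for (i in seq_along(cache$coph)) {
    cf <- cf + cache$probs[i] * .treeQuartetCF(cache$coph[[i]], q)
  }
  names(cf) <- c(paste0(q[1], q[2], "|", q[3], q[4]),
                 paste0(q[1], q[3], "|", q[2], q[4]),
                 paste0(q[1], q[4], "|", q[2], q[3]))
  cf
}

#' Precompute displayed-tree distance matrices of a network
#'
#' @param net a SpeciesNetwork with all edge lengths set.
#' @return list with \code{probs} and \code{coph} (one patristic matrix
#'   per displayed tree), reusable across quartets and \eqn{\gamma}
#'   updates of fixed topology.
#' @export
displayedTreeCache <- function(net) {
  if (any(is.na(net@edges$length))) stop("missing edge lengths")
  dts <- displayedTrees(net)
  labs <- tipLabels(net)
  list(probs = vapply(dts, `[[`, numeric(1), "prob"),
       coph = lapply(dts, function(dt) ape::cophenetic.phylo(dt$phylo)[labs, labs]),
       choice = lapply(dts, `[[`, "choice"))
}

#' Expected CF table for many quartets
#'
#' @param net a SpeciesNetwork in coalescent units.
#' @param quartets matrix/data.frame of taxon names (one quartet per row),
#'   or NULL for all quartets.
#' @return data.frame with taxa columns \code{t1..t4} (sorted) and
#'   \code{ecf1..ecf3}.
#' @export
expectedQuartetCFTable <- function(net, quartets = NULL) {
  labs <- tipLabels(net)
  if (is.null(quartets)) {
    quartets <- t(combn(sort(labs), 4))
  }
  quartets <- as.matrix(quartets)
  cache <- displayedTreeCache(net)
  out <- matrix(0, nrow(quartets), 3)
  sortedQ <- t(apply(quartets, 1, sort))
  for (i in seq_len(nrow(quartets))) {
    q <- sortedQ[i, ]
    cf <- numeric(3)
    for (k in seq_along(cache$coph)) {
      cf <- cf + cache$probs[k] * .treeQuartetCF(cache$coph[[k]], q)
    }
    out[i, ] <- cf
  }
  data.frame(t1 = sortedQ[, 1], t2 = sortedQ[, 2], t3 = sortedQ[, 3],
             t4 = sortedQ[, 4], ecf1 = out[, 1], ecf2 = out[, 2],
             ecf3 = out[, 3], stringsAsFactors = FALSE)
}

#' Observed quartet concordance factors from gene trees
#'
#' A gene tree is informative for a quartet iff it contains all four taxa
#' and resolves them; proportions are over informative trees.
#'
#' @param trees list / multiPhylo of gene trees (taxa may be missing).
#' @param taxa taxa to consider (default: union over trees).
#' @param quartets optional matrix of quartets (rows of 4 taxon names);
#'   default all \code{choose(n,4)} quartets of \code{taxa}.
#' @return data.frame with \code{t1..t4} (sorted), \code{cf1..cf3}
#'   (pairing convention; NA when n = 0) and \code{n} informative trees.
#' @export
observedQuartetCF <- function(trees, taxa = NULL, quartets = NULL) {
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  } else taxa <- sort(taxa)
  if (is.null(quartets)) quartets <- t(combn(taxa, 4))
  quartets <- as.matrix(quartets)
  sortedQ <- t(apply(quartets, 1, sort))
  nq <- nrow(sortedQ)
  counts <- matrix(0, nq, 3)
  ntot <- numeric(nq)
  # per-quartet tip-position indices into `taxa`
  qidx <- matrix(match(sortedQ, taxa), nq, 4)
  for (tr in trees) {
    pres <- match(taxa, tr$tip.label)
    arr <- .treeArrays(tr)
    n <- length(taxa)
    # mrca depth matrix over present taxa
    M <- matrix(NA_real_, n, n)
    presIdx <- which(!is.na(pres))
    for (ii in seq_along(presIdx)) {
      for (jj in seq_len(ii - 1L)) {
        a <- presIdx[ii]; b <- presIdx[jj]
        M[a, b] <- M[b, a] <- .mrcaDepth(arr, pres[a], pres[b])
      }
    }
    d12 <- M[cbind(qidx[, 1], qidx[, 2])]
    d34 <- M[cbind(qidx[, 3], qidx[, 4])]
    d13 <- M[cbind(qidx[, 1], qidx[, 3])]
    d24 <- M[cbind(qidx[, 2], qidx[, 4])]
    d14 <- M[cbind(qidx[, 1], qidx[, 4])]
    d23 <- M[cbind(qidx[, 2], qidx[, 3])]
    s1 <- pmax(d12, d34); s2 <- pmax(d13, d24); s3 <- pmax(d14, d23)
    ok <- !(is.na(s1) | is.na(s2) | is.na(s3))
    if (!any(ok)) next
    mx <- pmax(s1, s2, s3)
    w1 <- ok & s1 == mx; w2 <- ok & s2 == mx; w3 <- ok & s3 == mx
    nw <- w1 + w2 + w3
    resolved <- ok & nw == 1L
    counts[resolved & w1, 1] <- counts[resolved & w1, 1] + 1
    counts[resolved & w2, 2] <- counts[resolved & w2, 2] + 1
    counts[resolved & w3, 3] <- counts[resolved & w3, 3] + 1
    ntot <- ntot + resolved
  }
  cf <- counts / ifelse(ntot > 0, ntot, NA)
  data.frame(t1 = sortedQ[, 1], t2 = sortedQ[, 2], t3 = sortedQ[, 3],
             t4 = sortedQ[, 4], cf1 = cf[, 1], cf2 = cf[, 2], cf3 = cf[, 3],
             n = ntot, stringsAsFactors = FALSE)
}

#' Network pseudo-log-likelihood against observed quartet CFs
#'
#' Multinomial cross-entropy weighted by the per-quartet number of
#' informative gene trees: \eqn{\sum_q n_q \sum_{k=1}^3 \mathrm{obs}_{qk}
#' \log \mathrm{exp}_{qk}}, with expected CFs floored at 1e-12.  Matches
#' the SNaQ-style multinomial pseudolikelihood up to data-only additive
#' constants, so score differences are directly comparable.
#'
#' @param net a SpeciesNetwork in coalescent units.
#' @param cfTable output of \code{\link{observedQuartetCF}} (quartets with
#'   n = 0 are skipped).
#' @return the pseudo-log-likelihood (higher is better).
#' @export
pseudoLoglik <- function(net, cfTable) {
  ecf <- expectedQuartetCFTable(net, cfTable[, c("t1", "t2", "t3", "t4")])
  obs <- as.matrix(cfTable[, c("cf1", "cf2", "cf3")])
  expd <- pmax(as.matrix(ecf[, c("ecf1", "ecf2", "ecf3")]), 1e-12)
  n <- cfTable$n
  ok <- n > 0 & !is.na(obs[, 1])
  sum(n[ok] * rowSums(obs[ok, , drop = FALSE] * log(expd[ok, , drop = FALSE])))
}

#' Fit inheritance probabilities against observed CFs on a fixed topology
#'
#' One-dimensional maximization of the pseudolikelihood over \eqn{\gamma}
#' for each hybrid node (coordinate-wise for several hybrids), with the
#' topology and branch lengths held fixed.  Displayed-tree distances are
#' cached so only the mixture weights change with \eqn{\gamma}.
#'
#' @param net a SpeciesNetwork in coalescent units.
#' @param cfTable observed CF table.
#' @param maxIter coordinate sweeps for h > 1.
#' @return list with \code{gamma} (per hybrid, probability of the first
#'   parent edge), \code{loglik}, and \code{net} (network with updated
#'   \eqn{\gamma}).
#' @export
fitGammaCF <- function(net, cfTable, maxIter = 10L) {
  hyb <- hybridNodes(net)
  if (!length(hyb)) stop("network has no hybrid node")
  cache <- displayedTreeCache(net)
  qs <- as.matrix(cfTable[, c("t1", "t2", "t3", "t4")])
  nq <- nrow(qs)
  # per displayed tree, per quartet CF triples (independent of gamma)
  nT <- length(cache$coph)
  cfArr <- array(0, c(nT, nq, 3))
  for (k in seq_len(nT)) {
    for (i in seq_len(nq)) {
      cfArr[k, i, ] <- .treeQuartetCF(cache$coph[[k]], qs[i, ])
    }
  }
  obs <- as.matrix(cfTable[, c("cf1", "cf2", "cf3")])
  nn <- cfTable$n
  ok <- nn > 0 & !is.na(obs[, 1])
  choiceMat <- do.call(rbind, cache$choice)  # nT x h, kept edge-row indices
  firstRow <- vapply(hyb, function(v) which(net@edges$child == v)[1], 1L)
  score <- function(g) {
    # g: per-hybrid probability of the first parent edge
    pr <- rep(1, nT)
    for (j in seq_along(hyb)) {
      pr <- pr * ifelse(choiceMat[, j] == firstRow[j], g[j], 1 - g[j])
    }
    expd <- apply(cfArr * pr, c(2, 3), sum)
    expd <- pmax(expd, 1e-12)
    sum(nn[ok] * rowSums(obs[ok, , drop = FALSE] * log(expd[ok, , drop = FALSE])))
  }
  g <- vapply(hyb, function(v) {
    rows <- which(net@edges$child == v)
    net@edges$gamma[rows[1]]
  }, numeric(1))
  if (length(hyb) == 1L) {
    opt <- optimize(function(x) score(x), c(0, 1), maximum = TRUE, tol = 1e-8)
    g <- opt$maximum
    ll <- opt$objective
  } else {
    for (it in seq_len(maxIter)) {
      for (j in seq_along(hyb)) {
        gj <- g
        opt <- optimize(function(x) { gj[j] <- x; score(gj) }, c(0, 1),
                        maximum = TRUE, tol = 1e-8)
        g[j] <- opt$maximum
      }
    }
    ll <- score(g)
  }
  ed <- net@edges
  for (j in seq_along(hyb)) {
    rows <- which(ed$child == hyb[j])
    ed$gamma[rows[1]] <- g[j]
    ed$gamma[rows[2]] <- 1 - g[j]
  }
  net@edges <- ed
  list(gamma = setNames(g, net@hybridTags[hyb]), loglik = ll, net = net)
}

#' Classify candidate-network support from pseudolikelihood differences
#'
#' With \eqn{\Delta} = reference score - candidate score (natural-log
#' units): strong when \eqn{\Delta \le 10}, moderate when
#' \eqn{10 < \Delta \le 20}, poor when \eqn{20 < \Delta < 30}, excluded
#' when \eqn{\Delta \ge 30}.  A candidate better than the reference
#' (\eqn{\Delta < 0}) is strong.
#'
#' @param candidateScore,referenceScore pseudo-log-likelihoods on the same
#'   data and reticulation count.
#' @return one of \code{"strong"}, \code{"moderate"}, \code{"poor"},
#'   \code{"excluded_delta"}.
#' @export
classifySupport <- function(candidateScore, referenceScore) {
  delta <- referenceScore - candidateScore
  if (delta <= 10) "strong"
  else if (delta <= 20) "moderate"
  else if (delta < 30) "poor"
  else "excluded_delta"
}

#' Exclude candidates whose reticulation involves the outgroup
#'
#' A candidate is excluded when the outgroup's ancestor path (excluding
#' the root) meets a hybrid node or a non-top node of any reticulation
#' cycle — i.e. when a hybrid edge attaches to the outgroup stem or the
#' outgroup descends from a reticulation.
#'
#' @param candidates list of SpeciesNetwork objects.
#' @param outgroup outgroup taxon label.
#' @return list with \code{retained} and \code{excluded} (both lists of
#'   networks), and \code{flags} (logical, TRUE = excluded).
#' @export
excludeOutgroupReticulations <- function(candidates, outgroup) {
  flags <- vapply(candidates, function(net) {
    tipId <- match(outgroup, net@tipLabels)
    if (is.na(tipId)) stop("outgroup '", outgroup, "' is not a leaf of a candidate")
    ed <- net@edges
    # all ancestors of the outgroup (through every parent edge)
    anc <- integer(0)
    frontier <- tipId
    while (length(frontier)) {
      pars <- unique(ed$parent[ed$child %in% frontier])
      pars <- setdiff(pars, anc)
      anc <- c(anc, pars)
      frontier <- pars
    }
    anc <- setdiff(anc, net@root)
    hyb <- hybridNodes(net)
    if (!length(hyb)) return(FALSE)
    if (length(intersect(anc, hyb))) return(TRUE)
    for (cyc in reticulationCycles(net)) {
      onCycle <- setdiff(cyc$nodes, cyc$top)
      if (length(intersect(anc, c(onCycle, cyc$hybrid)))) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(retained = candidates[!flags], excluded = candidates[flags],
       flags = flags)
}

#' Evaluate candidate networks against gene-tree CFs
#'
#' Scores each candidate by pseudolikelihood, applies the outgroup
#' exclusion, and classifies support relative to the best non-excluded
#' candidate with the same reticulation count.
#'
#' @param candidates list of SpeciesNetwork objects (one resampling).
#' @param cfTable observed CF table for that resampling.
#' @param outgroup outgroup taxon label.
#' @return data.frame with columns \code{candidate}, \code{h},
#'   \code{topology} (canonical string), \code{score}, \code{delta},
#'   \code{class}.
#' @export
evaluateCandidates <- function(candidates, cfTable, outgroup) {
  og <- excludeOutgroupReticulations(candidates, outgroup)
  n <- length(candidates)
  h <- vapply(candidates, nHybrids, 1L)
  topo <- vapply(candidates, canonicalTopology, character(1))
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) score[i] <- pseudoLoglik(candidates[[i]], cfTable)
  cls <- character(n)
  delta <- rep(NA_real_, n)
  for (hh in unique(h)) {
    idx <- which(h == hh & !og$flags)
    if (!length(idx)) next
    ref <- max(score[idx])
    for (i in idx) {
      delta[i] <- ref - score[i]
      cls[i] <- classifySupport(score[i], ref)
    }
  }
  cls[og$flags] <- "excluded_outgroup"
  data.frame(candidate = seq_len(n), h = h, topology = topo, score = score,
             delta = delta, class = cls, stringsAsFactors = FALSE)
}

#' Select the prevailing network(s) across resamplings
#'
#' Majority rule: among reticulation counts for which some topology has
#' strong-or-moderate support in a majority of resamplings, the highest
#' count wins; within it, every topology with strong/moderate support in
#' at least two resamplings is returned, ordered by the number of
#' supporting resamplings and then by mean score.  If no topology meets
#' the two-resampling rule, the best-scoring h = 0 candidate is returned
#' with a warning.
#'
#' @param evals data.frame concatenating \code{\link{evaluateCandidates}}
#'   outputs with an added \code{resampling} column.
#' @return data.frame of selected topologies with columns \code{topology},
#'   \code{h}, \code{nSupporting}, \code{meanScore}.
#' @export
selectPrevailing <- function(evals) {
  stopifnot(all(c("resampling", "h", "topology", "score", "class") %in% names(evals)))
  nRes <- length(unique(evals$resampling))
  ok <- evals$class %in% c("strong", "moderate")
  sup <- evals[ok, , drop = FALSE]
  if (nrow(sup)) {
    # per (h, topology): number of distinct supporting resamplings
    agg <- aggregate(resampling ~ h + topology, data = sup,
                     FUN = function(r) length(unique(r)))
    names(agg)[3] <- "nSupporting"
    sc <- aggregate(score ~ h + topology, data = sup, FUN = mean)
    names(sc)[3] <- "meanScore"
    agg <- merge(agg, sc)
    majority <- agg[agg$nSupporting > nRes / 2, , drop = FALSE]
    if (nrow(majority)) {
      hSel <- max(majority$h)
      out <- agg[agg$h == hSel & agg$nSupporting >= 2L, , drop = FALSE]
      out <- out[order(-out$nSupporting, -out$meanScore), ]
      if (nrow(out)) {
        rownames(out) <- NULL
        return(out[, c("topology", "h", "nSupporting", "meanScore")])
      }
    } else {
      out <- agg[agg$nSupporting >= 2L, , drop = FALSE]
      if (nrow(out)) {
        hSel <- max(out$h)
        out <- out[out$h == hSel, , drop = FALSE]
        out <- out[order(-out$nSupporting, -out$meanScore), ]
        rownames(out) <- NULL
        return(out[, c("topology", "h", "nSupporting", "meanScore")])
      }
    }
  }
  warning("no topology is supported by at least two resamplings; returning the best h = 0 candidate")
  h0 <- evals[evals$h == 0L, , drop = FALSE]
  if (!nrow(h0)) stop("no h = 0 candidate available as fallback")
  best <- h0[which.max(h0$score), , drop = FALSE]
  data.frame(topology = best$topology, h = 0L, nSupporting = 0L,
             meanScore = best$score)
}
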