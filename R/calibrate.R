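## Network calibration: fit ultrametric node ages to gene-tree mean
## pairwise distances, with a power transform on the distance matrix and a
## weighted penalty on changes to the input network's internal branch
## lengths.  Parameterizing by node ages makes ultrametricity and the
## hybrid-below-parents constraint structural rather than penalized.

#' Mean pairwise patristic distances over gene trees
#'
#' @param trees list / multiPhylo of (QC-normalized) gene trees; trees may
#'   miss taxa, in which case they contribute to no pair involving them.
#' @param taxa taxa to include (default: union over trees).
#' @param requireComplete error when some pair is never co-present
#'   (default TRUE); otherwise the entry is NA.
#' @return list with \code{D} (mean distance matrix) and \code{counts}
#'   (trees contributing per pair).
#' @export
meanPairwiseDistances <- function(trees, taxa = NULL, requireComplete = TRUE) {
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  }
  n <- length(taxa)
  S <- matrix(0, n, n, dimnames = list(taxa, taxa))
  Cn <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (tr in trees) {
    pres <- intersect(taxa, tr$tip.label)
    if (length(pres) < 2L) next
    D <- ape::cophenetic.phylo(tr)[pres, pres]
    S[pres, pres] <- S[pres, pres] + D
    Cn[pres, pres] <- Cn[pres, pres] + 1L
  }
  diag(Cn) <- 0L
  out <- S / ifelse(Cn > 0, Cn, NA)
  diag(out) <- 0
  if (requireComplete) {
    bad <- which(is.na(out) & upper.tri(out), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("taxon pairs never co-present in any tree: ",
           paste(sprintf("%s-%s", taxa[bad[, 1]], taxa[bad[, 2]]), collapse = ", "))
    }
  }
  list(D = out, counts = Cn)
}

#' Elementwise power transform of a distance matrix
#'
#' @param D nonnegative matrix.
#' @param p exponent, > 0 (identity at p = 1; order-preserving).
#' @return \code{D^p}.
#' @export
powerTransform <- function(D, p) {
  if (p <= 0) stop("exponent p must be > 0")
  D^p
}

#' Internal-branch penalty weight
#'
#' The ratio of the mean off-diagonal entry of the pairwise distance
#' matrix to the mean initial internal branch length of the network,
#' compensating for the inherently shorter internal branches.
#'
#' @param D taxon pairwise distance matrix.
#' @param net SpeciesNetwork with initial internal branch lengths.
#' @return the weight w.
#' @export
internalWeight <- function(D, net) {
  internal <- .internalEdgeRows(net)
  if (!length(internal)) stop("network has no internal branch")
  l0 <- net@edges$length[internal]
  if (any(is.na(l0))) stop("internal branch lengths missing")
  ml <- mean(l0)
  if (ml <= 0) stop("mean internal branch length is zero; weight undefined")
  mean(D[upper.tri(D)]) / ml
}

# rows of the edge table whose child is an internal node
.internalEdgeRows <- function(net) {
  which(net@edges$child > nTips(net))
}

# Linear model of the expected network distances in the node ages:
# d(i,j) = sum_t P_t * 2 * age(mrca_t(i,j)); rows = taxon pairs, columns =
# internal nodes.  Also returns the internal-edge incidence rows.
.calibrationDesign <- function(net) {
  labs <- tipLabels(net)
  ntip <- length(labs)
  intNodes <- (ntip + 1L):net@nNodes
  dts <- displayedTrees(net)
  pairs <- t(combn(ntip, 2))
  A <- matrix(0, nrow(pairs), length(intNodes))
  for (dt in dts) {
    phy <- dt$phylo
    # mrca of each pair in this displayed tree, mapped to network node ids
    nn <- length(phy$tip.label) + phy$Nnode
    arr <- .treeArrays(phy)
    netIdOf <- integer(nn)
    for (v in seq_len(net@nNodes)) {
      pn <- dt$phyloNode[v]
      if (!is.na(pn) && !is.na(dt$surv[v]) && dt$surv[v] == v) netIdOf[pn] <- v
    }
    tipIdx <- match(labs, phy$tip.label)
    for (r in seq_len(nrow(pairs))) {
      a <- tipIdx[pairs[r, 1]]; b <- tipIdx[pairs[r, 2]]
      # climb to the mrca node id
      da <- arr$depth[a]; db <- arr$depth[b]
      while (da > db) { a <- arr$parent[a]; da <- da - 1L }
      while (db > da) { b <- arr$parent[b]; db <- db - 1L }
      while (a != b) { a <- arr$parent[a]; b <- arr$parent[b] }
      v <- netIdOf[a]
      A[r, v - ntip] <- A[r, v - ntip] + 2 * dt$prob
    }
  }
  internal <- .internalEdgeRows(net)
  E <- matrix(0, length(internal), length(intNodes))
  for (k in seq_along(internal)) {
    e <- internal[k]
    E[k, net@edges$parent[e] - ntip] <- 1
    E[k, net@edges$child[e] - ntip] <- E[k, net@edges$child[e] - ntip] - 1
  }
  list(A = A, E = E, pairs = pairs, intNodes = intNodes,
       l0 = net@edges$length[internal], internalRows = internal)
}

# ages feasible iff every edge has nonnegative implied length
.agesFeasible <- function(net, ages) {
  ntip <- nTips(net)
  ageOf <- c(rep(0, ntip), ages)
  len <- ageOf[net@edges$parent] - ageOf[net@edges$child]
  all(len >= -1e-10) && all(ages >= -1e-10)
}

#' Calibrate (ultrametrize) a network from pairwise distances
#'
#' Minimizes
#' \deqn{F(\mathrm{ages}, p) = \sum_{i<j} [d_{net}(i,j) - \bar D(i,j)^p]^2
#'   + w \sum_{e\ \mathrm{internal}} [l_e(\mathrm{ages}) - l^0_e]^2}
#' over node ages and the exponent \eqn{p \in [p_{init}/10,
#' 10\,p_{init}]}.  Network distances are the \eqn{\gamma}-weighted
#' displayed-tree expectations, which are linear in the ages, so the inner
#' problem is solved by least squares; when the unconstrained solution
#' violates an age-order constraint, a box-constrained multistart
#' refinement in a feasible parameterization takes over.  Terminal
#' branches are unpenalized.
#'
#' @param net SpeciesNetwork (topology and \eqn{\gamma} fixed; initial
#'   internal lengths are the penalty targets).
#' @param D taxon pairwise distance matrix (e.g. from
#'   \code{\link{meanPairwiseDistances}}).
#' @param pInit initial exponent (> 0); the search range is
#'   [pInit/10, pInit*10].
#' @param w internal penalty weight; default
#'   \code{\link{internalWeight}(D, net)}.
#' @param optimizeP logical; FALSE fixes p = pInit.
#' @param multistarts restarts of the constrained refinement.
#' @param seed seed for the multistart jitter.
#' @return list of class \code{"calibratedNetwork"}: \code{network} (edge
#'   lengths from the fitted ages), \code{ages} (internal-node ages),
#'   \code{p}, \code{objective}, \code{terms} (distance and penalty
#'   parts), \code{w}, \code{feasibleLinear}, \code{trace} (monotone
#'   best-so-far objective values).
#' @export
calibrateNetwork <- function(net, D, pInit = 1, w = NULL,
                             optimizeP = TRUE, multistarts = 8L, seed = 1L) {
  stopifnot(is(net, "SpeciesNetwork"), pInit > 0)
  labs <- tipLabels(net)
  if (!all(labs %in% rownames(D))) stop("distance matrix must cover all network taxa")
  D <- D[labs, labs]
  if (is.null(w)) w <- internalWeight(D, net)
  des <- .calibrationDesign(net)
  y0 <- D[cbind(des$pairs[, 1], des$pairs[, 2])]
  sw <- sqrt(w)
  X <- rbind(des$A, sw * des$E)
  trace <- numeric(0)
  qrX <- qr(X)
  solveLinear <- function(p) {
    y <- c(y0^p, sw * des$l0)
    fit <- tryCatch(qr.coef(qrX, y), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit))) {
      # rank deficiency: tiny ridge
      XtX <- crossprod(X) + diag(1e-10, ncol(X))
      fit <- solve(XtX, crossprod(X, y))
    }
    ages <- as.numeric(fit)
    r1 <- des$A %*% ages - y0^p
    r2 <- des$E %*% ages - des$l0
    list(ages = ages, objective = sum(r1^2) + w * sum(r2^2),
         feasible = .agesFeasible(net, ages),
         terms = c(distance = sum(r1^2), penalty = w * sum(r2^2)))
  }
  # the exponent search scores the unconstrained least-squares optimum (a
  # tight lower bound); the age-order constraints are enforced once, at
  # the selected exponent
  solveForP <- function(p, refine = FALSE) {
    sol <- solveLinear(p)
    if (refine && !sol$feasible) {
      ages <- .constrainedAges(net, des, y0^p, sw, multistarts, seed, sol$ages)
      r1 <- des$A %*% ages - y0^p
      r2 <- des$E %*% ages - des$l0
      sol <- list(ages = ages, objective = sum(r1^2) + w * sum(r2^2),
                  feasible = FALSE,
                  terms = c(distance = sum(r1^2), penalty = w * sum(r2^2)))
    }
    sol
  }
  objP <- function(p) {
    v <- solveLinear(p)$objective
    if (!length(trace) || v < min(trace)) trace <<- c(trace, v)
    v
  }
  if (optimizeP) {
    lo <- pInit / 10; hi <- pInit * 10
    # coarse log-spaced grid, then local refinement around the best point
    grid <- exp(seq(log(lo), log(hi), length.out = 25))
    vals <- vapply(grid, objP, numeric(1))
    b <- which.min(vals)
    bl <- if (b == 1) lo else grid[b - 1]
    bh <- if (b == length(grid)) hi else grid[b + 1]
    opt <- optimize(objP, c(bl, bh), tol = 1e-9)
    p <- opt$minimum
    if (vals[b] < opt$objective) p <- grid[b]
  } else {
    p <- pInit
  }
  sol <- solveForP(p, refine = TRUE)
  ages <- pmax(sol$ages, 0)
  ntip <- nTips(net)
  ageOf <- c(rep(0, ntip), ages)
  ed <- net@edges
  ed$length <- pmax(ageOf[ed$parent] - ageOf[ed$child], 0)
  out <- net
  out@edges <- ed
  structure(list(network = out,
                 ages = setNames(ages, des$intNodes),
                 p = p, objective = sol$objective, terms = sol$terms,
                 w = w, feasibleLinear = sol$feasible,
                 trace = sort(trace, decreasing = TRUE)),
            class = "calibratedNetwork")
}

# Box-constrained refinement: root age on the log scale, every other
# internal node's age a logistic fraction of its parents' minimum age.
.constrainedAges <- function(net, des, target, sw, multistarts, seed, warmAges) {
  ntip <- nTips(net)
  intNodes <- des$intNodes
  nInt <- length(intNodes)
  ed <- net@edges
  root <- net@root
  # topological order of internal nodes, root first
  parentsOf <- lapply(intNodes, function(v) ed$parent[ed$child == v])
  ord <- integer(0)
  placed <- c(root)
  while (length(ord) < nInt - 1L) {
    for (k in seq_len(nInt)) {
      v <- intNodes[k]
      if (v %in% placed) next
      if (all(parentsOf[[k]] %in% placed)) {
        ord <- c(ord, k)
        placed <- c(placed, v)
      }
    }
  }
  agesFromPar <- function(par) {
    ages <- numeric(nInt)
    ages[match(root, intNodes)] <- exp(par[1])
    for (i in seq_along(ord)) {
      k <- ord[i]
      pmin_ <- min(ages[match(parentsOf[[k]], intNodes)])
      s <- 1 / (1 + exp(-par[1 + i]))
      ages[k] <- s * pmin_
    }
    ages
  }
  obj <- function(par) {
    ages <- agesFromPar(par)
    sum((des$A %*% ages - target)^2) + sum((sw * (des$E %*% ages - des$l0))^2)
  }
  best <- NULL
  u <- .locusUniforms(seed, 1, 707, multistarts * (nInt))
  dim(u) <- c(multistarts, nInt)
  rootGuess <- max(target) / 2
  # warm start from the clipped unconstrained solution
  warmPar <- tryCatch({
    wa <- pmax(warmAges, 1e-8)
    rootAge <- wa[match(root, intNodes)]
    par <- c(log(rootAge), numeric(length(ord)))
    for (i in seq_along(ord)) {
      k <- ord[i]
      pm_ <- min(wa[match(parentsOf[[k]], intNodes)])
      s <- min(max(wa[k] / pm_, 1e-4), 1 - 1e-4)
      par[1 + i] <- log(s / (1 - s))
    }
    par
  }, error = function(e) NULL)
  starts <- list()
  if (!is.null(warmPar)) starts[[1]] <- warmPar
  for (s in seq_len(multistarts)) {
    starts[[length(starts) + 1L]] <- c(log(rootGuess * (0.5 + u[s, 1])),
                                       qnorm(pmin(pmax(u[s, -1], 0.02), 0.98)))
  }
  for (par0 in starts) {
    o <- tryCatch(optim(par0, obj, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("constrained age optimization failed for every start")
  agesFromPar(best$par)
}

#' Ultrametricity check of a network
#'
#' Computes all root-to-leaf path lengths (over every up-down path through
#' the network) and reports the maximum deviation from the root age
#' (taken as the maximum path length).
#'
#' @param net SpeciesNetwork with edge lengths.
#' @param tol pass threshold on the maximum deviation (default 1e-8).
#' @return list with \code{pass}, \code{maxDeviation}, \code{rootAge}.
#' @export
ultrametricCheck <- function(net, tol = 1e-8) {
  ed <- net@edges
  if (any(is.na(ed$length))) stop("missing edge lengths")
  ntip <- nTips(net)
  # depths of all paths root -> leaf
  depths <- numeric(0)
  walk <- function(v, d) {
    kids <- which(ed$parent == v)
    if (!length(kids)) {
      depths <<- c(depths, d)
      return(invisible(NULL))
    }
    for (e in kids) walk(ed$child[e], d + ed$length[e])
  }
  walk(net@root, 0)
  rootAge <- max(depths)
  dev <- max(abs(depths - rootAge))
  list(pass = dev < tol, maxDeviation = dev, rootAge = rootAge)
}
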