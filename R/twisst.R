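## Topology weighting for four taxon groups (TWISST-style), majority-rule
## support assignment, and the chi-square test of the ILS null that the two
## non-major topologies are equally frequent.

# Pairing convention for a quartet (one tip from each of P1..P4):
#   topology 1 = P1P2 | P3P4,  topology 2 = P1P3 | P2P4,  topology 3 = P1P4 | P2P3.

# parent and depth arrays of a phylo (depth = edges from root)
.treeArrays <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  depth <- integer(nn)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  depth[root] <- 0L
  stack <- root
  kidsOf <- split(phy$edge[, 2], phy$edge[, 1])
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    kids <- kidsOf[[as.character(v)]]
    if (!is.null(kids)) {
      depth[kids] <- depth[v] + 1L
      stack <- c(stack, kids)
    }
  }
  list(parent = parent, depth = depth, root = root)
}

# depth of the MRCA of tips a and b
.mrcaDepth <- function(arr, a, b) {
  da <- arr$depth[a]; db <- arr$depth[b]
  while (da > db) { a <- arr$parent[a]; da <- da - 1L }
  while (db > da) { b <- arr$parent[b]; db <- db - 1L }
  while (a != b) { a <- arr$parent[a]; b <- arr$parent[b]; da <- da - 1L }
  da
}

# quartet vote for tips q[1..4] (tree indices): numeric length-3 vector
# splitting one vote across the pairings compatible with the induced quartet
.quartetVote <- function(arr, q) {
  pairs <- rbind(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 4L), c(2L, 3L))
  pairing <- c(1L, 1L, 2L, 2L, 3L, 3L)
  d <- integer(6)
  for (i in 1:6) d[i] <- .mrcaDepth(arr, q[pairs[i, 1]], q[pairs[i, 2]])
  top <- which(d == max(d))
  winners <- unique(pairing[top])
  v <- numeric(3)
  v[winners] <- 1 / length(winners)
  v
}

#' Topology weights of one gene tree for four taxon groups
#'
#' Enumerates every combination of one tip per group, determines the
#' unrooted quartet topology induced by the tree for that combination
#' (votes of unresolved quartets are split equally across the compatible
#' topologies), and returns the vote proportions.  Trees are treated as
#' unrooted; groups with several tips in the tree contribute all their
#' combinations.  Above \code{maxComb} combinations, a seeded random sample
#' of combinations is used instead of exact enumeration.
#'
#' @param tree an \code{ape::phylo}.
#' @param grouping a \linkS4class{GroupingConfig} (groups P1..P4).
#' @param maxComb exact-enumeration limit (default 1e6).
#' @param seed seed for the sampling fallback.
#' @param nSample number of sampled combinations when sampling engages.
#' @return list with \code{weights} (length 3, pairing convention
#'   P1P2|P3P4, P1P3|P2P4, P1P4|P2P3), \code{usable} (logical),
#'   \code{nCombinations}, \code{exact}.
#' @export
quartetTopologyWeights <- function(tree, grouping, maxComb = 1e6, seed = 1L,
                                   nSample = 1e5) {
  stopifnot(is(grouping, "GroupingConfig"))
  tipTaxa <- tree$tip.label
  if (length(grouping@indivMap)) {
    mapped <- grouping@indivMap[tipTaxa]
    tipTaxa <- ifelse(is.na(mapped), tipTaxa, mapped)
  }
  gidx <- lapply(grouping@groups[1:4], function(g) which(tipTaxa %in% g))
  sizes <- vapply(gidx, length, 1L)
  if (any(sizes == 0L)) {
    return(list(weights = rep(NA_real_, 3), usable = FALSE,
                nCombinations = 0L, exact = TRUE))
  }
  arr <- .treeArrays(tree)
  nComb <- prod(sizes)
  w <- numeric(3)
  if (nComb <= maxComb) {
    for (i1 in gidx[[1]]) for (i2 in gidx[[2]]) for (i3 in gidx[[3]]) for (i4 in gidx[[4]]) {
      w <- w + .quartetVote(arr, c(i1, i2, i3, i4))
    }
    w <- w / nComb
    exact <- TRUE
  } else {
    u <- .locusUniforms(seed, 1, 505, 4L * nSample)
    dim(u) <- c(nSample, 4L)
    for (s in seq_len(nSample)) {
      q <- c(gidx[[1]][1L + floor(u[s, 1] * sizes[1])],
             gidx[[2]][1L + floor(u[s, 2] * sizes[2])],
             gidx[[3]][1L + floor(u[s, 3] * sizes[3])],
             gidx[[4]][1L + floor(u[s, 4] * sizes[4])])
      w <- w + .quartetVote(arr, q)
    }
    w <- w / nSample
    exact <- FALSE
  }
  list(weights = w, usable = TRUE, nCombinations = nComb, exact = exact)
}

#' Majority-rule support from topology weights
#'
#' The topology with the strictly greatest weight gets support 1; k-way
#' ties split the support equally.
#'
#' @param weights numeric length-3 vector summing to 1.
#' @param tol tie tolerance.
#' @return numeric length-3 support vector (values in {0, 1/3, 1/2, 1}).
#' @export
assignSupport <- function(weights, tol = 1e-9) {
  top <- which(weights >= max(weights) - tol)
  s <- numeric(3)
  s[top] <- 1 / length(top)
  s
}

#' Gene-tree support counts for the three quartet topologies
#'
#' Sums majority-rule supports over all usable gene trees.  The
#' \code{designation} names which pairing (1 = P1P2|P3P4, 2 = P1P3|P2P4,
#' 3 = P1P4|P2P3) is the reference network's major, minor and contradictory
#' topology.
#'
#' @param trees list / multiPhylo of gene trees.
#' @param grouping a \linkS4class{GroupingConfig}.
#' @param designation integer length-3 vector: pairing index of the major,
#'   minor and contradictory topology (a permutation of 1:3).
#' @param ... passed to \code{\link{quartetTopologyWeights}}.
#' @return list with \code{counts} (named major/minor/contra),
#'   \code{nUsable}, and \code{perTree} (weights and supports per tree).
#' @export
twisstCounts <- function(trees, grouping, designation = c(1L, 2L, 3L), ...) {
  if (!all(sort(designation) == 1:3)) stop("designation must be a permutation of 1:3")
  wts <- matrix(NA_real_, length(trees), 3)
  sup <- matrix(0, length(trees), 3)
  usable <- logical(length(trees))
  for (i in seq_along(trees)) {
    r <- quartetTopologyWeights(trees[[i]], grouping, ...)
    usable[i] <- r$usable
    if (r$usable) {
      wts[i, ] <- r$weights
      sup[i, ] <- assignSupport(r$weights)
    }
  }
  if (!any(usable)) stop("no usable trees: some group is absent from every tree")
  tot <- colSums(sup[usable, , drop = FALSE])
  counts <- setNames(tot[designation], c("major", "minor", "contra"))
  perTree <- data.frame(tree = seq_along(trees), usable = usable,
                        w_major = wts[, designation[1]],
                        w_minor = wts[, designation[2]],
                        w_contra = wts[, designation[3]],
                        s_major = sup[, designation[1]],
                        s_minor = sup[, designation[2]],
                        s_contra = sup[, designation[3]])
  list(counts = counts, nUsable = sum(usable), perTree = perTree)
}

#' Chi-square test of the ILS null of equal minor/contradictory frequencies
#'
#' Under incomplete lineage sorting alone the two non-major quartet
#' topologies are expected at equal frequency; introgression skews them.
#' Fractional support sums are rounded to the nearest integer pair
#' preserving their total before testing (flagged in the output).
#'
#' @param minor,contra support counts of the minor and contradictory
#'   topology.
#' @return list with \code{chisq}, \code{df} (= 1), \code{p} (two-sided
#'   upper tail of chi-square_1), \code{direction} ("minor" or "contra"
#'   excess, "none" if equal), \code{rounded} (logical) and the counts
#'   used.
#' @export
ilsChisqTest <- function(minor, contra) {
  if (minor < 0 || contra < 0) stop("counts must be nonnegative")
  if (minor + contra <= 0) stop("chi-square test undefined: both counts are zero")
  tot <- round(minor + contra)
  m <- round(minor)
  c_ <- tot - m
  rounded <- (abs(m - minor) > 1e-9) || (abs(c_ - contra) > 1e-9)
  E <- tot / 2
  chisq <- (m - E)^2 / E + (c_ - E)^2 / E
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  direction <- if (m > c_) "minor" else if (c_ > m) "contra" else "none"
  list(chisq = chisq, df = 1L, p = p, direction = direction,
       rounded = rounded, minor = m, contra = c_)
}

#' Construct a GroupingConfig
#'
#' @param P1,P2,P3,P4 character vectors of taxa (disjoint, nonempty).
#' @param outgroup character vector of outgroup taxa.
#' @param indivMap optional named character vector mapping individual ids
#'   to taxon names.
#' @return a \linkS4class{GroupingConfig}.
#' @export
groupingConfig <- function(P1, P2, P3, P4, outgroup = character(0),
                           indivMap = character(0)) {
  g <- new("GroupingConfig",
           groups = list(P1 = P1, P2 = P2, P3 = P3, P4 = P4),
           outgroup = outgroup, indivMap = indivMap)
  validObject(g)
  g
}

setMethod("show", "GroupingConfig", function(object) {
  cat("GroupingConfig:\n")
  for (nm in names(object@groups)) {
    cat(sprintf("  %s: %s\n", nm, paste(object@groups[[nm]], collapse = ", ")))
  }
  if (length(object@outgroup)) {
    cat("  outgroup:", paste(object@outgroup, collapse = ", "), "\n")
  }
})
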