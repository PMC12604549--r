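#' SpeciesNetwork: a rooted level-1 phylogenetic network
#'
#' A directed acyclic graph rooted at a single node.  Tree nodes have
#' in-degree at most 1; hybrid nodes have in-degree 2 and carry an
#' inheritance probability \eqn{\gamma} on each parent edge (the two values
#' sum to 1).  Tips are numbered \code{1..nTips(x)} and named by
#' \code{tipLabels(x)}; internal nodes follow.  Edge lengths may be in
#' substitutions/site or coalescent units; the unit is recorded in
#' \code{lengthUnit}.
#'
#' @slot edges data.frame with columns \code{parent}, \code{child} (integer
#'   node ids), \code{length} (non-negative, may be NA) and \code{gamma}
#'   (inheritance probability for hybrid edges, NA on tree edges).
#' @slot tipLabels character vector of taxon names; tip \code{i} is node id
#'   \code{i}.
#' @slot root integer id of the root node.
#' @slot nNodes total number of nodes.
#' @slot nodeNames optional internal-node names ("" when absent).
#' @slot hybridTags hybrid-node tags (e.g. "H1"), "" for non-hybrid nodes.
#' @slot lengthUnit unit of the edge lengths ("coalescent", "substitutions"
#'   or "unknown").
#' @export
setClass("SpeciesNetwork",
  representation(
    edges = "data.frame",
    tipLabels = "character",
    root = "integer",
    nNodes = "integer",
    nodeNames = "character",
    hybridTags = "character",
    lengthUnit = "character"
  ),
  prototype(lengthUnit = "unknown")
)

setValidity("SpeciesNetwork", function(object) {
  ed <- object@edges
  msgs <- character(0)
  need <- c("parent", "child", "length", "gamma")
  if (!all(need %in% names(ed))) {
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  }
  n <- object@nNodes
  ntip <- length(object@tipLabels)
  ids <- unique(c(ed$parent, ed$child))
  if (length(ids) && (max(ids) > n || min(ids) < 1L)) {
    msgs <- c(msgs, "edge node ids out of range")
  }
  if (anyDuplicated(object@tipLabels)) {
    msgs <- c(msgs, "tip labels must be unique")
  }
  indeg <- tabulate(ed$child, nbins = n)
  outdeg <- tabulate(ed$parent, nbins = n)
  if (ntip > 0 && any(outdeg[seq_len(ntip)] > 0L)) {
    msgs <- c(msgs, "tips (ids 1..nTips) must not have children")
  }
  if (nrow(ed)) {
    roots <- which(indeg == 0L & outdeg > 0L)
    if (length(roots) != 1L || roots != object@root) {
      msgs <- c(msgs, "network must have exactly one root (in-degree 0)")
    }
  }
  if (any(indeg > 2L)) msgs <- c(msgs, "in-degree must be at most 2")
  if (any(ed$length < 0, na.rm = TRUE)) msgs <- c(msgs, "edge lengths must be >= 0")
  hyb <- which(indeg == 2L)
  for (v in hyb) {
    g <- ed$gamma[ed$child == v]
    if (any(is.na(g))) {
      msgs <- c(msgs, sprintf("hybrid node %d has a missing inheritance probability", v))
    } else {
      if (abs(sum(g) - 1) > 1e-6) {
        msgs <- c(msgs, sprintf("inheritance probabilities at hybrid node %d sum to %.8f, not 1", v, sum(g)))
      }
      if (any(g < -1e-12 | g > 1 + 1e-12)) {
        msgs <- c(msgs, sprintf("inheritance probabilities at hybrid node %d outside [0,1]", v))
      }
    }
  }
  bad <- which(!is.na(ed$gamma) & !(ed$child %in% hyb))
  if (length(bad)) msgs <- c(msgs, "gamma set on a non-hybrid edge")
  # acyclicity via topological elimination
  if (nrow(ed)) {
    dout <- outdeg
    din <- indeg
    queue <- which(din == 0L)
    seen <- 0L
    childOf <- split(ed$child, ed$parent)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
      for (w in childOf[[as.character(v)]]) {
        din[w] <- din[w] - 1L
        if (din[w] == 0L) queue <- c(queue, w)
      }
    }
    used <- unique(c(ed$parent, ed$child))
    if (seen < length(used)) msgs <- c(msgs, "network contains a directed cycle")
  }
  # level-1: reticulation cycles must be pairwise edge-disjoint
  if (length(hyb) >= 2L && !length(msgs)) {
    cyc <- lapply(hyb, function(v) .reticulationCycle(ed, v)$edgeKeys)
    for (i in seq_along(cyc)) {
      for (j in seq_len(i - 1L)) {
        if (length(intersect(cyc[[i]], cyc[[j]]))) {
          msgs <- c(msgs, "network is not level-1: reticulation cycles share an edge")
        }
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SNPMatrix: individuals by biallelic sites
#'
#' Genotypes are derived-allele counts per individual (0/1 for haploids,
#' 0/1/2 for diploids), with \code{NA} as the distinguished missing code.
#' Site metadata records the locus, the 1-based position within the locus
#' and the ref/alt alleles.  Positions are strictly increasing within a
#' locus.
#'
#' @slot genotypes integer matrix, rows = individuals (named), columns =
#'   sites.
#' @slot sites data.frame with columns \code{locus}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @slot ploidy 1 or 2; the maximum genotype value.
#' @export
setClass("SNPMatrix",
  representation(
    genotypes = "matrix",
    sites = "data.frame",
    ploidy = "integer"
  ),
  prototype(ploidy = 1L)
)

setValidity("SNPMatrix", function(object) {
  g <- object@genotypes
  s <- object@sites
  msgs <- character(0)
  if (!all(c("locus", "pos", "ref", "alt") %in% names(s))) {
    msgs <- c(msgs, "sites must have columns locus, pos, ref, alt")
  } else {
    if (ncol(g) != nrow(s)) msgs <- c(msgs, "ncol(genotypes) must equal nrow(sites)")
    byLocus <- split(s$pos, s$locus)
    if (any(vapply(byLocus, function(p) any(diff(p) <= 0), logical(1)))) {
      msgs <- c(msgs, "positions must be strictly increasing within a locus")
    }
    if (any(s$pos < 1, na.rm = TRUE)) msgs <- c(msgs, "positions are 1-based (>= 1)")
  }
  if (is.null(rownames(g))) msgs <- c(msgs, "genotype rows must be named by individual")
  pl <- object@ploidy
  if (!(pl %in% c(1L, 2L))) msgs <- c(msgs, "ploidy must be 1 or 2")
  vals <- g[!is.na(g)]
  if (length(vals) && (any(vals < 0) || any(vals > pl))) {
    msgs <- c(msgs, "genotypes must lie in 0..ploidy or be NA")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' GroupingConfig: four taxon groups plus an outgroup
#'
#' Holds the disjoint taxon groups P1..P4 used for topology weighting and
#' site-pattern statistics, the outgroup, and an optional
#' individual-to-taxon map.
#'
#' @slot groups named list of character vectors (P1, P2, P3, P4).
#' @slot outgroup character vector of outgroup taxa.
#' @slot indivMap named character vector mapping individual ids to taxon
#'   names (identity when empty).
#' @export
setClass("GroupingConfig",
  representation(
    groups = "list",
    outgroup = "character",
    indivMap = "character"
  )
)

setValidity("GroupingConfig", function(object) {
  g <- object@groups
  msgs <- character(0)
  if (length(g) && is.null(names(g))) msgs <- c(msgs, "groups must be named")
  if (any(!vapply(g, length, 1L))) msgs <- c(msgs, "groups must be nonempty")
  all_ <- unlist(g, use.names = FALSE)
  if (anyDuplicated(c(all_, object@outgroup))) {
    msgs <- c(msgs, "groups and outgroup must be disjoint")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
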