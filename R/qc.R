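## Gene-tree quality control: distance-ratio and minimum-outgroup-distance
## filters, and branch-length normalization by the mean outgroup-ingroup
## patristic distance.

#' Filter a gene tree on patristic-distance criteria
#'
#' A tree passes iff (1) the maximum patristic distance among ingroup taxa
#' does not exceed \code{ratio} times the maximum ingroup-outgroup distance
#' and (2) the minimum ingroup-outgroup distance is at least
#' \code{minOutDist}.  Both boundaries are inclusive.  Trees lacking the
#' outgroup are excluded (verdict \code{"fail_missing_outgroup"}), not an
#' error.
#'
#' @param tree an \code{ape::phylo} gene tree with branch lengths.
#' @param ingroup character vector of ingroup taxa.
#' @param outgroup single outgroup taxon.
#' @param ratio maximum allowed ratio of max ingroup distance to max
#'   ingroup-outgroup distance (default 1.5).
#' @param minOutDist minimum allowed ingroup-outgroup distance (default
#'   1e-4).
#' @return list with \code{verdict} (one of \code{"pass"},
#'   \code{"fail_ratio"}, \code{"fail_mindist"},
#'   \code{"fail_missing_outgroup"}) and the measured quantities
#'   \code{maxIn}, \code{maxInOut}, \code{minInOut}.
#' @export
filterGeneTree <- function(tree, ingroup, outgroup, ratio = 1.5,
                           minOutDist = 1e-4) {
  tips <- tree$tip.label
  if (!(outgroup %in% tips)) {
    return(list(verdict = "fail_missing_outgroup", maxIn = NA_real_,
                maxInOut = NA_real_, minInOut = NA_real_))
  }
  ing <- intersect(ingroup, tips)
  if (length(ing) < 2L) stop("tree must contain at least two ingroup taxa")
  D <- ape::cophenetic.phylo(tree)
  maxIn <- max(D[ing, ing])
  io <- D[ing, outgroup]
  maxInOut <- max(io)
  minInOut <- min(io)
  verdict <- if (maxIn > ratio * maxInOut) "fail_ratio"
             else if (minInOut < minOutDist) "fail_mindist"
             else "pass"
  list(verdict = verdict, maxIn = maxIn, maxInOut = maxInOut,
       minInOut = minInOut)
}

#' Normalize a gene tree by its mean outgroup-ingroup distance
#'
#' Divides every branch length by the mean patristic distance between the
#' outgroup and the ingroup taxa, so that this mean equals 1 afterwards.
#' Normalization is idempotent and leaves distance ratios unchanged.
#'
#' @inheritParams filterGeneTree
#' @return the rescaled tree.
#' @export
normalizeTree <- function(tree, ingroup, outgroup) {
  tips <- tree$tip.label
  if (!(outgroup %in% tips)) stop("outgroup absent from tree")
  ing <- intersect(ingroup, tips)
  if (!length(ing)) stop("no ingroup taxa in tree")
  D <- ape::cophenetic.phylo(tree)
  m <- mean(D[ing, outgroup])
  if (!is.finite(m) || m <= 0) stop("mean outgroup-ingroup distance is zero; cannot normalize")
  tree$edge.length <- tree$edge.length / m
  tree
}

#' Batch gene-tree QC
#'
#' Applies \code{\link{filterGeneTree}} to every tree, then
#' \code{\link{normalizeTree}} to the passing ones.
#'
#' @param trees a list / multiPhylo of gene trees.
#' @param ingroup,outgroup,ratio,minOutDist as in
#'   \code{\link{filterGeneTree}}.
#' @return list with \code{report} (per-tree data.frame of verdicts and
#'   measured distances), \code{counts} (verdict table) and
#'   \code{retained} (normalized passing trees, multiPhylo).
#' @export
qcBatch <- function(trees, ingroup, outgroup, ratio = 1.5, minOutDist = 1e-4) {
  if (!length(trees)) {
    warning("empty gene-tree batch")
    return(list(report = data.frame(), counts = table(character(0)),
                retained = structure(list(), class = "multiPhylo")))
  }
  rep_ <- vector("list", length(trees))
  retained <- list()
  for (i in seq_along(trees)) {
    r <- filterGeneTree(trees[[i]], ingroup, outgroup, ratio, minOutDist)
    rep_[[i]] <- data.frame(tree = i, verdict = r$verdict, maxIn = r$maxIn,
                            maxInOut = r$maxInOut, minInOut = r$minInOut)
    if (r$verdict == "pass") {
      retained[[length(retained) + 1L]] <- normalizeTree(trees[[i]], ingroup, outgroup)
    }
  }
  report <- do.call(rbind, rep_)
  class(retained) <- "multiPhylo"
  list(report = report,
       counts = table(factor(report$verdict,
                             levels = c("pass", "fail_ratio", "fail_mindist",
                                        "fail_missing_outgroup"))),
       retained = retained)
}
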