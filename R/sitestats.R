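## SNP filtering/thinning, population allele frequencies, Patterson's D,
## f4-ratio, f-branch, BH-FDR adjustment and the simple-matching
## similarity matrix.

#' Construct a SNPMatrix
#'
#' @param genotypes integer matrix (rows = named individuals, columns =
#'   sites) of derived-allele counts with NA for missing.
#' @param sites data.frame with columns \code{locus}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @param ploidy 1 (genotypes 0/1) or 2 (0/1/2).
#' @return a validated \linkS4class{SNPMatrix}.
#' @export
snpMatrix <- function(genotypes, sites, ploidy = 1L) {
  storage.mode(genotypes) <- "integer"
  obj <- new("SNPMatrix", genotypes = genotypes, sites = sites,
             ploidy = as.integer(ploidy))
  validObject(obj)
  obj
}

#' @rdname snpMatrix
#' @param x,object a SNPMatrix.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname snpMatrix
#' @export
setMethod("genotypes", "SNPMatrix", function(x) x@genotypes)

#' @rdname snpMatrix
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname snpMatrix
#' @export
setMethod("siteInfo", "SNPMatrix", function(x) x@sites)

#' @rdname snpMatrix
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname snpMatrix
#' @export
setMethod("nSites", "SNPMatrix", function(x) ncol(x@genotypes))

#' @rdname snpMatrix
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname snpMatrix
#' @export
setMethod("individuals", "SNPMatrix", function(x) rownames(x@genotypes))

setMethod("show", "SNPMatrix", function(object) {
  cat(sprintf("SNPMatrix: %d individuals x %d biallelic sites (%d loci), ploidy %d\n",
              nrow(object@genotypes), ncol(object@genotypes),
              length(unique(object@sites$locus)), object@ploidy))
  miss <- mean(is.na(object@genotypes))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
})

.subsetSites <- function(x, keep) {
  new("SNPMatrix", genotypes = x@genotypes[, keep, drop = FALSE],
      sites = x@sites[keep, , drop = FALSE], ploidy = x@ploidy)
}

#' Filter and thin a SNP matrix
#'
#' Drops sites that are not biallelic in-sample (monomorphic among
#' non-missing genotypes), drops sites whose missing fraction is greater
#' than or equal to \code{maxMissing} (strict retention, "< 20% missing"),
#' then thins greedily from the lowest position within each locus, keeping
#' a site only if it lies at least \code{thinBp} base pairs beyond the last
#' kept site.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param maxMissing maximum tolerated missing fraction (default 0.2;
#'   sites at exactly this fraction are dropped).
#' @param thinBp thinning window in bp (default 100); 0 disables thinning.
#' @return the filtered SNPMatrix (possibly with zero sites, with a
#'   warning).
#' @export
filterSnps <- function(x, maxMissing = 0.2, thinBp = 100L) {
  stopifnot(is(x, "SNPMatrix"))
  g <- x@genotypes
  nInd <- nrow(g)
  missFrac <- colMeans(is.na(g))
  nAllele <- apply(g, 2, function(col) length(unique(col[!is.na(col)])))
  keep <- which(missFrac < maxMissing & nAllele >= 2L)
  x2 <- .subsetSites(x, keep)
  if (thinBp > 0 && nSites(x2) > 0) {
    s <- x2@sites
    keep2 <- logical(nrow(s))
    for (loc in unique(s$locus)) {
      idx <- which(s$locus == loc)
      idx <- idx[order(s$pos[idx])]
      last <- -Inf
      for (i in idx) {
        if (s$pos[i] - last >= thinBp) {
          keep2[i] <- TRUE
          last <- s$pos[i]
        }
      }
    }
    x2 <- .subsetSites(x2, which(keep2))
  }
  if (nSites(x2) == 0L) warning("no sites retained after filtering")
  x2
}

#' Retain one SNP per locus
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param method "first" (default) or "random".
#' @param seed seed for random selection.
#' @return a SNPMatrix with exactly one site per locus.
#' @export
oneSnpPerLocus <- function(x, method = c("first", "random"), seed = 1L) {
  method <- match.arg(method)
  s <- x@sites
  keep <- integer(0)
  loci <- unique(s$locus)
  for (j in seq_along(loci)) {
    idx <- which(s$locus == loci[j])
    if (method == "first") {
      keep <- c(keep, idx[which.min(s$pos[idx])])
    } else {
      u <- .locusUniforms(seed, j, 606, 1)
      keep <- c(keep, idx[1L + floor(u * length(idx))])
    }
  }
  .subsetSites(x, sort(keep))
}

#' Population derived-allele frequencies
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param popMap named list: population name -> character vector of
#'   individual ids.
#' @return list with \code{freq} (populations x sites matrix, NA when no
#'   non-missing genotype) and \code{n} (allele counts observed).
#' @export
popFreqs <- function(x, popMap) {
  g <- x@genotypes
  pl <- x@ploidy
  pops <- names(popMap)
  freq <- matrix(NA_real_, length(pops), ncol(g), dimnames = list(pops, NULL))
  n <- matrix(0L, length(pops), ncol(g), dimnames = list(pops, NULL))
  for (i in seq_along(pops)) {
    ids <- popMap[[i]]
    miss <- setdiff(ids, rownames(g))
    if (length(miss)) stop("unknown individuals in population ", pops[i], ": ",
                           paste(miss, collapse = ", "))
    sub <- g[ids, , drop = FALSE]
    cnt <- colSums(!is.na(sub))
    freq[i, cnt > 0] <- colMeans(sub, na.rm = TRUE)[cnt > 0] / pl
    n[i, ] <- as.integer(cnt) * pl
  }
  list(freq = freq, n = n)
}

# shared ABBA/BABA site terms; rows of `freq` must be P1, P2, P3, O
.dTerms <- function(freq) {
  ok <- colSums(is.na(freq)) == 0L
  p1 <- freq[1, ok]; p2 <- freq[2, ok]; p3 <- freq[3, ok]; pO <- freq[4, ok]
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  # f4-ratio denominator: P3 substituted into the P2 (recipient) position
  abba3 <- (1 - p1) * p3 * p3 * (1 - pO)
  baba3 <- p1 * (1 - p3) * p3 * (1 - pO)
  list(num = abba - baba, den = abba + baba, fden = abba3 - baba3, ok = ok)
}

# delete-one-block jackknife of a ratio statistic sum(num)/sum(den)
.blockJackknife <- function(num, den, nBlocks = 20L) {
  n <- length(num)
  if (n < 2L || sum(den) == 0) {
    return(list(est = if (sum(den) == 0) NA_real_ else sum(num) / sum(den),
                se = NA_real_, z = NA_real_, p = NA_real_, nBlocks = 0L))
  }
  nBlocks <- max(2L, min(nBlocks, n))
  blocks <- cut(seq_len(n), breaks = nBlocks, labels = FALSE)
  est <- sum(num) / sum(den)
  loo <- vapply(seq_len(nBlocks), function(b) {
    keep <- blocks != b
    d <- sum(den[keep])
    if (d == 0) return(NA_real_)
    sum(num[keep]) / d
  }, numeric(1))
  loo <- loo[is.finite(loo)]
  B <- length(loo)
  if (B < 2L) return(list(est = est, se = NA_real_, z = NA_real_, p = NA_real_, nBlocks = B))
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  z <- if (se > 0) est / se else NA_real_
  p <- if (is.finite(z)) 2 * pnorm(-abs(z)) else NA_real_
  list(est = est, se = se, z = z, p = p, nBlocks = B)
}

#' Patterson's D (ABBA-BABA) statistic
#'
#' @param freq populations x sites frequency matrix whose rows are, in
#'   order, P1, P2, P3 and the outgroup (e.g. a subset of
#'   \code{popFreqs(x, popMap)$freq}).
#' @param nBlocks number of equal-size site blocks for the jackknife
#'   (default 20).
#' @return list with \code{D}, \code{se}, \code{z}, \code{p} (two-sided
#'   normal), \code{nSites}, \code{undefined} (TRUE when the denominator
#'   is zero).
#' @export
pattersonD <- function(freq, nBlocks = 20L) {
  stopifnot(nrow(freq) == 4L)
  tm <- .dTerms(freq)
  if (!sum(tm$ok)) stop("no informative sites (all have missing frequencies)")
  jk <- .blockJackknife(tm$num, tm$den, nBlocks)
  list(D = jk$est, se = jk$se, z = jk$z, p = jk$p, nSites = sum(tm$ok),
       undefined = !is.finite(jk$est))
}

#' f4-ratio admixture-fraction estimator
#'
#' Same numerator as Patterson's D; the denominator substitutes the donor
#' P3 into the recipient position, so the ratio estimates the admixture
#' fraction \eqn{\gamma}.  The raw value is retained; \code{f} is clipped
#' to [-1, 1] for reporting.
#'
#' @inheritParams pattersonD
#' @return list with \code{f} (clipped), \code{fRaw}, \code{se}, \code{z},
#'   \code{p}, \code{nSites}, \code{undefined}.
#' @export
f4Ratio <- function(freq, nBlocks = 20L) {
  stopifnot(nrow(freq) == 4L)
  tm <- .dTerms(freq)
  if (!sum(tm$ok)) stop("no informative sites (all have missing frequencies)")
  jk <- .blockJackknife(tm$num, tm$fden, nBlocks)
  fRaw <- jk$est
  list(f = if (is.finite(fRaw)) max(-1, min(1, fRaw)) else NA_real_,
       fRaw = fRaw, se = jk$se, z = jk$z, p = jk$p, nSites = sum(tm$ok),
       undefined = !is.finite(fRaw))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment (delegated to \code{stats::p.adjust}).
#'
#' @param p vector of p-values in [0, 1] (NAs preserved).
#' @return adjusted q-values.
#' @export
fdrAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' f-branch statistic across a species tree
#'
#' Summarizes f4-ratio signals over the branches of a rooted reference
#' species tree: for branch b and candidate donor taxon C,
#' \eqn{f_b(C)} is the median over descendants a of b of the minimum over
#' representatives A of b's sister clade of the f4-ratio f4(A, a; C, O),
#' with negative contributing f4-ratios floored at 0 (mirroring the
#' reference implementation).  Cells where C descends from b or from b's
#' sister are undefined.  P-values come from the jackknife Z of the
#' combination attaining the reported value and are BH-adjusted across all
#' defined cells.
#'
#' @param speciesTree rooted \code{ape::phylo} whose tips are population
#'   names.
#' @param freqs output of \code{\link{popFreqs}} covering all populations
#'   and the outgroup.
#' @param outgroup outgroup population name.
#' @param nBlocks jackknife blocks.
#' @return list with \code{matrix} (branches x candidates, NA =
#'   undefined), \code{p}, \code{q} (same shape), and \code{branches}
#'   (data.frame describing each branch by its descendant tips).
#' @export
fBranch <- function(speciesTree, freqs, outgroup, nBlocks = 20L) {
  if (!ape::is.rooted(speciesTree)) stop("species tree must be rooted")
  tr <- ape::drop.tip(speciesTree, outgroup)
  if (is.null(tr)) stop("species tree must retain taxa besides the outgroup")
  freq <- freqs$freq
  if (!(outgroup %in% rownames(freq))) stop("outgroup absent from frequency table")
  tips <- tr$tip.label
  if (!all(tips %in% rownames(freq))) {
    stop("species-tree tips missing from frequency table: ",
         paste(setdiff(tips, rownames(freq)), collapse = ", "))
  }
  ntip <- length(tips)
  root <- ntip + 1L
  nodes <- setdiff(seq_len(ntip + tr$Nnode), root)  # every branch = non-root node
  descOf <- function(v) tips[.tipsBelow(tr, v)]
  sisterOf <- function(v) {
    par <- tr$edge[tr$edge[, 2] == v, 1]
    sibs <- setdiff(tr$edge[tr$edge[, 1] == par, 2], v)
    unique(unlist(lapply(sibs, descOf)))
  }
  branchDesc <- lapply(nodes, descOf)
  branchSis <- lapply(nodes, sisterOf)
  fm <- matrix(NA_real_, length(nodes), ntip,
               dimnames = list(vapply(branchDesc, paste, character(1), collapse = ","),
                               tips))
  pm <- fm
  # cache f4 results per (A, a, C) trio
  cache <- new.env(parent = emptyenv())
  f4of <- function(A, a, C) {
    key <- paste(A, a, C, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- f4Ratio(freq[c(A, a, C, outgroup), , drop = FALSE], nBlocks)
    cache[[key]] <- r
    r
  }
  for (bi in seq_along(nodes)) {
    dsc <- branchDesc[[bi]]
    sis <- branchSis[[bi]]
    if (!length(sis)) next
    for (C in setdiff(tips, c(dsc, sis))) {
      vals <- numeric(0)
      zs <- numeric(0)
      for (a in dsc) {
        best <- NULL
        for (A in sis) {
          r <- f4of(A, a, C)
          if (r$undefined) next
          if (is.null(best) || r$fRaw < best$fRaw) best <- r
        }
        if (is.null(best)) next
        vals <- c(vals, max(0, best$fRaw))
        zs <- c(zs, best$z)
      }
      if (!length(vals)) next
      fb <- median(vals)
      fm[bi, C] <- fb
      # p from the contributing combination closest to the reported value
      pick <- which.min(abs(vals - fb))
      z <- zs[pick]
      pm[bi, C] <- if (is.finite(z)) 2 * pnorm(-abs(z)) else NA_real_
    }
  }
  qm <- pm
  def <- which(!is.na(pm))
  qm[def] <- fdrAdjust(pm[def])
  list(matrix = fm, p = pm, q = qm,
       branches = data.frame(branch = rownames(fm),
                             nDesc = vapply(branchDesc, length, 1L)))
}

#' Simple-matching similarity matrix
#'
#' \eqn{s(i,j)} = number of matching genotypes / number of comparable
#' sites (both non-missing).  The diagonal is 1; pairs with no comparable
#' sites are NA (flagged with a warning).
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @return symmetric individuals x individuals matrix.
#' @export
simpleMatchingSimilarity <- function(x) {
  g <- x@genotypes
  n <- nrow(g)
  if (n < 2L) stop("need at least two individuals")
  S <- diag(1, n)
  dimnames(S) <- list(rownames(g), rownames(g))
  anyUndef <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !is.na(g[i, ]) & !is.na(g[j, ])
      nc <- sum(comp)
      if (nc == 0L) {
        S[i, j] <- S[j, i] <- NA_real_
        anyUndef <- TRUE
      } else {
        S[i, j] <- S[j, i] <- sum(g[i, comp] == g[j, comp]) / nc
      }
    }
  }
  if (anyUndef) warning("some pairs share no comparable sites (NA entries)")
  S
}
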