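## SpeciesNetwork construction, accessors, extended-newick I/O and the
## displayed-tree machinery that the scoring, calibration and ASR stages
## build on.

#' Construct a SpeciesNetwork
#'
#' @param edges data.frame with columns parent, child, length, gamma.
#' @param tipLabels taxon names; tip i is node id i.
#' @param nodeNames,hybridTags optional per-node annotation vectors.
#' @param lengthUnit unit of the edge lengths.
#' @return A validated \linkS4class{SpeciesNetwork}.
#' @export
speciesNetwork <- function(edges, tipLabels, nodeNames = NULL, hybridTags = NULL,
                           lengthUnit = "unknown") {
  n <- max(c(edges$parent, edges$child, length(tipLabels)))
  indeg <- tabulate(edges$child, nbins = n)
  root <- which(indeg == 0L & tabulate(edges$parent, nbins = n) > 0L)
  if (length(root) != 1L) stop("network must have exactly one root")
  if (is.null(nodeNames)) nodeNames <- rep("", n)
  if (is.null(hybridTags)) {
    hybridTags <- rep("", n)
    hyb <- which(indeg == 2L)
    hybridTags[hyb] <- paste0("H", seq_along(hyb))
  }
  edges$parent <- as.integer(edges$parent)
  edges$child <- as.integer(edges$child)
  edges$length <- as.numeric(edges$length)
  edges$gamma <- as.numeric(edges$gamma)
  rownames(edges) <- NULL
  new("SpeciesNetwork", edges = edges, tipLabels = as.character(tipLabels),
      root = as.integer(root), nNodes = as.integer(n),
      nodeNames = nodeNames, hybridTags = hybridTags,
      lengthUnit = lengthUnit)
}

#' @rdname speciesNetwork
#' @param x,object a SpeciesNetwork.
#' @export
setGeneric("nTips", function(x) standardGeneric("nTips"))

#' @rdname speciesNetwork
#' @export
setMethod("nTips", "SpeciesNetwork", function(x) length(x@tipLabels))

#' @rdname speciesNetwork
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' @rdname speciesNetwork
#' @export
setMethod("tipLabels", "SpeciesNetwork", function(x) x@tipLabels)

#' @rdname speciesNetwork
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname speciesNetwork
#' @export
setMethod("networkEdges", "SpeciesNetwork", function(x) x@edges)

#' @rdname speciesNetwork
#' @export
setGeneric("hybridNodes", function(x) standardGeneric("hybridNodes"))

#' @rdname speciesNetwork
#' @export
setMethod("hybridNodes", "SpeciesNetwork", function(x) {
  indeg <- tabulate(x@edges$child, nbins = x@nNodes)
  which(indeg == 2L)
})

#' @rdname speciesNetwork
#' @export
setGeneric("nHybrids", function(x) standardGeneric("nHybrids"))

#' @rdname speciesNetwork
#' @export
setMethod("nHybrids", "SpeciesNetwork", function(x) length(hybridNodes(x)))

#' @rdname speciesNetwork
#' @export
setGeneric("inheritanceProbs", function(x) standardGeneric("inheritanceProbs"))

#' @rdname speciesNetwork
#' @export
setMethod("inheritanceProbs", "SpeciesNetwork", function(x) {
  hyb <- hybridNodes(x)
  out <- lapply(hyb, function(v) {
    rows <- which(x@edges$child == v)
    setNames(x@edges$gamma[rows], x@edges$parent[rows])
  })
  names(out) <- x@hybridTags[hyb]
  out
})

setMethod("show", "SpeciesNetwork", function(object) {
  h <- nHybrids(object)
  cat(sprintf("SpeciesNetwork: %d tips, %d nodes, %d hybrid node%s (%s units)\n",
              nTips(object), object@nNodes, h, if (h == 1) "" else "s",
              object@lengthUnit))
  cat("  tips: ", paste(head(tipLabels(object), 8), collapse = ", "),
      if (nTips(object) > 8) ", ..." else "", "\n", sep = "")
  enw <- tryCatch(writeExtendedNewick(object), error = function(e) NULL)
  if (!is.null(enw)) {
    if (nchar(enw) > 200) enw <- paste0(substr(enw, 1, 200), "...")
    cat("  ", enw, "\n", sep = "")
  }
})

## ---------------------------------------------------------------------------
## Parsing

#' Parse a newick gene tree
#'
#' Thin wrapper around \code{ape::read.tree} with a preflight syntax check
#' that reports the character offset of unbalanced parentheses.
#'
#' @param text a newick string.
#' @return an \code{ape::phylo} tree.
#' @export
parseNewick <- function(text) {
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("newick parse error at character %d: unmatched ')'", i))
    }
  }
  if (depth != 0L) {
    stop(sprintf("newick parse error at character %d: %d unclosed '('", length(chars), depth))
  }
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr)) stop("newick parse error: ape could not read the string")
  tr
}

#' Parse an extended-newick species network
#'
#' Reads the de-facto standard extended newick dialect in which a hybrid
#' node appears twice under a shared \code{#H} tag, once with its subtree
#' and once as a bare reference, and hybrid edges carry
#' \code{:length:support:gamma} annotation.  A \eqn{\gamma} missing on one
#' parent edge is inferred as 1 minus the other; the pair must sum to 1
#' within 1e-6.
#'
#' @param text an extended-newick string.
#' @param lengthUnit recorded unit of the branch lengths.
#' @return a \linkS4class{SpeciesNetwork}.
#' @export
parseExtendedNewick <- function(text, lengthUnit = "unknown") {
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty extended-newick string")
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$occ <- list()
  peek <- function() if (env$pos <= length(chars)) chars[[env$pos]] else ""
  adv <- function() env$pos <- env$pos + 1L
  perr <- function(msg) stop(sprintf("extended-newick parse error at character %d: %s",
                                     env$pos, msg), call. = FALSE)
  readToken <- function() {
    from <- env$pos
    while (!(peek() %in% c("", "(", ")", ",", ":", ";"))) adv()
    if (env$pos > from) paste(chars[from:(env$pos - 1L)], collapse = "") else ""
  }
  readNumField <- function() {
    tok <- readToken()
    if (!nzchar(tok)) return(NA_real_)
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) perr(sprintf("bad numeric field '%s'", tok))
    v
  }
  parseClade <- function() {
    children <- integer(0)
    if (peek() == "(") {
      adv()
      repeat {
        children <- c(children, parseClade())
        if (peek() == ",") { adv(); next }
        if (peek() == ")") { adv(); break }
        perr("expected ',' or ')'")
      }
    }
    lab <- readToken()
    tag <- NA_character_
    name <- lab
    if (grepl("#", lab, fixed = TRUE)) {
      parts <- strsplit(lab, "#", fixed = TRUE)[[1]]
      name <- parts[1]
      tag <- paste(parts[-1], collapse = "#")
      if (!nzchar(tag)) perr("empty hybrid tag after '#'")
    }
    len <- NA_real_; sup <- NA_real_; gam <- NA_real_
    if (peek() == ":") {
      adv(); len <- readNumField()
      if (peek() == ":") {
        adv(); sup <- readNumField()
        if (peek() == ":") { adv(); gam <- readNumField() }
      }
    }
    env$occ[[length(env$occ) + 1L]] <- list(children = children, name = name,
                                            tag = tag, length = len,
                                            support = sup, gamma = gam)
    length(env$occ)
  }
  rootOcc <- parseClade()
  if (peek() == ";") adv()
  if (env$pos <= length(chars)) perr("trailing characters after tree")
  .occurrencesToNetwork(env$occ, rootOcc, lengthUnit)
}

.occurrencesToNetwork <- function(occ, rootOcc, lengthUnit) {
  nOcc <- length(occ)
  tagOf <- vapply(occ, function(o) o$tag, character(1))
  tags <- unique(tagOf[!is.na(tagOf)])
  for (tg in tags) {
    k <- sum(tagOf == tg, na.rm = TRUE)
    if (k != 2L) {
      stop(sprintf("extended-newick parse error: hybrid tag '#%s' appears %d time(s), expected 2", tg, k))
    }
  }
  # node key per occurrence: tagged occurrences of the same tag share a node
  nodeKey <- integer(nOcc)
  nextKey <- 0L
  tagKey <- setNames(rep(NA_integer_, length(tags)), tags)
  for (i in seq_len(nOcc)) {
    tg <- tagOf[i]
    if (is.na(tg)) {
      nextKey <- nextKey + 1L
      nodeKey[i] <- nextKey
    } else if (is.na(tagKey[tg])) {
      nextKey <- nextKey + 1L
      tagKey[tg] <- nextKey
      nodeKey[i] <- nextKey
    } else {
      nodeKey[i] <- tagKey[tg]
    }
  }
  nNode <- nextKey
  childrenOf <- vector("list", nNode)
  nameOf <- rep("", nNode)
  tagNode <- rep("", nNode)
  for (i in seq_len(nOcc)) {
    k <- nodeKey[i]
    if (length(occ[[i]]$children)) {
      if (length(childrenOf[[k]])) {
        stop(sprintf("extended-newick parse error: hybrid '#%s' has a subtree at both occurrences", tagOf[i]))
      }
      childrenOf[[k]] <- nodeKey[occ[[i]]$children]
    }
    if (nzchar(occ[[i]]$name)) nameOf[k] <- occ[[i]]$name
    if (!is.na(tagOf[i])) tagNode[k] <- tagOf[i]
  }
  # edges: one per non-root occurrence, annotated by that occurrence
  parentOcc <- rep(NA_integer_, nOcc)
  for (i in seq_len(nOcc)) for (c in occ[[i]]$children) parentOcc[c] <- i
  ep <- integer(0); ec <- integer(0); el <- numeric(0); eg <- numeric(0)
  for (i in seq_len(nOcc)) {
    if (is.na(parentOcc[i])) next
    ep <- c(ep, nodeKey[parentOcc[i]])
    ec <- c(ec, nodeKey[i])
    el <- c(el, occ[[i]]$length)
    eg <- c(eg, occ[[i]]$gamma)
  }
  # duplicate-edge check (same hybrid referenced twice under one parent)
  if (anyDuplicated(paste(ep, ec))) {
    stop("extended-newick parse error: duplicated edge")
  }
  # infer missing gamma on one side of each hybrid
  indeg <- tabulate(ec, nbins = nNode)
  for (v in which(indeg == 2L)) {
    rows <- which(ec == v)
    g <- eg[rows]
    if (all(is.na(g))) {
      stop(sprintf("inheritance probabilities missing on both parent edges of hybrid node '%s'",
                   if (nzchar(tagNode[v])) tagNode[v] else as.character(v)))
    }
    if (sum(is.na(g)) == 1L) eg[rows[is.na(g)]] <- 1 - g[!is.na(g)]
    if (abs(sum(eg[rows]) - 1) > 1e-6) {
      stop(sprintf("inheritance probabilities at hybrid '%s' sum to %.8f, not 1",
                   if (nzchar(tagNode[v])) tagNode[v] else as.character(v), sum(eg[rows])))
    }
  }
  # renumber: tips (no children) 1..ntip in key order, then internal in preorder
  isTip <- vapply(seq_len(nNode), function(k) length(childrenOf[[k]]) == 0L, logical(1))
  tipKeys <- which(isTip)
  id <- integer(nNode)
  id[tipKeys] <- seq_along(tipKeys)
  nextId <- length(tipKeys)
  rootKey <- nodeKey[rootOcc]
  # preorder over the DAG: visit children of each internal in stored order
  visited <- rep(FALSE, nNode)
  visitRec <- function(k) {
    if (visited[k]) return(invisible(NULL))
    visited[k] <<- TRUE
    if (!isTip[k]) {
      nextId <<- nextId + 1L
      id[k] <<- nextId
    }
    for (c in childrenOf[[k]]) visitRec(c)
  }
  visitRec(rootKey)
  if (any(id == 0L)) stop("extended-newick parse error: unreachable node")
  tipNames <- nameOf[tipKeys]
  blank <- !nzchar(tipNames)
  tipNames[blank] <- ifelse(nzchar(tagNode[tipKeys][blank]), tagNode[tipKeys][blank],
                            paste0("t", which(blank)))
  edges <- data.frame(parent = id[ep], child = id[ec], length = el, gamma = eg)
  nodeNames <- rep("", nNode); nodeNames[id] <- nameOf
  hybridTags <- rep("", nNode); hybridTags[id] <- tagNode
  # order tip labels by final id
  tipLabs <- character(length(tipKeys))
  tipLabs[id[tipKeys]] <- tipNames
  net <- speciesNetwork(edges, tipLabs, nodeNames = nodeNames,
                        hybridTags = hybridTags, lengthUnit = lengthUnit)
  validObject(net)
  net
}

## ---------------------------------------------------------------------------
## Writing

#' Write a network as extended newick
#'
#' Each hybrid node is written with its subtree at the first visit and as a
#' bare \code{#H} reference at the second; hybrid edges carry
#' \code{:length::gamma}.
#'
#' @param net a SpeciesNetwork.
#' @param digits significant digits for numeric fields.
#' @return a single extended-newick string (with trailing ";").
#' @export
writeExtendedNewick <- function(net, digits = 12) {
  ed <- net@edges
  hyb <- hybridNodes(net)
  tags <- net@hybridTags
  for (v in hyb) if (!nzchar(tags[v])) tags[v] <- paste0("H", match(v, hyb))
  visited <- rep(FALSE, net@nNodes)
  num <- function(x) sprintf("%.*g", digits, x)
  lab <- function(v) {
    base <- if (v <= nTips(net)) net@tipLabels[v] else net@nodeNames[v]
    if (v %in% hyb) paste0(base, "#", tags[v]) else base
  }
  ann <- function(row) {
    l <- ed$length[row]; g <- ed$gamma[row]
    if (!is.na(g)) {
      paste0(":", if (is.na(l)) "" else num(l), "::", num(g))
    } else if (!is.na(l)) {
      paste0(":", num(l))
    } else ""
  }
  wr <- function(v, row) {
    kids <- which(ed$parent == v)
    sub <- ""
    if (v %in% hyb && visited[v]) {
      sub <- ""  # bare reference
    } else {
      visited[v] <<- TRUE
      if (length(kids)) {
        sub <- paste0("(", paste(vapply(kids, function(e) wr(ed$child[e], e), character(1)),
                                 collapse = ","), ")")
      }
    }
    paste0(sub, lab(v), if (is.na(row)) "" else ann(row))
  }
  paste0(wr(net@root, NA_integer_), ";")
}

## ---------------------------------------------------------------------------
## Conversion between phylo and SpeciesNetwork

#' Convert an ape tree to a SpeciesNetwork
#' @param phy an \code{ape::phylo} tree (rooted).
#' @param lengthUnit recorded unit of the edge lengths.
#' @return a SpeciesNetwork with zero hybrid nodes.
#' @export
phyloToNetwork <- function(phy, lengthUnit = "unknown") {
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object")
  len <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(phy$edge)) else phy$edge.length
  edges <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                      length = len, gamma = NA_real_)
  speciesNetwork(edges, phy$tip.label, lengthUnit = lengthUnit)
}

# Build an ape phylo from a tree-shaped edge table over arbitrary node ids.
# Tips must be ids 1..ntip.  Returns list(phylo, netIdOfPhyloNode).
.edgesToPhylo <- function(ed, tipLabels, root) {
  ntip <- length(tipLabels)
  ids <- sort(unique(c(ed$parent, ed$child)))
  internal <- setdiff(ids, seq_len(ntip))
  # preorder internal numbering with root first (cladewise-ish edge order)
  phyId <- integer(max(ids))
  phyId[seq_len(ntip)] <- seq_len(ntip)
  nxt <- ntip
  childRows <- split(seq_len(nrow(ed)), ed$parent)
  edgeOrder <- integer(0)
  visit <- function(v) {
    if (v > ntip) {
      nxt <<- nxt + 1L
      phyId[v] <<- nxt
    }
    rows <- childRows[[as.character(v)]]
    for (r in rows) {
      edgeOrder <<- c(edgeOrder, r)
      visit(ed$child[r])
    }
  }
  visit(root)
  edm <- cbind(phyId[ed$parent[edgeOrder]], phyId[ed$child[edgeOrder]])
  storage.mode(edm) <- "integer"
  phy <- structure(list(edge = edm,
                        edge.length = ed$length[edgeOrder],
                        tip.label = tipLabels,
                        Nnode = length(internal)),
                   class = "phylo", order = "cladewise")
  netId <- integer(ntip + length(internal))
  netId[phyId[ids]] <- ids
  list(phylo = phy, netId = netId)
}

## ---------------------------------------------------------------------------
## Displayed trees

#' Enumerate the displayed trees of a network
#'
#' A network with \eqn{h} hybrid nodes displays \eqn{2^h} trees, obtained by
#' keeping exactly one parent edge per hybrid node; each tree's probability
#' is the product of the kept \eqn{\gamma} values.  Degree-2 nodes created
#' by edge removal are suppressed with their edge lengths summed, and the
#' suppression map from network nodes to surviving nodes is recorded (used
#' by the ancestral-state machinery).
#'
#' @param net a SpeciesNetwork with \eqn{h \le 12}.
#' @return list of entries with elements \code{phylo} (ape tree whose tips
#'   are the network tips), \code{prob}, \code{choice} (kept parent per
#'   hybrid), \code{surv} (integer vector: network node -> surviving network
#'   node, NA if the node is absent from this displayed tree), and
#'   \code{phyloNode} (network node -> node id in \code{phylo}).
#' @export
displayedTrees <- function(net) {
  stopifnot(is(net, "SpeciesNetwork"))
  hyb <- hybridNodes(net)
  h <- length(hyb)
  if (h > 12) stop("refusing to enumerate displayed trees for h > 12")
  ed0 <- net@edges
  ntip <- nTips(net)
  combos <- if (h == 0) list(integer(0)) else {
    do.call(expand.grid, rep(list(1:2), h))
  }
  nCombo <- if (h == 0) 1L else nrow(combos)
  out <- vector("list", nCombo)
  for (ci in seq_len(nCombo)) {
    ed <- ed0
    prob <- 1
    choice <- integer(h)
    drop <- integer(0)
    for (j in seq_len(h)) {
      rows <- which(ed0$child == hyb[j])
      pick <- if (h == 0) 1L else combos[ci, j]
      choice[j] <- rows[pick]
      prob <- prob * ed0$gamma[rows[pick]]
      drop <- c(drop, rows[-pick])
    }
    if (length(drop)) ed <- ed[-drop, , drop = FALSE]
    ed$gamma <- NULL
    res <- .suppressDegree2(ed, net@root, ntip, net@nNodes)
    conv <- .edgesToPhylo(res$edges, net@tipLabels, res$root)
    surv <- res$surv
    phyloNode <- rep(NA_integer_, net@nNodes)
    ok <- !is.na(surv)
    # map: network node -> phylo node of its surviving node
    lut <- rep(NA_integer_, net@nNodes)
    lut[conv$netId] <- seq_along(conv$netId)
    phyloNode[ok] <- lut[surv[ok]]
    out[[ci]] <- list(phylo = conv$phylo, prob = prob, choice = choice,
                      surv = surv, phyloNode = phyloNode)
  }
  out
}

# Remove dead internal nodes, collapse the root chain and suppress degree-2
# nodes in a tree-shaped edge table.  Returns edges, root, and the
# network-node -> surviving-node map.
.suppressDegree2 <- function(ed, root, ntip, nNodes) {
  surv <- seq_len(nNodes)
  repeat {
    outd <- tabulate(ed$parent, nbins = nNodes)
    ind <- tabulate(ed$child, nbins = nNodes)
    present <- unique(c(ed$parent, ed$child))
    dead <- setdiff(present[outd[present] == 0L], seq_len(ntip))
    dead <- setdiff(dead, root)
    if (length(dead)) {
      surv[!is.na(surv) & surv %in% dead] <- NA_integer_
      ed <- ed[!(ed$child %in% dead), , drop = FALSE]
      next
    }
    if (outd[root] == 1L) {
      e <- which(ed$parent == root)
      newRoot <- ed$child[e]
      surv[surv == root & !is.na(surv)] <- newRoot
      ed <- ed[-e, , drop = FALSE]
      root <- newRoot
      next
    }
    mids <- present[ind[present] == 1L & outd[present] == 1L]
    mids <- setdiff(mids, c(root, seq_len(ntip)))
    if (!length(mids)) break
    v <- mids[[1]]
    eUp <- which(ed$child == v)
    eDn <- which(ed$parent == v)
    tgt <- ed$child[eDn]
    ed$length[eUp] <- ed$length[eUp] + ed$length[eDn]
    ed$child[eUp] <- tgt
    ed <- ed[-eDn, , drop = FALSE]
    surv[surv == v & !is.na(surv)] <- tgt
  }
  list(edges = ed, root = root, surv = surv)
}

## ---------------------------------------------------------------------------
## Distances and times

#' Pairwise taxon distances on a network
#'
#' Defined as the expectation of the patristic (path-sum) distance over the
#' network's displayed trees, weighted by their \eqn{\gamma} probabilities.
#' Reduces to the ordinary patristic matrix when the network is a tree.
#'
#' @param net a SpeciesNetwork with all edge lengths set.
#' @return a symmetric taxon-by-taxon matrix with zero diagonal.
#' @export
networkPairwiseDistances <- function(net) {
  ed <- net@edges
  if (any(is.na(ed$length))) {
    bad <- which(is.na(ed$length))
    stop("missing edge lengths on edges: ",
         paste(sprintf("%d->%d", ed$parent[bad], ed$child[bad]), collapse = ", "))
  }
  dts <- displayedTrees(net)
  labs <- net@tipLabels
  D <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (dt in dts) {
    cd <- ape::cophenetic.phylo(dt$phylo)[labs, labs]
    D <- D + dt$prob * cd
  }
  D
}

#' Node times of a time-consistent network
#'
#' Computes each node's time before present from the edge lengths, with all
#' tips at time 0.  Errors if the edge lengths are not time-consistent
#' (i.e. parent time differs depending on the path taken).
#'
#' @param net a SpeciesNetwork with all edge lengths set.
#' @param tol consistency tolerance (relative to the root age).
#' @return numeric vector of node times, indexed by node id.
#' @export
nodeTimes <- function(net, tol = 1e-6) {
  ed <- net@edges
  if (any(is.na(ed$length))) stop("missing edge lengths; cannot compute node times")
  n <- net@nNodes
  times <- rep(NA_real_, n)
  times[seq_len(nTips(net))] <- 0
  remaining <- ed
  while (nrow(remaining)) {
    ready <- !is.na(times[remaining$child])
    if (!any(ready)) stop("network edge table is not connected")
    for (r in which(ready)) {
      p <- remaining$parent[r]
      t <- times[remaining$child[r]] + remaining$length[r]
      if (is.na(times[p])) {
        times[p] <- t
      } else if (abs(times[p] - t) > tol * max(1, max(times, na.rm = TRUE))) {
        stop(sprintf("network is not time-consistent at node %d (%.8g vs %.8g)",
                     p, times[p], t))
      }
    }
    remaining <- remaining[!ready, , drop = FALSE]
  }
  times
}

## ---------------------------------------------------------------------------
## Reticulation cycles (level-1 helpers)

# Undirected cycle generated by a hybrid node's two parent edges.
# Returns node ids on the cycle, the top node, and undirected edge keys.
.reticulationCycle <- function(ed, hybrid) {
  rows <- which(ed$child == hybrid)
  u1 <- ed$parent[rows[1]]
  u2 <- ed$parent[rows[2]]
  # undirected adjacency without the first hybrid edge
  m <- nrow(ed)
  keep <- setdiff(seq_len(m), rows[1])
  adj <- list()
  addEdge <- function(a, b, key) {
    adj[[as.character(a)]] <<- rbind(adj[[as.character(a)]], c(b, key))
    adj[[as.character(b)]] <<- rbind(adj[[as.character(b)]], c(a, key))
  }
  for (r in keep) addEdge(ed$parent[r], ed$child[r], r)
  # BFS path hybrid -> u1
  prev <- list()
  prevEdge <- list()
  queue <- hybrid
  seen <- as.character(hybrid)
  found <- FALSE
  while (length(queue) && !found) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- adj[[as.character(v)]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      w <- nb[i, 1]
      if (as.character(w) %in% seen) next
      seen <- c(seen, as.character(w))
      prev[[as.character(w)]] <- v
      prevEdge[[as.character(w)]] <- nb[i, 2]
      if (w == u1) { found <- TRUE; break }
      queue <- c(queue, w)
    }
  }
  if (!found) stop("no reticulation cycle found (network malformed?)")
  path <- u1
  edgeKeys <- integer(0)
  v <- u1
  while (v != hybrid) {
    edgeKeys <- c(edgeKeys, prevEdge[[as.character(v)]])
    v <- prev[[as.character(v)]]
    path <- c(path, v)
  }
  nodes <- unique(path)
  edgeKeys <- c(edgeKeys, rows[1])
  # top node: cycle node none of whose parent edges lies on the cycle
  top <- NA_integer_
  for (v in nodes) {
    pe <- which(ed$child == v)
    if (!length(intersect(pe, edgeKeys))) { top <- v; break }
  }
  list(nodes = nodes, top = top,
       edgeKeys = sort(edgeKeys))
}

#' Reticulation cycles of a network
#'
#' @param net a SpeciesNetwork.
#' @return list per hybrid node with elements \code{hybrid}, \code{nodes}
#'   (node ids on the cycle), \code{top} (the cycle's uppermost node) and
#'   \code{edgeRows} (rows of \code{networkEdges(net)} on the cycle).
#' @export
reticulationCycles <- function(net) {
  hyb <- hybridNodes(net)
  lapply(hyb, function(v) {
    cyc <- .reticulationCycle(net@edges, v)
    list(hybrid = v, nodes = cyc$nodes, top = cyc$top, edgeRows = cyc$edgeKeys)
  })
}

## ---------------------------------------------------------------------------
## Network surgery (used to construct simulation scenarios and fixtures)

#' Add a hybrid edge to a time-consistent network
#'
#' Subdivides the donor and recipient edges at time \code{at} (both edges
#' must span that time) and inserts a horizontal hybrid edge from the donor
#' to the new hybrid node on the recipient edge, with inheritance
#' probability \code{gamma} on the new edge (the recipient's original
#' parent edge gets \code{1 - gamma}).
#'
#' @param net a SpeciesNetwork (typically a tree) with time-consistent
#'   lengths.
#' @param donor,recipient taxon label (the edge above that tip) or a
#'   character vector of taxa (the edge above their MRCA).
#' @param at time of the attachment, before present.
#' @param gamma inheritance probability of the new (donor -> recipient)
#'   edge.
#' @return a SpeciesNetwork with one extra hybrid node.
#' @export
addHybridEdge <- function(net, donor, recipient, at, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  times <- nodeTimes(net)
  eDonor <- .edgeAbove(net, donor)
  eRecip <- .edgeAbove(net, recipient)
  if (eDonor == eRecip) stop("donor and recipient edges must differ")
  ed <- net@edges
  spans <- function(e) {
    times[ed$child[e]] < at + 1e-12 && at < times[ed$parent[e]] + 1e-12
  }
  if (!spans(eDonor)) stop("donor edge does not span time 'at'")
  if (!spans(eRecip)) stop("recipient edge does not span time 'at'")
  n <- net@nNodes
  dNode <- n + 1L   # new tree node on the donor edge
  hNode <- n + 2L   # new hybrid node on the recipient edge
  newRows <- data.frame(
    parent = c(ed$parent[eDonor], dNode, ed$parent[eRecip], dNode),
    child  = c(dNode, ed$child[eDonor], hNode, hNode),
    length = c(times[ed$parent[eDonor]] - at, at - times[ed$child[eDonor]],
               times[ed$parent[eRecip]] - at, 0),
    gamma  = c(NA, NA, 1 - gamma, gamma)
  )
  keepRecipLen <- at - times[ed$child[eRecip]]
  ed2 <- ed[-c(eDonor, eRecip), , drop = FALSE]
  ed2 <- rbind(ed2, newRows,
               data.frame(parent = hNode, child = ed$child[eRecip],
                          length = keepRecipLen, gamma = NA))
  nodeNames <- c(net@nodeNames, "", "")
  hybridTags <- c(net@hybridTags, "", paste0("H", nHybrids(net) + 1L))
  out <- speciesNetwork(ed2, net@tipLabels, nodeNames = nodeNames,
                        hybridTags = hybridTags, lengthUnit = net@lengthUnit)
  validObject(out)
  out
}

# Edge above a tip or above the MRCA of a taxon set; returns the row index.
.edgeAbove <- function(net, taxa) {
  ed <- net@edges
  tipIds <- match(taxa, net@tipLabels)
  if (any(is.na(tipIds))) stop("unknown taxa: ", paste(taxa[is.na(tipIds)], collapse = ", "))
  if (length(tipIds) == 1L) {
    rows <- which(ed$child == tipIds)
    if (length(rows) != 1L) stop("tip has no unique parent edge")
    return(rows)
  }
  # MRCA in the tree skeleton (follow first parent at hybrids)
  anc <- function(v) {
    path <- v
    repeat {
      rows <- which(ed$child == v)
      if (!length(rows)) break
      v <- ed$parent[rows[1]]
      path <- c(path, v)
    }
    path
  }
  paths <- lapply(tipIds, anc)
  common <- Reduce(intersect, paths)
  mrca <- common[which.min(match(common, paths[[1]]))]
  rows <- which(ed$child == mrca)
  if (!length(rows)) stop("MRCA is the root; no edge above it")
  rows[1]
}

## ---------------------------------------------------------------------------
## Canonical topology strings

#' Canonical topology string of a network
#'
#' The sorted multiset of canonical rooted-topology strings of the
#' network's displayed trees (children sorted recursively, lengths and
#' \eqn{\gamma} dropped).  The form is independent of node numbering and
#' of which hybrid occurrence carries the subtree in an extended-newick
#' representation, so two networks share a string iff they display the
#' same rooted tree topologies.
#'
#' @param net a SpeciesNetwork.
#' @return a character scalar.
#' @export
canonicalTopology <- function(net) {
  strs <- vapply(displayedTrees(net), function(dt) {
    .canonicalTreeString(dt$phylo)
  }, character(1))
  paste0("h", nHybrids(net), "{", paste(sort(unique(strs)), collapse = " "), "}")
}

# sorted-children rooted topology string of a phylo, lengths dropped
.canonicalTreeString <- function(phy) {
  ntip <- length(phy$tip.label)
  kidsOf <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    parts <- sort(vapply(kidsOf[[as.character(v)]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(ntip + 1L), ";")
}
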