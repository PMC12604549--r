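## Equal-rates (Mk) discrete-trait likelihood and marginal ancestral state
## reconstruction on a calibrated network, computed over displayed trees.

#' Equal-rates transition probability matrix
#'
#' For the k-state symmetric model with rate \code{alpha}:
#' \eqn{P(i \to j \mid t) = 1/k - (1/k) e^{-k \alpha t}} for \eqn{i \ne j}
#' and \eqn{P(i \to i \mid t) = 1/k + (1 - 1/k) e^{-k \alpha t}}.
#'
#' @param k number of states.
#' @param alpha rate, > 0.
#' @param t duration, >= 0.
#' @return a k x k stochastic matrix.
#' @export
ersmTransition <- function(k, alpha, t) {
  if (alpha <= 0) stop("alpha must be > 0")
  e <- exp(-k * alpha * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (1 - 1 / k) * e
  P
}

# normalize a calibrated or plain network argument
.asNetwork <- function(net) {
  if (inherits(net, "calibratedNetwork")) net$network else net
}

# postorder partial likelihoods on a phylo; tipStates: named integer 1..k
.prunePartials <- function(phy, tipStates, k, alpha) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  L <- matrix(0, nn, k)
  st <- tipStates[phy$tip.label]
  if (any(is.na(st))) stop("missing tip states: ",
                           paste(phy$tip.label[is.na(st)], collapse = ", "))
  L[cbind(seq_len(ntip), st)] <- 1
  # postorder: reverse cladewise edge order visits children before parents
  edges <- phy$edge
  done <- c(rep(TRUE, ntip), rep(FALSE, phy$Nnode))
  init <- rep(FALSE, nn)
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1]; c_ <- edges[e, 2]
    P <- ersmTransition(k, alpha, phy$edge.length[e])
    contrib <- as.numeric(P %*% L[c_, ])
    if (!init[p]) {
      L[p, ] <- contrib
      init[p] <- TRUE
    } else {
      L[p, ] <- L[p, ] * contrib
    }
  }
  L
}

# tree log-likelihood with uniform root prior
.pruneLoglik <- function(phy, tipStates, k, alpha) {
  L <- .prunePartials(phy, tipStates, k, alpha)
  root <- length(phy$tip.label) + 1L
  log(mean(L[root, ]))
}

#' Trait log-likelihood on a network under the equal-rates model
#'
#' \eqn{L = \sum_T P(T) \, L_T(\alpha)} over displayed trees T, with
#' \eqn{L_T} from Felsenstein pruning under the equal-rates model and a
#' uniform root prior.
#'
#' @param net a calibrated network (or \code{"calibratedNetwork"}).
#' @param tipStates named integer vector of states (1..k) per taxon, or a
#'   character/factor vector (levels define the states).
#' @param alpha rate, > 0.
#' @param k number of states (default: inferred from the data/levels).
#' @return log-likelihood.
#' @export
networkTraitLoglik <- function(net, tipStates, alpha, k = NULL) {
  net <- .asNetwork(net)
  ts <- .encodeStates(tipStates, k)
  dts <- displayedTrees(net)
  lls <- vapply(dts, function(dt) .pruneLoglik(dt$phylo, ts$states, ts$k, alpha),
                numeric(1))
  probs <- vapply(dts, `[[`, numeric(1), "prob")
  keep <- probs > 0
  m <- max(lls[keep])
  m + log(sum(probs[keep] * exp(lls[keep] - m)))
}

.encodeStates <- function(tipStates, k = NULL) {
  if (is.character(tipStates) || is.factor(tipStates)) {
    f <- factor(tipStates)
    states <- setNames(as.integer(f), names(tipStates))
    levels_ <- levels(f)
    if (is.null(k)) k <- length(levels_)
    if (k < length(levels_)) stop("k smaller than the number of observed states")
  } else {
    states <- tipStates
    levels_ <- NULL
    if (is.null(k)) k <- max(states, na.rm = TRUE)
  }
  if (k < 2) k <- 2L
  list(states = states, k = as.integer(k), levels = levels_)
}

#' Fit the equal-rates rate on a network
#'
#' One-dimensional maximization of \code{\link{networkTraitLoglik}} over
#' \eqn{\log \alpha}, \eqn{\alpha \in [10^{-8}, 10^3]}.  Several traits
#' (a matrix with one column per trait) share a single rate, with the
#' log-likelihoods summed.  Boundary hits are flagged.
#'
#' @param net calibrated network.
#' @param tipStates named vector (one trait) or matrix (taxa x traits).
#' @param k number of states (default inferred).
#' @return list with \code{alpha}, \code{loglik}, \code{boundary}.
#' @export
fitErsm <- function(net, tipStates, k = NULL) {
  net <- .asNetwork(net)
  traits <- if (is.matrix(tipStates)) tipStates else
    matrix(tipStates, ncol = 1, dimnames = list(names(tipStates), NULL))
  f <- function(logAlpha) {
    a <- exp(logAlpha)
    sum(vapply(seq_len(ncol(traits)), function(j) {
      networkTraitLoglik(net, setNames(traits[, j], rownames(traits)), a, k)
    }, numeric(1)))
  }
  opt <- optimize(f, c(log(1e-8), log(1e3)), maximum = TRUE, tol = 1e-8)
  alpha <- exp(opt$maximum)
  boundary <- alpha <= 1.01e-8 || alpha >= 0.99e3
  list(alpha = alpha, loglik = opt$objective, boundary = boundary)
}

# marginal posteriors at every node of one displayed tree (up-down pass)
.treeMarginals <- function(phy, tipStates, k, alpha) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  Dn <- .prunePartials(phy, tipStates, k, alpha)
  root <- ntip + 1L
  Up <- matrix(0, nn, k)
  Up[root, ] <- 1 / k
  edges <- phy$edge
  kidsOf <- split(seq_len(nrow(edges)), edges[, 1])
  # preorder (cladewise): parents processed before children
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; c_ <- edges[e, 2]
    P <- ersmTransition(k, alpha, phy$edge.length[e])
    sibs <- setdiff(kidsOf[[as.character(p)]], e)
    sibContrib <- rep(1, k)
    for (se in sibs) {
      Ps <- ersmTransition(k, alpha, phy$edge.length[se])
      sibContrib <- sibContrib * as.numeric(Ps %*% Dn[edges[se, 2], ])
    }
    Up[c_, ] <- as.numeric(t(P) %*% (Up[p, ] * sibContrib))
  }
  M <- Up * Dn
  M / rowSums(M)
}

#' Marginal ancestral states on a network
#'
#' Per network node v, the posterior mixes the displayed trees'
#' marginal reconstructions with weights \eqn{P(T) L_T / L}; a node
#' suppressed in a displayed tree inherits the posterior of its surviving
#' descendant node.
#'
#' @param net calibrated network.
#' @param tipStates named vector of tip states.
#' @param alpha fitted rate.
#' @param k number of states (default inferred).
#' @return object of class \code{"asrResult"}: list with
#'   \code{posterior} (network nodes x states, rows sum to 1; tip rows are
#'   point masses), \code{alpha}, \code{loglik}, \code{treeWeights},
#'   \code{states} (level labels when the input was character/factor).
#' @export
marginalAsr <- function(net, tipStates, alpha, k = NULL) {
  net <- .asNetwork(net)
  ts <- .encodeStates(tipStates, k)
  dts <- displayedTrees(net)
  probs <- vapply(dts, `[[`, numeric(1), "prob")
  lls <- vapply(dts, function(dt) .pruneLoglik(dt$phylo, ts$states, ts$k, alpha),
                numeric(1))
  keep <- probs > 0
  m <- max(lls[keep])
  wts <- numeric(length(dts))
  wts[keep] <- probs[keep] * exp(lls[keep] - m)
  wts <- wts / sum(wts)
  post <- matrix(0, net@nNodes, ts$k)
  wsum <- numeric(net@nNodes)
  for (i in seq_along(dts)) {
    if (wts[i] == 0) next
    dt <- dts[[i]]
    M <- .treeMarginals(dt$phylo, ts$states, ts$k, alpha)
    for (v in seq_len(net@nNodes)) {
      pn <- dt$phyloNode[v]
      if (is.na(pn)) next
      post[v, ] <- post[v, ] + wts[i] * M[pn, ]
      wsum[v] <- wsum[v] + wts[i]
    }
  }
  ok <- wsum > 0
  post[ok, ] <- post[ok, , drop = FALSE] / wsum[ok]
  post[!ok, ] <- NA_real_
  rn <- c(tipLabels(net), paste0("node", (nTips(net) + 1L):net@nNodes))
  dimnames(post) <- list(rn, if (!is.null(ts$levels)) ts$levels else paste0("state", seq_len(ts$k)))
  ll <- m + log(sum(probs[keep] * exp(lls[keep] - m)))
  structure(list(posterior = post, alpha = alpha, loglik = ll,
                 treeWeights = wts, states = ts$levels),
            class = "asrResult")
}

#' Fit and reconstruct several discrete traits on a network
#'
#' Runs \code{\link{fitErsm}} and \code{\link{marginalAsr}} per trait
#' (each trait gets its own fitted rate) on the same calibrated network
#' and combines the node posteriors into one long table.
#'
#' @param net calibrated network.
#' @param traitTable data.frame with a \code{taxon} column and one column
#'   per trait (character states), e.g. from \code{\link{readTraitTable}}.
#' @param traits trait columns to analyze (default: all non-taxon
#'   columns).
#' @param onMissing "error" (default) or "drop" for taxa without a state.
#' @return list with \code{results} (one \code{"asrResult"} per trait),
#'   \code{alpha} (named vector) and \code{table} (node x trait x state
#'   posterior, long format).
#' @export
reconstructAll <- function(net, traitTable, traits = NULL,
                           onMissing = c("error", "drop")) {
  onMissing <- match.arg(onMissing)
  net0 <- .asNetwork(net)
  if (!"taxon" %in% names(traitTable)) stop("traitTable needs a 'taxon' column")
  if (is.null(traits)) traits <- setdiff(names(traitTable), "taxon")
  labs <- tipLabels(net0)
  results <- list()
  rows <- list()
  for (tr in traits) {
    st <- setNames(as.character(traitTable[[tr]]), traitTable$taxon)
    st <- st[!is.na(st) & nzchar(st)]
    missing_ <- setdiff(labs, names(st))
    useNet <- net0
    if (length(missing_)) {
      if (onMissing == "error") {
        stop("taxa without a state for trait '", tr, "': ",
             paste(missing_, collapse = ", "))
      }
      stop("dropping taxa is not supported on networks; supply states for: ",
           paste(missing_, collapse = ", "))
    }
    fit <- fitErsm(useNet, st[labs])
    asr <- marginalAsr(useNet, st[labs], fit$alpha)
    results[[tr]] <- asr
    pp <- asr$posterior
    rows[[tr]] <- data.frame(node = rep(rownames(pp), ncol(pp)),
                             trait = tr,
                             state = rep(colnames(pp), each = nrow(pp)),
                             posterior = as.numeric(pp),
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(results = results,
       alpha = vapply(results, `[[`, numeric(1), "alpha"),
       table = tab)
}
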