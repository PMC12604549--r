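## A reproducible synthetic study scenario shaped like the package's
## target use case: 17 ingroup taxa plus one outgroup, ~1000 nuclear
## loci, incomplete lineage sorting from the coalescent and one
## introgression event from gamma-mixing on a level-1 network.

#' Build the synthetic study scenario
#'
#' Constructs a deterministic 18-taxon species network (17 ingroup taxa
#' and the outgroup \code{"OUT"}) in coalescent units: a random
#' ultrametric ingroup tree (seeded), an outgroup attached above the
#' ingroup root, and one hybrid edge between two well-separated ingroup
#' taxa.  Also derives the four-group configuration around the
#' reticulation (P2 = recipient, P3 = donor, P1 = the recipient's closest
#' non-donor relative, P4 = a distant ingroup taxon), the topology
#' designation (major = species-tree pairing, minor = the
#' introgression pairing), and a three-trait table simulated on the
#' network under the equal-rates model.
#'
#' @param seed integer seed controlling the ingroup topology, the hybrid
#'   placement and the simulated traits.
#' @param nIngroup number of ingroup taxa (default 17).
#' @param gamma inheritance probability of the introgression edge
#'   (default 0.3).
#' @param alphaTrait equal-rates rate used to simulate the trait table
#'   (default 0.5).
#' @return list with \code{network} (one hybrid), \code{backbone} (the
#'   h = 0 species tree), \code{outgroup}, \code{donor},
#'   \code{recipient}, \code{grouping} (a
#'   \linkS4class{GroupingConfig}), \code{designation}, and
#'   \code{traits} (data.frame: taxon, longevity, fruit, environment).
#' @export
studyScenario <- function(seed = 20L, nIngroup = 17L, gamma = 0.3,
                          alphaTrait = 0.5) {
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)
  ing <- ape::rcoal(nIngroup, tip.label = sprintf("T%02d", seq_len(nIngroup)))
  # rescale so the ingroup crown sits at 3 coalescent units
  depth <- max(ape::node.depth.edgelength(ing))
  ing$edge.length <- ing$edge.length * 3 / depth
  nwk <- ape::write.tree(ing)
  full <- sprintf("(%s:1,OUT:4);", sub(";$", "", nwk))
  backbone <- parseExtendedNewick(full, lengthUnit = "coalescent")
  # donor/recipient: the two tips with the longest terminal branches that
  # are not sisters, attached at half the shorter branch
  times <- nodeTimes(backbone)
  ed <- backbone@edges
  term <- vapply(seq_len(nIngroup), function(v) {
    r <- which(ed$child == match(sprintf("T%02d", v), tipLabels(backbone)))
    ed$length[r]
  }, numeric(1))
  D0 <- ape::cophenetic.phylo(ing)
  ord <- order(term, decreasing = TRUE)
  donor <- sprintf("T%02d", ord[1])
  recipient <- NA_character_
  for (k in ord[-1]) {
    cand <- sprintf("T%02d", k)
    if (D0[donor, cand] > 2) { recipient <- cand; break }
  }
  at <- 0.5 * min(term[match(donor, sprintf("T%02d", seq_len(nIngroup)))],
                  term[match(recipient, sprintf("T%02d", seq_len(nIngroup)))])
  network <- addHybridEdge(backbone, donor = donor, recipient = recipient,
                           at = at, gamma = gamma)
  # grouping around the reticulation
  others <- setdiff(rownames(D0), c(donor, recipient))
  p1 <- others[which.min(D0[recipient, others])]
  rest <- setdiff(others, p1)
  p4 <- rest[which.max(D0[recipient, rest] + D0[donor, rest])]
  grouping <- groupingConfig(P1 = p1, P2 = recipient, P3 = donor, P4 = p4,
                             outgroup = "OUT")
  # designation: pairings are indexed on the sorted quartet; find which
  # pairing corresponds to {P1,P2} (major) and {P2,P3} (minor)
  q <- sort(c(p1, recipient, donor, p4))
  pairingOf <- function(a, b) {
    pr <- sort(c(match(a, q), match(b, q)))
    if (identical(pr, c(1L, 2L)) || identical(pr, c(3L, 4L))) 1L
    else if (identical(pr, c(1L, 3L)) || identical(pr, c(2L, 4L))) 2L
    else 3L
  }
  major <- pairingOf(p1, recipient)
  minor <- pairingOf(recipient, donor)
  designation <- c(major, minor, setdiff(1:3, c(major, minor)))
  # traits simulated on the network
  st <- simulateTraitsOnNetwork(network, alpha = alphaTrait, k = 2L,
                                nTraits = 3L, seed = seed + 1L)
  lv <- list(longevity = c("semelparous", "iteroparous"),
             fruit = c("homocarpic", "heterocarpic"),
             environment = c("predictable", "unpredictable"))
  traits <- data.frame(taxon = rownames(st$tipStates),
                       longevity = lv$longevity[st$tipStates[, 1]],
                       fruit = lv$fruit[st$tipStates[, 2]],
                       environment = lv$environment[st$tipStates[, 3]],
                       stringsAsFactors = FALSE)
  list(network = network, backbone = backbone, outgroup = "OUT",
       donor = donor, recipient = recipient, grouping = grouping,
       designation = designation, traits = traits)
}
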