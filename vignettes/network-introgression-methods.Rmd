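---
title: "Methods: introgression analysis on species networks with retic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression analysis on species networks with retic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retic)
```

# The problem

Hybridization leaves a genomic signature that is easy to confuse with
incomplete lineage sorting (ILS): both produce gene trees that disagree
with the species tree. `retic` implements a network-based workflow for
telling the two apart and for reconstructing trait evolution once a
reticulate history has been accepted: gene-tree quality control, topology
weighting with a chi-square test of the ILS null, site-pattern statistics
(Patterson's D, the f4-ratio and the f-branch summary), pseudolikelihood
scoring of candidate level-1 networks, calibration of a selected network
to ultrametric node ages, and equal-rates ancestral state reconstruction
on the calibrated network. A coalescent-on-network simulator provides
ground-truthed inputs for every stage, so each statistical claim the
package makes is checked against data whose generating parameters are
known.

# The generative model and the simulator

The central object is a rooted **level-1 species network**: a binary tree
augmented with hybrid nodes of in-degree 2, each parent edge of a hybrid
carrying an inheritance probability $\gamma$ (the pair sums to 1), and no
two reticulation cycles sharing an edge. Edge lengths are in coalescent
units (time / population size).

`simulateGeneTrees()` runs the multispecies coalescent backwards in time
on such a network: within an edge, $k$ lineages coalesce at rate
$k(k-1)/2$; at a hybrid node every lineage independently picks a parent
edge with probability $\gamma$; above the root coalescence continues to a
single lineage. Gene trees are ultrametric in coalescent units;
`scaleToSubstitutions()` multiplies each tree by an i.i.d. lognormal
multiplier to emulate among-locus substitution-rate variation, and
`simulateSnpMatrix()` places one infinite-sites mutation per locus on a
branch drawn proportionally to branch length, yielding biallelic 0/1
genotypes with configurable missingness.

Randomness follows a strict counter contract: one root seed, with the
stream for locus $i$ derived from $(\mathrm{seed}, i)$ by a hash
(splitmix64 seeding xorshift128+), so locus $i$ is byte-reproducible
regardless of how many loci are simulated, and identical seeds give
byte-identical outputs end to end.

**What the generator emulates, and what it does not.** Defaults mirror a
target-capture study design: 17 ingroup taxa plus one outgroup
(`studyScenario()`), on the order of a thousand nuclear loci, gene trees
of unequal size (each taxon dropped per locus with probability
`mTax = 0.05`), lognormal rate variation (`sigmaRate = 0.4`), and SNP
matrices with tens of individuals and a few thousand biallelic sites with
masked genotypes (`mGt = 0.1`, sites with at least 20% missing data are
later filtered out). It does **not** simulate sequence evolution
(mutations are infinite-sites, one per locus), recombination within loci,
gene-tree estimation error, alignment or orthology error, or gene flow
models other than hybrid-edge $\gamma$-mixing. Passing tests therefore
demonstrate correctness of the *inference machinery* under the coalescent
with reticulation, not robustness to upstream bioinformatic noise.

# Gene-tree quality control

`filterGeneTree()` applies two patristic-distance criteria with inclusive
boundaries: the maximum distance among ingroup taxa must not exceed 1.5
times the maximum ingroup–outgroup distance, and the minimum
ingroup–outgroup distance must be at least $10^{-4}$ (both thresholds are
exposed as arguments). Distances are tip-to-tip path sums and therefore
rooting-independent; the ratio criterion is scale-invariant while the
floor is deliberately scale-sensitive, catching near-zero outgroup
attachment. Trees lacking the outgroup are excluded rather than raising
an error, so unattended batches run through. Filtering precedes
normalization: `normalizeTree()` divides all branch lengths by the mean
outgroup–ingroup distance, making that mean exactly 1 — an idempotent,
ratio-preserving rescaling that puts loci with different substitution
rates on a common scale before distance-based calibration.

# Topology weighting and the ILS null

For four taxon groups, only three unrooted quartet topologies exist.
`quartetTopologyWeights()` enumerates every combination of one tip per
group and assigns each combination's vote to the topology induced by the
tree (unresolved quartets split their vote equally among the compatible
topologies); weights are vote proportions. Enumeration is exact below
$10^6$ combinations — group sizes here are small, so exactness is cheap —
with a seeded sampling fallback above. The implementation determines the
quartet from MRCA depths; the test suite checks it against an independent
prune-and-inspect enumerator on hundreds of random (partly polytomous)
trees, exactly.

Majority rule (`assignSupport()`) gives the highest-weight topology
support 1, splitting ties equally, so per-tree supports lie in
$\{0, \tfrac13, \tfrac12, 1\}$. Under ILS alone the two non-major
topologies are expected at equal frequency, while introgression inflates
the one that groups donor with recipient. `ilsChisqTest()` compares the
minor and contradictory counts with a 1-df chi-square against equality.
Fractional support sums are rounded to the nearest integer pair
preserving their total (and flagged), keeping the count-based test
well-defined. The reported p-value is the two-sided upper tail; the signed
direction (minor vs contradictory excess) is reported separately rather
than guessing a one-sided convention. Simulation places the test's type-I
error within [0.03, 0.07] at nominal 0.05 and its power above 0.9 for
$\gamma = 0.3$ at 2000 loci.

# Site-pattern statistics

`filterSnps()` retains biallelic sites with missing fraction strictly
below 0.2 and thins greedily from the lowest position, keeping a site
only if it is at least 100 bp past the last kept site in the same locus
(greedy-from-the-left is deterministic; the thinning algorithm is not
dictated by any standard, so the simplest reproducible rule was chosen).

With population derived-allele frequencies $p_1, p_2, p_3, p_O$,
Patterson's D is
$\sum (1-p_1)p_2p_3(1-p_O) - p_1(1-p_2)p_3(1-p_O)$ over the sum of the
same two terms; the f4-ratio keeps D's numerator and substitutes the
donor $p_3$ into the recipient position in the denominator, estimating
the admixture fraction $\gamma$. Standard errors come from a
delete-one-block jackknife over sites (20 equal blocks by default — the
block count is a parameter, since no single convention exists) and
p-values from the two-sided normal tail of $Z$.

A practical caveat the package's own simulations expose: with a *single*
haploid sample per taxon, the f4-ratio denominator absorbs the entire
private drift of the donor lineage, biasing $\hat\gamma$ downward by
roughly a third in our scenarios. With population samples (8 individuals
per taxon via `expandPopulations()`, matching the multi-individual SNP
matrices this workflow is designed for) the estimator recovers
$\gamma \in \{0.1, 0.3, 0.5\}$ within $\pm 0.07$ at 5000 loci. The
acceptance suite runs the population-sample design; single-sample runs
are supported but should be interpreted qualitatively.

`fBranch()` summarizes f4-ratios over a rooted reference tree: for branch
$b$ and candidate donor $C$, the median over descendants $a$ of $b$ of
the minimum over representatives $A$ of $b$'s sister of
$f_4(A, a; C, O)$, with negative contributing ratios floored at zero —
mirroring the reference implementation of this statistic, which this
package deliberately reproduces rather than "improves". Cells where $C$
descends from $b$ or its sister are undefined. P-values are taken from
the jackknife $Z$ of the combination attaining the reported value and
adjusted by Benjamini–Hochberg across defined cells.
`simpleMatchingSimilarity()` gives the matching-proportion heatmap matrix
over comparable (both-genotyped) sites.

# Scoring candidate networks

A network with $h$ hybrid nodes displays $2^h$ trees
(`displayedTrees()`), each with probability equal to the product of its
chosen $\gamma$ values. Expected quartet concordance factors are computed
as the $\gamma$-weighted mixture of displayed-tree CFs, where a displayed
tree whose pruned quartet has internal length $t$ contributes
$(1 - \tfrac23 e^{-t}, \tfrac13 e^{-t}, \tfrac13 e^{-t})$. **This mixture
is an approximation**: it is exact whenever, restricted to the quartet,
lineages cannot coalesce between the two hybrid-edge endpoints inside the
reticulation cycle — in particular whenever each hybrid subtends a single
sampled taxon, which covers the simulation designs used throughout. The
full coalescent case analysis inside cycles is not reproduced; the
simulator quantifies the residual error on any configuration of interest
(below 0.005 absolute CF error in the shipped scenarios).

`pseudoLoglik()` scores a network against observed CFs as the
count-weighted multinomial cross-entropy
$\sum_q n_q \sum_k \mathrm{obs}_{qk} \log \mathrm{exp}_{qk}$ (expected
CFs floored at $10^{-12}$), which matches a SNaQ-style multinomial
pseudolikelihood up to data-only constants — so score *differences*, the
only quantities the thresholds consume, are comparable. "Log units" are
natural-log units. Candidate ranking follows fixed rules: candidates
whose reticulation involves the outgroup are excluded a priori
(`excludeOutgroupReticulations()`); within a reticulation count,
$\Delta$ = reference − candidate classifies support as strong
($\Delta \le 10$), moderate ($10 < \Delta \le 20$), poor
($20 < \Delta < 30$) or excluded ($\Delta \ge 30$); boundary values go to
the better class. `selectPrevailing()` picks, among reticulation counts
where some topology has strong-or-moderate support in a majority of
resamplings, the highest count, returning every topology supported in at
least two resamplings, ordered by supporting resamplings then mean score;
when no count reaches a majority the highest count with a twice-supported
topology is used, and failing even that, the best tree-like candidate is
returned with a warning. Network *search* is out of scope: candidates
come from the user. Topology identity across resamplings uses the sorted
multiset of displayed-tree topologies, which is invariant to node
numbering and to extended-newick representation choices.

# Calibration to ultrametric ages

`calibrateNetwork()` fits node ages to a matrix $\bar D$ of mean pairwise
patristic distances from (normalized) gene trees by minimizing

$$F(\mathrm{ages}, p) = \sum_{i<j} \left[ d_{net}(i,j) - \bar D(i,j)^p \right]^2
  + w \sum_{e\,\mathrm{internal}} \left[ l_e(\mathrm{ages}) - l^0_e \right]^2$$

with $w$ = mean off-diagonal of $\bar D$ over the mean initial internal
branch length (computed once from the inputs), $l^0$ the input network's
internal lengths, and the exponent $p$ searched in
$[p_{init}/10,\, 10\,p_{init}]$. Design choices worth recording:

* **Ages, not edge lengths.** Parameterizing by node ages makes
  ultrametricity and the hybrid-below-parents constraint structural. In
  an ultrametric network the expected distance is
  $d_{net}(i,j) = 2 \sum_T P(T)\, \mathrm{age}(\mathrm{mrca}_T(i,j))$ —
  *linear* in the ages — so for fixed $p$ the inner problem is a linear
  least squares, solved by QR in microseconds. The outer 1-D search over
  $p$ uses a 25-point log-grid plus local refinement (tolerance
  $10^{-9}$); it scores the unconstrained optimum, a tight lower bound,
  and the age-order constraints are enforced once at the selected $p$ by
  a seeded multistart BFGS in a feasible parameterization (log root age,
  logistic fractions), warm-started from the clipped linear solution.
* **Terminal branches are unpenalized**: the procedure exists precisely
  to compute terminal branch lengths, so only internal-branch changes are
  charged.
* The power transform applies to the distance matrix entries; the penalty
  compares post-transform fitted lengths against the input lengths as
  given.

On perfect data (distances generated from an ultrametric tree) the
procedure recovers ages to $10^{-6}$ with objective below $10^{-10}$, and
recovers $p \approx 0.5$ from squared distances within $\pm 0.05$.
Calibrated ages are relative (no absolute time calibration is attempted).

# Ancestral states on networks

The equal-rates $k$-state model has the closed-form transition kernel
$P(i \to j \mid t) = \tfrac1k - \tfrac1k e^{-k\alpha t}$ for $i \ne j$.
`networkTraitLoglik()` evaluates
$L = \sum_T P(T)\, L_T(\alpha)$ over displayed trees with $L_T$ by
Felsenstein pruning under a uniform root prior (the conventional default;
nothing in the workflow pins the root frequency). `fitErsm()` maximizes
over $\log\alpha \in [\log 10^{-8}, \log 10^3]$, flagging boundary hits;
several traits can share one rate by summing log-likelihoods, which is
how the rate-recovery check is run (a single trait on ~10 taxa carries
little information about $\alpha$). `marginalAsr()` mixes per-tree
marginal posteriors (up–down algorithm) with weights $P(T) L_T / L$; a
node suppressed in a displayed tree (its outgoing hybrid edge was
removed) inherits the posterior of its surviving descendant, so every
network node gets a posterior. Traits are coded binary by default
(semelparous/iteroparous, homocarpic/heterocarpic,
predictable/unpredictable); $k > 2$ state codings are supported should a
trait require an intermediate state. Exact displayed-tree enumeration is
used throughout ($2^h \le 32$ at the supported $h \le 5$), not
per-lineage approximations.

# Numerical conventions and degenerate inputs

* Expected CFs floored at $10^{-12}$ inside logs; tie detection in
  majority rule at $10^{-9}$; $\gamma$ pairs validated to $10^{-6}$;
  round-trip I/O asserted to $10^{-9}$; ultrametricity to $10^{-8}$.
* Genotype missingness is a distinguished code (`NA` / `.`), never an
  allele count; positions are 1-based.
* Degenerate cases are defined, not fatal: zero-length internal branches
  give star CFs of 1/3; a zero-total-length locus is skipped with a
  warning; pairs with no comparable sites get `NA` similarity; identical
  tips drive the fitted rate to the lower boundary with a flag.
* Pipeline stages log their parameters and write a `.done` marker;
  reruns resume after completed stages, and pre-flight validation
  rejects configs whose inputs are missing before any stage runs.

# Problem sizes used in the shipped checks

The test and acceptance workloads use sizes at which the asymptotic
claims are comfortably resolved on a single CPU: 20,000 loci for
closed-form CF checks (binomial SE ~0.003 against ±0.01 bands), 500
replicates of 1000 loci for test calibration, 50 replicates of 2000 loci
per $\gamma$ for recovery rates, 5000 loci for f4-ratios, 100 random
trees for calibration exactness, 200 traits for rate recovery, and the
18-taxon / 964-locus scenario for the end-to-end reproducibility run.

# Known limitations

* The displayed-tree CF mixture is exact only outside within-cycle
  coalescence (see above); for hybrids subtending large clades the
  pseudolikelihood ranks networks under a documented approximation.
* The f4-ratio needs population samples for quantitative $\gamma$
  recovery; single-sample designs are biased toward zero.
* Level-1 networks only, $h \le 5$ recommended ($2^h$ enumeration), no
  network search, no recombination, no gene-tree error model, relative
  (not absolute) calibrated ages.
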