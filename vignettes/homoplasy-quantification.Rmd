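---
title: "Quantifying morphological homoplasy: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphological homoplasy: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoplasr)
```

This vignette is the package's account of the science behind its functions:
the parsimony model and its two resolutions, the homoplasy indices, the
state and mechanism classifications, the statistical tests, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The setting

The input is a taxa-by-characters table of unordered discrete states
(`0`–`8`, `?` for missing or inapplicable observations) together with a
rooted phylogeny estimated from independent (molecular) data. Because the
tree is not inferred from the morphology, every excess step a character
needs on that tree is evidence of homoplasy — recurrent gain, parallel
change or reversal — rather than an artifact of tree fitting. Characters
carry two pieces of metadata: the developmental stage at which they are
expressed (egg, three larval instars, pupa, adult) and, for adult
characters, the body part (head, thorax, abdomen, male or female
terminalia). Stage and organ structure the downstream statistics.

## Parsimony reconstruction

`reconstruct_parsimony()` minimises the number of state changes under unit
transformation costs. Lengths are computed with Hartigan's generalisation of
the Fitch down-pass, which is exact on polytomous nodes; consensus trees
therefore need no prior resolution. Missing observations enter as complete
ambiguity (any state) and never increase tree length; reconstructed states
at missing tips are excluded from all tip-based counts downstream.

A minimum-length ancestral assignment is generally not unique. The package
implements the two classical conventions as a deterministic preorder sweep
over the dynamic-programming cost tables:

* **ACCTRAN** (accelerate): a node abandons the parental state whenever
  that strictly lowers the cost of its subtree, so changes move as close to
  the root as possible and homoplasy is expressed as reversal.
* **DELTRAN** (delay): a node keeps the parental state whenever a
  most-parsimonious reconstruction allows it, so changes slide toward the
  tips and homoplasy is expressed as parallelism.

Both resolutions attain the Hartigan minimum (the suite checks this against
brute-force enumeration on all small fixtures), and the summed depth of
ACCTRAN change edges never exceeds DELTRAN's. Remaining ties — several
states equally optimal at the root or at a forced change — break toward the
smallest state code. This is an arbitrary but reproducible convention;
published counts obtained with other software may differ by a few units on
exactly tied assignments, which is why tie-sensitive quantities (root-state
counts, synapomorphy tallies) should be read with that granularity in mind.

## Indices

With m the minimum conceivable steps (distinct observed states − 1), s the
observed steps and g the star-tree maximum (non-missing leaves minus the
largest state class), per-character indices are ci = m/s, hi = 1 − ci,
ri = (g − s)/(g − m) and rc = ci·ri. ci is undefined for invariant
characters (s = 0); ri is undefined when g = m, which happens exactly for
characters whose derived states are all autapomorphic. Because such
characters are informative about the *absence* of homoplasy, the
convention r_ic assigns them ri = 1; `stage_organ_tests()` exposes an
`autapomorphies = "exclude"` switch so both treatments can be compared.

Ensemble indices pool steps before forming ratios (CI = ΣM/ΣS, etc.), so
invariant characters drop out of CI arithmetically rather than by an
exclusion rule. `average_over_trees()` repeats everything across a sample
of trees and reports means and SDs — the SD quantifies how much topological
uncertainty moves the ensemble values — and per-character index averages
for the stage/organ tests.

`permutation_null()` destroys phylogenetic signal by shuffling the
assignment of matrix rows to tips, keeping the topology and the characters
(hence m and g) fixed; only ΣS changes. The observed HI of structured data
falls below the null distribution; the reported p-value uses the add-one
Monte-Carlo correction.

## State categories and pairwise mechanisms

From the change list, every character state is the root state or a derived
state, classified by its number of independent derivations and the number
of terminal taxa showing it. A root state re-derived elsewhere on the tree
is itself homoplastic. Among once-derived states, those shared by two or
more taxa are synapomorphies and those confined to one taxon autapomorphies.
A once-derived state present at no terminal taxon (possible when later
changes overwrite it along a lineage) gets its own `transient_apomorphic`
bucket, kept out of the synapomorphy/autapomorphy tallies so those remain
comparable across resolutions.

For mechanisms, each (taxon, character) gets a derivation record: the
current state, the original state immediately preceding the lineage's most
recent change, the node bearing that change, and the node the change
departed from. Pairs of taxa with equal current states are phylogenetic
inertia (same change node: the state is identical by descent), parallelism
(independent changes from equal original states) or convergence (from
different original states). Pairs with different current states are
disparity 2 (different original states), or — with equal originals —
divergence when both lineages changed away from the same ancestral node
(sister edges leaving one point of the morphospace at the pair's most
recent common ancestor) and disparity 1 otherwise, including the common
case where one lineage never moved. This departure-node operationalisation
was a genuinely open design point: separating "same ancestral position" from
"similar ancestral position" needs identity by descent, and keying it on
the shared departure node is what makes divergence structurally impossible
under the accelerated resolution on binary trees (the sweep re-roots one of
the two changes above the shared node) while leaving a small count under
the delayed one — the asymmetry these categories are meant to capture. The
recursive origin node of the original state is still reported in the
records as a diagnostic.

Reversals are counted per lineage rather than per pair: a (taxon, ancestor)
comparison is an incidence when the ancestor carries the taxon's current
state but some node strictly between them differs. Fractions are per
character (incidences over all comparisons), and `per_char_mean` vs
`pooled` averaging is available for the mechanism proportions because the
two conventions differ slightly; pooled is the default since pooled
proportions sum to exactly 1 over all comparisons.

## Stage and organ statistics

`kruskal_wallis()` and `wilcoxon_rank_sum()` delegate to base R's
tie-corrected rank tests; the terminalia-vs-somatic comparison reports W
with terminalia as the first group. The hourglass regression fits
r_ic ~ D and r_ic ~ D + D² by least squares, with D the stage code (egg = 1
through adult = 6; a `stage_offset` argument shifts the origin for
sensitivity analyses). Fits are compared by AIC with the full Gaussian
log-likelihood as `stats::AIC()` computes it; since additive constants
cancel in differences, ΔAIC = AIC(linear) − AIC(quadratic) is the
convention-robust quantity, and the fitted extremum D* = −b/(2c) locates
the mid-developmental trough or peak.

## The coding front end

Raw numeric traits (ranges summarised by their midpoint) are clustered by
Ward's method (`ward.D2`) on Euclidean distances of the *unstandardised*
values — clustering operates on the trait's own units, and no statement
about standardisation was available to justify rescaling, so none is
applied. The number of states is a majority vote of five cluster-validity
indices — silhouette, Calinski–Harabasz, Davies–Bouldin, Dunn and the gap
statistic (Tibshirani first-SE rule) — over k = 2..k_max, with ties broken
toward fewer states (parsimony of states). The panel replaces a larger
index battery on purpose: five well-understood indices with a documented
vote are testable, and the vote's behaviour (not any single index) is what
the suite pins down. The candidate range extends to the number of
*distinct* observations, so genuinely discrete inputs (bristle counts,
three maximally different colors) can receive one state per distinct value;
cluster codes are ordered by ascending cluster mean.

Colors go through a PCA of their RGB triples; the scores on the first two
components are clustered jointly in the plane with the same vote. Joint 2-D
clustering was chosen over per-axis clustering (an open reading of the
procedure): the pigment structure is a triangle in the PC1×PC2 plane, and
axis-wise cuts cannot delimit triangular clusters. State codes order by
cluster brightness (mean R+G+B), which makes the output invariant to the
arbitrary signs of principal components. `recode_state()` applies explicit
biological overrides — splitting a statistically lumped state by a taxon
predicate, or merging states behind an explicit flag.

## The synthetic-data generator

`simulate_paperlike()` emulates the empirical study design: a 56-taxon Yule
tree and 490 characters distributed over stages as egg 12, L1 13, L2 23,
L3 26, pupa 46, adult 370 (adults spread over five body parts 78/90/40/150/12),
1–8 states per character with a mean near three, and 10% missing data.
Characters evolve as equal-rates Mk jump chains — the simplest model
consistent with unordered symmetric characters — at a stage-dependent rate:
base rate 0.1 changes per unit branch length, multiplied by an hourglass
profile (egg 1.6, L1 0.5, L2 0.35, L3 0.4, pupa 0.8, adult 1.5). The base
rate follows from an expected-steps argument rather than from fitting: a
pure-birth tree with n tips and unit speciation rate has expected total
length n − 1 ≈ 55, so a rate near 0.1 yields several true changes per
character for the fast stages — the regime in which roughly two thirds of
observed changes are homoplastic, as in the empirical matrix. Every
realised change is logged, giving a per-character truth against which
reconstructions are tested (parsimony step counts are a lower bound on
true change counts; the suite asserts this).

Two caveats define what passing tests do and do not show. First, a
one-parameter Mk rate ties morphological conservation and homoplasy
together: slow stages produce *fewer* recurrent states and hence a
*higher* r_ic, so the synthetic hourglass appears as a mid-developmental
r_ic peak, whereas constrained state spaces in real data can make conserved
stages the most homoplastic (a trough). The hourglass checks therefore
assert the signature — quadratic preferred by AIC, extremum between stages
2 and 5, significant stage effect — not the sign or magnitude of the
curvature. Second, missingness is injected completely at random by default
(a `block_missing` option mimics clade-wise inapplicability), while real
missingness is structured by anatomy; tests passing under MCAR say nothing
about informative missingness.

## Numerical and degenerate-input choices

* All ties in the parsimony sweep break toward the smallest state code;
  the root state is the smallest-code minimiser of the root cost.
* Internal nodes are restricted to each character's observed alphabet
  (never optimal to do otherwise under unit costs; keeps tie-breaking off
  unobserved states).
* A character observed in no taxon is a hard error, as is an empty NEXUS
  matrix or a taxon in the matrix missing from the tree; tree tips without
  matrix rows are pruned with a warning.
* Constant numeric traits code as a single state without a vote; a
  degenerate (all-identical) color table likewise.
* Problem sizes in the test and acceptance runs — 56 taxa × 490 characters
  for end-to-end checks, 10–24 taxa for property loops, permutation nulls
  of 200–2000 replicates against an exhaustive 120-permutation oracle —
  were chosen so each check measures what it claims on a single CPU in
  seconds; all stochastic steps take explicit seeds.

## Known limitations

Ordered or cost-weighted characters (Sankoff matrices) are out of scope, as
are likelihood or Bayesian ancestral reconstructions; the pipeline consumes
trees, it never infers them. The ACCTRAN/DELTRAN conventions are
deterministic here but not canonical across software, so tie-heavy datasets
can shift individual counts between implementations. The permutation null
shuffles all taxa exchangeably; stratified permutations (e.g. within
clades) are not provided.
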