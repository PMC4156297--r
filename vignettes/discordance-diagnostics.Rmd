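---
title: "Diagnosing gene-tree discordance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing gene-tree discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodiscord)
```

## The problem

Closely related plant species frequently show conflicting phylogenetic
signal between the nuclear ribosomal ITS region and plastid spacers. Three
processes can produce the conflict: incomplete lineage sorting (ILS) of
ancestral polymorphism, hybridization/introgression, and — specific to
multi-copy ribosomal markers — incomplete concerted evolution, which leaves
individuals carrying two divergent ribotypes whose direct sequences show
intra-individual polymorphic sites (IPS) coded with IUPAC ambiguity
symbols. An IPS whose two constituent bases both segregate as unambiguous
states in other accessions at the same position is an *additive*
polymorphic site (APS): the signature of two parental ribotypes inside one
genome. `phylodiscord` implements the complete diagnostic workflow around
these observations: IPS/APS classification and dataset splitting, Fitch
parsimony statistics and the incongruence length difference (ILD) test,
supporting-position split spectra, statistical-parsimony haplotype
networks, RELL-based topology tests, and a coalescent posterior-predictive
test that separates hybridization from ILS.

## Sequence substrate

Alignments are matrices of IUPAC-coded characters with named column
partitions and a taxon map (label, taxon, ingroup flag). Internally every
character is a 4-bit base mask; `-` and `?` are missing, `N` is treated as
a failed base call (missing for polymorphism and distance purposes, the
full state set for Fitch and likelihood computations, where it simply
contributes no information). Two characters *differ* only when their base
sets are disjoint, so R vs A matches while R vs Y differs. This rule is
deliberately conservative for the minimum-distance hybridization test: an
ambiguous base never manufactures a difference. Distances use pairwise
deletion. Coordinates are 1-based inclusive throughout, the native R and
NEXUS convention; a NEXUS `charset 1-230` is stored as `c(1, 230)` and
covers 230 columns.

## Polymorphism and additivity

A column is polymorphic for a scope of accessions when at least one scoped
sequence carries a 2- or 3-base ambiguity code. The code at (column,
sequence) is additive when **every** constituent base occurs as an
unambiguous state in at least one *other* scoped accession at the **same
column** — the only reading of additivity that is testable from an
alignment, since the two parental variants must be observable separately.
Another accession's ambiguity code does not count as an observation.
Scope defaults to the ingroup. `split_by_aps()` then separates APS-free
from APS-bearing sequences, mirroring the standard practice of analysing
homogenised ribosomal sequences separately.

## Parsimony statistics

Fitch small parsimony treats IUPAC codes as state sets and missing data as
the full set; scoring is delegated to `phangorn::fitch`, and heuristic
searches combine random-addition starting trees with SPR (unconstrained,
via `phangorn::optim.parsimony`) or NNI hill-climbing (constrained
searches, where each rearrangement is filtered against the required
clades). TBR is approximated by SPR plus random restarts; on the data
sizes this package targets the restarts recover the same optima, which the
test suite verifies against exhaustive enumeration up to 7 taxa. Per-site
minimum steps are computed exactly by searching the 15 nonempty subsets of
\{A,C,G,T\} for the smallest set intersecting every leaf's state set; the
per-site maximum is the star-tree bound (effective leaves minus the
largest single-state frequency). CI and RI sum these over variable sites.
Sites that cannot express homoplasy (maximum equals minimum) contribute
zero to both RI sums, and constant sites only to tree length. Variable and
informative site counts use unambiguous states only by default — the
common convention — with a flag (`count_ambiguous`) that treats a column as
variable when no single base is compatible with all non-missing characters.

The ILD (partition homogeneity) test permutes column assignments between
the two partitions, keeping their sizes, and uses the add-one p-value
convention. For seven or fewer taxa partition lengths are *exact*: Fitch
length is additive over columns, so one per-topology, per-site step matrix
turns every permutation replicate into a row-sum minimum.

## Supporting-position spectra

For a functional ingroup/outgroup bipartition each column is symmetric
(two states, each side fixed for a different one), asymmetric (one side
fixed for a state the other side lacks while showing two or more states),
or noisy (a side's fixed state recurs in the other side). Ambiguity codes
and missing data are excluded from the fixation tallies, and a side counts
as fixed only when at least one character is resolved. A constant column
is noisy by this definition and is counted once. Headline "supporting
position" counts are symmetric + asymmetric for the named side; noisy
positions are reported but excluded, since they represent convergence or
chance similarity rather than support. All three categories are always in
the output so either convention can be read off.

## Haplotype networks

Sequences are collapsed to haplotypes (exact or missing-compatible
identity) and connected by an agglomerative statistical-parsimony
construction: at step length *j* = 1, 2, ..., limit, every pair of
haplotypes in different components at mutational distance *j* is joined by
a path with *j* − 1 inferred (unsampled) intermediates; all equal-length
alternative connections arising at the same *j* are retained, which is
what produces reticulations. The probability-of-parsimony (95%) criterion
for choosing the limit is not implemented — the limit is an explicit
parameter (30 steps is the conventional fixed choice). Gaps are missing in
haplotype distances by default; a fifth-state option exists because
published analyses differ on this point.

## Likelihood machinery and topology tests

Per-site log-likelihoods come from Felsenstein pruning (`phangorn::pml`)
under JC69, K80, HKY85, SYM, TVM or GTR, with 4 discrete mean-category
gamma rates and an invariant-sites mixture when requested; base
frequencies are equal for JC/K80/SYM and empirical otherwise. Branch
lengths for a fixed topology are optimized coordinate-wise
(`optim.pml(optEdge = TRUE)`); the two-taxon case is optimized directly as
a single path length. Candidate topologies for testing come from
constrained parsimony searches, the pragmatic stand-in for a constrained
ML search: what the RELL tests consume is only the per-site
log-likelihoods of each candidate after branch-length optimization.

RELL resampling draws site columns with replacement without
re-optimization. The weighted KH test standardizes the pairwise
log-likelihood difference with its bootstrap standard deviation and takes
a two-sided p-value against the best tree from the centred replicates; the
weighted SH test uses each tree's maximum standardized difference with a
centred null. Zero-variance comparisons (identical trees) return p = 1
with a warning. The AU test is not implemented (it requires the
multiscale bootstrap).

## The multispecies coalescent simulator and the hybridization test

A `species_tree_sample` is a rooted ultrametric tree in
substitutions/site with one population parameter theta per branch
(including the root stem, which extends indefinitely). Theta is the mean
pairwise coalescence time for a locus with heredity scalar *h* = 1, the
convention of `dmv`-annotated posterior files: *k* lineages in a branch
coalesce at total rate *k*(*k* − 1) / (2 theta h), so a pair waits theta·h
on average and the TMRCA of *n* lineages in one population approaches
2·theta·h·(1 − 1/*n*). Gene trees are simulated branch by branch from the
tips up; hybridization pulses are modelled as lineage reassignment — each
lineage present in the recipient species at the event time moves to the
donor with probability gamma — the simplest gene-flow mechanism the
posterior-predictive distance test is sensitive to (a full network model
is out of scope). Sequences evolve along the gene tree via
`phangorn::simSeq` with the locus model, per-site gamma/invariant rates
and the locus-relative rate multiplier.

The hybridization test simulates one dataset per retained posterior tree
(after burn-in and thinning), records every species pair's minimum
inter-species p-distance, and reports the plain proportion of simulated
minima at or below the observed minimum — no add-one correction, matching
the convention of posterior-predictive distance tests whose published
p-values are exact multiples of 1/n_sim. Pairs with p < 0.05 are flagged.
Because ILS is part of the null model, small distances flag gene flow
specifically.

Two statistical properties are exercised by the test suite. *Calibration*:
under no-migration truth with the true tree as posterior, about 5% of
pairs are flagged; the band used (0.02–0.08 over 200 replicate studies) is
wide because pairs within a study share simulations and the minimum
distance is discrete, which makes the plain-proportion p slightly
conservative when ties occur. *Power*: the benchmark scenario uses two
species whose divergence (0.02 substitutions/site) is twenty times theta
(0.001), a pulse at 0.0002 with gamma = 0.5 and three sampled lineages in
the recipient — the regime where the null predicts clearly nonzero
minimum distances. Two design points matter: the pulse must postdate most
within-recipient coalescence (a pulse older than about theta reaches a
single surviving lineage and halves the detection ceiling), and the
ceiling itself is the probability that at least one recipient lineage
moves (about 0.8 here); the flagged fraction in the suite is required to
exceed 50%. In regimes where species divergence is within a few multiples
of theta, null and introgressed distance distributions overlap and no
test based on minimum distances can have high power.

## The synthetic-data generator

`generate_scenario()` produces a full study with known truth: a pure-birth
ingroup species tree rescaled to a crown height of 0.012
substitutions/site (ITS-scale divergence among close congeners), a
divergent outgroup attached 0.08 above the crown, per-branch theta drawn
uniformly from 0.002–0.006, uneven sampling of 1–8 individuals per species
(a scaled-down version of the heavily uneven sampling real studies have),
and two loci mirroring the canonical marker pair: a 653-site nuclear
SYM+G locus with relative rate 1.016 and heredity scalar 2, sampled as
*two* gene lineages per individual, and a 960-site plastid TVM+I+G locus
with relative rate 0.385 and heredity scalar 1, sampled haploid. The two
nuclear alleles of each individual are merged into one observed sequence
by `apply_ribotype_mixing()`: each differing site is homogenized to one
parent with probability *c* (default 0.5) or written as the IUPAC code
otherwise. The truth bundle records which individuals are mixed (with
their parental ribotypes) and which lineages were moved by hybridization
pulses, so every pipeline stage can be validated against truth.

What the generator does *not* emulate: indels (alignments are gapless; gap
handling is tested on hand-built fixtures), sequencing error, PCR
recombination, rate variation among lineages, and intra-locus
recombination. Passing tests therefore demonstrate correctness of the
algorithms under the multispecies coalescent with pulse gene flow and
site-independent substitution — not robustness to alignment error or
recombination in real data.

## Numerical and design choices

* Exhaustive parsimony search is used automatically for ≤ 7 taxa (at most
  945 unrooted topologies); heuristic searches use seeded random
  restarts and retain all equally parsimonious topologies.
* Branch-length optimization iterates to a relative log-likelihood change
  below 1e-8 (tests verify the 2-taxon analytic optima to 1e-6).
* Ties in stepwise addition and hill climbing are broken uniformly at
  random under the caller's seed; haplotype-network node ids are assigned
  deterministically in input order.
* The pipeline derives one RNG stream per stage from the master seed and
  the stage name, so enabling or disabling a stage never changes another
  stage's output.
* Problem sizes in the test suite (6–8 taxa, 100–650 sites, tens to a few
  hundred replicates) were chosen so the whole suite exercises every
  statistical property at useful resolution while remaining quick to run;
  the same properties hold at larger sizes.
* ILD null calibration is checked in the saturated regime (branch lengths
  1.2 substitutions/site) where the statistic takes many values. Because
  the incongruence length difference is integer-valued, ties make the
  add-one permutation p-value conservative (super-uniform) rather than
  exactly uniform; the suite therefore checks uniformity of the mid-p
  (half weight on ties, computed from the returned replicate statistics)
  and separately that the reported p is never anticonservative at the 5%
  level. At ITS-scale divergence the statistic is a small integer and the
  conservativeness is pronounced — a property of the convention, worth
  remembering when interpreting large ILD p-values.

## Known limitations

Exact reproduction of search-dependent published numbers (tree lengths,
CI) depends on PAUP*'s tie-breaking and counting conventions; the
`validate_against_supplementary()` table recomputes them when the original
alignment files are supplied. Constrained topologies are found under
parsimony, not constrained ML, so likelihood differences for constrained
tests are upper bounds on the ML-search values. The TCS probability
criterion, nested clade analysis, root-probability weights, neighbour-net
diagrams and the AU test are intentionally absent.
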