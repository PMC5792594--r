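---
title: "Methods: clade-specific subfamily mining and candidate prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade-specific subfamily mining and candidate prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccminer)
```

# The problem

Plant specialized metabolism is rich in enzyme superfamilies — cytochrome
P450 monooxygenases foremost among them — whose members number in the
hundreds per genome. When a biosynthetic step (here, flavone
6-hydroxylation en route to scutellarin) is known to be catalyzed by some
member of such a superfamily, and the metabolic phenotype is restricted to
one plant clade, candidates can be narrowed drastically by asking which
subfamilies exist *only* in that clade, and then ranking the survivors by
expression in the producing tissue. `ccminer` implements that chain of
reasoning as a tested pipeline, together with the enzyme-kinetics and
fermentation-yield arithmetic used to characterize the enzymes that come
out of it.

The pipeline has four stages:

1. **mine** — find superfamily members in each proteome by profile scoring,
   keeping hits with E-value below `1e-10` whose whole-protein length lies
   strictly between 350 and 650 residues;
2. **cluster** — compute all-pairs global-alignment identities, build a
   neighbor-joining tree from `1 - identity`, and cut it into subfamilies:
   maximal monophyletic clades in which *every* pair of members exceeds 55%
   identity;
3. **specificity** — call a subfamily clade-specific when its members occur
   only in the declared ingroup species;
4. **rank** — shortlist genes of clade-specific subfamilies by mean
   expression (default shortlist size 36).

# Synthetic data: what it emulates, and what it does not

Because the original multi-genome inputs are not redistributable at desk
scale, the package ships a generator whose defaults *are* the study
conditions: a 13-species panel (a monophyletic 5-species ingroup against 8
outgroup species on a fixed guide tree with branch lengths in
substitutions/site), planted gene families with controlled identity
structure, an expression table with 5 "wild" and 6 "cultivated" samples,
and Michaelis–Menten rate data at the characterized enzyme parameters.

Each family descends from a random ancestral domain sequence of 400
residues (inside the 350–650 length screen). A fixed 15% of positions are
**anchor columns** that are never mutated — the stand-in for the invariant
catalytic and fold-defining residues that make a superfamily recognizable
to a profile model in real data. Subfamily seeds are derived from the
ancestor by re-mutating free positions, and members are evolved from each
seed along the guide tree with per-branch substitution counts
`round(rate × branch length × sequence length)`. Two bisections set the
knobs:

* the **between-subfamily** mutation count is the smallest count whose
  predicted seed-to-seed identity sits at least 3σ below the between-target
  (default 0.30);
* the **within-subfamily** rate is the largest rate whose predicted
  worst-pair identity sits at least 3σ above the within-target (default
  0.90), using the deepest tip-to-tip path of the guide tree.

Prediction uses the exact collision arithmetic of uniform replacement over
20 residues (a mutation can restore the original residue with probability
1/20). After generation, realized identities are *verified* against the
brute-force alignment oracle on every bundle of at most 200 genes, and
generation stops with an error rather than silently missing a target. The
anchor fraction floors attainable between-subfamily identity at roughly
`0.15 + 0.85/20 ≈ 0.19`; between-targets below that floor are rejected
loudly. All family specifications in one bundle must share the domain
length, since a single profile model scans one superfamily.

Deliberate simplifications: no indels inside the domain (keeping identity
arithmetic exact), no codon or rate-heterogeneity model, i.i.d.
uniform-residue decoys rather than real non-homologous proteins, and
expression values that are unit-agnostic log-normals rather than processed
RNA-seq counts. Passing tests therefore demonstrate the *logic* of the
pipeline — recovery of planted structure under controlled divergence — not
robustness to alignment ambiguity, domain architecture variation, or
normalization artifacts in real proteomes and expression data.

Decoy lengths are drawn uniformly from 200–800 so that some decoys pass
the length screen and must be rejected on significance alone, while others
test the length filter itself.

# Profile search and empirical E-values

The scanner scores ungapped placements of a log-odds profile
(`log2((count + 1)/(n + 20) / background)`, gap-majority columns dropped)
along each protein and keeps the best window. A full profile-HMM with
insert/delete states would be the tool of choice for real Pfam domains —
the `read_domtbl()` importer is the escape hatch for exactly that — but for
the indel-free synthetic domain, ungapped scoring is lossless and keeps the
null calibration clean.

Significance is calibrated per sequence by residue shuffling (default 200
shuffles, seeded): shuffling preserves length and composition, which are
the two covariates the best-window score is most sensitive to. A pure
rank-based empirical E-value cannot resolve below `1/n_shuffles`, far above
the `1e-10` acceptance threshold, so the package fits an extreme-value
(Gumbel) distribution to the shuffled best-window scores by moments — the
asymptotic law for maxima of ungapped local scores — and reports its upper
tail, scaled by the number of sequences searched. Inside the null support
this agrees with the empirical rank within Monte-Carlo error; beyond it,
the tail extrapolates smoothly, so a genuine domain can reach E-values many
orders of magnitude below the threshold while the best decoy stays near
E ≈ 1. E-values are continuous and strictly decreasing in score for a
fixed null. Both length-filter bounds and the E-value threshold are strict
inequalities.

# Identity, trees, and the subfamily cut

Pairwise identity is computed from a Needleman–Wunsch global alignment
with free terminal gaps (BLOSUM62, gap open 10, gap extend 1): identical
aligned pairs divided by alignment columns, excluding terminal-gap columns
and counting internal gaps. This "coverage-robust" definition tolerates
length differences without rewarding them. Because co-optimal alignments
can differ between argument orders, the implementation fixes a canonical
order internally, making identity exactly symmetric. Scoring parameters
are fixed and recorded.

`neighbor_joining()` is a from-scratch Saitou–Nei implementation. Negative
branch-length estimates are clamped to zero with the deficit transferred
to the sibling edge, preserving their sum — so on additive matrices the
tree reproduces the input path lengths exactly (tested to 1e-9 over random
6–10 leaf trees). Ties in the Q-matrix are broken by column-major order,
making the construction deterministic.

The subfamily criterion — "phylogenetically close *and* all pairs above
55% identity" — is operationalized as the **maximal monophyletic clades**
of the all-member NJ tree in which every leaf pair has identity strictly
above `tau = 0.55`. The NJ tree is unrooted; it is midpoint-rooted before
the root-to-tip traversal. With tightly clustered subfamilies the longest
path runs between, not within, subfamilies, so midpoint rooting cannot
split one. The traversal accepts the first passing clade and recurses
otherwise; a leaf that fails with all neighbors becomes a singleton. The
output is always a partition. This all-pairs (complete-linkage-like)
reading is the strictest one consistent with the stated criteria; an
average-linkage reading would merge more aggressively and is not
implemented.

Recovery of planted subfamilies is exact (adjusted Rand index 1.0)
whenever the within-identity target exceeds `tau + 0.05` and the
between-identity target falls below `tau - 0.05` — the margins under which
the acceptance suite tests it.

# Species tree and orthology

One-to-one orthologs are reciprocal best hits by global-alignment score;
groups are connected components of the RBH graph that contain exactly one
gene per species across all species, and equal-score ties deliberately
poison their component (a duplicated gene is not one-to-one). The species
tree is NJ on mean `1 - identity` across ortholog groups, with support
from resampling *genes* (ortholog groups) with replacement, 100
replicates by default — site-level bootstrapping would require a
concatenated alignment, which the distance-averaging construction never
forms. Supports are percentages of replicates containing each internal
bipartition.

# Specificity calls and class counts

A subfamily is clade-specific iff its species multiset is a subset of the
ingroup. No minimum ingroup breadth is required by default — a subfamily
private to a single ingroup species is still specific under the
set-inclusion definition — but `min_ingroup_species` exposes the stricter
alternative. Every summary carries the caveat that specificity is relative
to the sampled outgroup: with only eight outgroup genomes, some "specific"
subfamilies may simply be unsampled elsewhere. Class counts are reported
for a focal species and their conservation (specific + shared genes =
focal superfamily size) is asserted, the same arithmetic that makes
178 shared + 134 specific genes sum to a 312-member superfamily.

# Expression comparison and ranking

Group means are plain arithmetic means over the wild, cultivated, and all
columns. The specific-vs-shared comparison is a two-sided Wilcoxon
rank-sum test on `log2(mean + 1)` (pseudocount 1.0 because zeros are
legitimate expression values): exact enumeration when both classes hold at
most 20 genes, normal approximation with tie correction otherwise — the
behavior of `stats::wilcox.test`, which is used directly. Its type-I error
is verified by simulation to sit in [0.03, 0.07] at α = 0.05.

"Highly expressed" has no published threshold, only a shortlist size, so
ranking takes the top `k` (default 36) clade-specific genes by raw mean
over all samples, ties broken lexicographically by gene id. The log
transform is monotone, so testing on log scale and ranking on raw scale
order genes identically.

# Kinetics and yield arithmetic

`fit_michaelis_menten()` fits `v = Vmax·S/(Km + S)` by Levenberg–Marquardt
least squares, initialized from a Lineweaver–Burk double-reciprocal
regression (with a safe fallback when the linearization misbehaves) and
restarted from perturbed starts on failure; standard errors come from the
Jacobian at the optimum. Units are fixed — concentrations in µM, rates in
µM s⁻¹, enzyme in µM — making `kcat = Vmax/E0` dimensionally s⁻¹. On
noise-free data spanning `[Km/10, 10·Km]` recovery is exact to optimizer
tolerance; at 5% multiplicative noise with a triplicate 8-point design the
median relative Km error stays below 10%. A Km estimate pinned at a bound
raises a warning flag rather than an error.

`yield_metrics()` is deliberately plain arithmetic over reported
quantities: component titers sum to the total (also reported at
nearest-hundred precision, e.g. 108 + 185 = 293 ≈ 300 mg l⁻¹), specific
yield is titer/DCW, the fold change is displayed rounded half-up to two
decimals (15.5/9.2 → 1.68) with the raw ratio retained, and the
intracellular fraction is the complement of the extracellular percentage.
Molar conversions require a caller-supplied molecular weight; no compound
table is hard-coded.

# Numerical and design choices

* Branch lengths are serialized to Newick with 17 significant digits, so
  tree round-trips are bit-exact; fixture numerics are written the same
  way.
* Coordinates are 0-based half-open internally and 1-based inclusive only
  at file boundaries (the domtbl importer converts).
* The pipeline is a pure function of (config, seeds); report JSON is
  byte-identical across reruns, which the acceptance suite asserts.
* Expression units are unspecified in the source material; the generator
  and all downstream statistics are unit-agnostic (means, ranks, and a
  rank test are invariant to a global rescaling).
* Whether the published subfamily count used average- or complete-linkage
  identity, and whether the species tree used concatenation, are unstated;
  the all-pairs cut and gene-distance averaging implemented here are
  recorded as this package's choices, not inferred intent.

## Problem sizes used in the shipped analyses

The default synthetic study uses 13 species, six families × two
subfamilies (108 members), 20 decoys, and 11 expression samples; the test
suite additionally exercises a 50-family single-copy bundle for the
species tree, 500-replicate simulations for the rank-sum calibration and
the noisy-kinetics regression guard, and 100 random trees for the NJ
inversion property. These sizes give each statistical check comfortable
resolution while keeping a full run of the suite around a minute on a
single core.

# Known limitations

* Ungapped profile scoring cannot model domains with indel-rich seed
  alignments; import real hmmsearch results via `read_domtbl()` instead.
* RBH orthology is quadratic in proteome size and intended for the
  focused, superfamily-scale inputs used here, not whole-proteome
  orthology inference.
* Clade-specificity is an absence claim and inherits the sampling caveat
  of the outgroup panel.
* The NJ subfamily tree is a distance method; very heterogeneous rates
  across subfamilies could in principle break monophyly of a true
  subfamily before the identity test ever sees it.
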