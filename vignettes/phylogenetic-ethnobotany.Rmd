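---
title: "Methods: clumping tests and hot-node detection for medicinal-use communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clumping tests and hot-node detection for medicinal-use communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`ethnophylo` transplants the machinery of community phylogenetics into
ethnobotany. A "community" here is not a geographic assemblage but the set
of taxa reported for one medicinal-use category (or one named condition,
such as malaria). Given a rooted phylogeny with branch lengths over a pool
of *N* tips and a community of *n* of them, the package asks whether the
community members are more closely related than a random set of *n* tips,
and if so, where on the tree the excess relatedness sits.

Two distance statistics are computed from the patristic matrix
(`patristic_matrix()`, the sum of branch lengths along the path between
each pair of tips):

* **MPD** — the mean of the *n(n−1)/2* pairwise distances among community
  members. Clumping at deep nodes (two related subclades both rich in
  users) pulls MPD down.
* **MNTD** — the mean, over members, of the distance to the nearest other
  member. Clumping near the tips (clusters of sister species sharing a
  use) pulls MNTD down, even when the clusters are scattered across the
  tree. MNTD ≤ MPD always, since a minimum cannot exceed a mean.

For bioprospecting, tip-level clumping is the actionable signal — a deep
clumped node spans too many species to prioritize — which is why the two
metrics are always reported side by side.

### Null model and p-values

The null draws *n* distinct tips uniformly from the full tip pool
(`model = "pool_draw"`). For presence/absence data this is equivalent to
shuffling tip labels on the tree, and a `"label_shuffle"` variant is
provided for completeness; the uniform-draw formulation is the default
because it is the natural reading of "random samples of the same size" and
it makes the node test's null exactly hypergeometric (below). The number of
randomizations defaults to R = 999, the Phylocom convention.

Each sample is summarized by a standardized effect size per metric,

    SES = (mean_null − observed) / sd_null,

the NRI/NTI sign convention (positive = clumped; SES is defined as 0 when
`sd_null = 0`, which happens only in the degenerate case n = N), and by a
one-tailed clumping p-value with the add-one estimator

    p = (k + 1) / (R + 1),

where *k* counts null values **at or below** the observed. Ties count
toward clumping, the estimator never returns 0, and when `alpha (R + 1)` is
an integer the test is exactly valid (at R = 999 and alpha = 0.05,
rejection probability under the null is exactly 0.05). Because the draws
only compare distances, multiplying all branch lengths by a constant leaves
SES and p unchanged — only relative branch lengths matter.

`exact_signal_p()` replaces the Monte-Carlo tail with full enumeration of
all `choose(N, n)` subsets (capped at 1e6) and is the oracle the test suite
uses to verify the permutation machinery.

No multiple-testing correction is applied across samples by default —
reports of this kind conventionally print raw per-category p-values — but
`signal_test(p_adjust = "BH")` adds Benjamini–Hochberg columns. Only the
clumping tail is tested by default; overdispersion is visible as negative
SES.

### The node-enrichment ("nodesig") scan

For every internal node *v* with *D* descendant tips (2 ≤ D ≤ N − 1; the
root is excluded since it always contains the entire community and flagging
it would be vacuous), the observed member count *x* among its descendants
is compared to the null. Under uniform draws, *X* is exactly
Hypergeometric(*N*, *D*, *n*), so two modes are offered:

* `mode = "exact"` — `p_more = P(X ≥ x)` from `phyper`; a node is flagged
  `MORE` at `p_more ≤ 0.025`.
* `mode = "permutation"` — the conventional randomization: a node is
  flagged when its observed count **strictly** exceeds the null count in at
  least 97.5% of runs (the 975/1000 convention of Phylocom's nodesig,
  reproduced as the default so that results are comparable with the large
  body of analyses produced by that tool); the reported
  `p_more = (#{X_null ≥ x} + 1)/(R + 1)` converges to the hypergeometric
  tail as R grows.

Both cutoffs are overridable through `flag_threshold`, and raw `p_more` is
always printed so a reader can apply a different threshold.
Underabundance (`LESS`) is computed symmetrically but never highlighted:
the question the scan answers is where use concentrates. Flagged nodes are
named `MRCA(x,y)` with *x*, *y* the first and last descendant tips in the
tree's stored tip order — a deterministic convention for a fixed input
tree — and written into the Newick output as quoted node labels
`'MORE:<sample>|<sample>'` (sorted, so output is reproducible).

Nested nodes are flagged independently (a fully used cherry inside a fully
used larger clade both appear); interpreting the nesting is left to the
reader, as is conventional for this scan.

## Data model and matching

Communities can be built three ways: from long-form use records
(taxon/region/category/condition/source, with categories canonicalized
against the 13-category vocabulary — Circulatory/Blood, Gastro-intestinal,
Genito-urinary/Fertility, Infections/Fever, Inflammation, Musculo-Skeletal,
Nervous, Pain, Poisons treatment, Respiratory, Sensory, Skin, Unspecific —
plus an editable synonym table); from a wide taxon-by-sample 0/1 matrix; or
from a Phylocom-style 3-column sample file. Abundances are deliberately
collapsed to presence: the analysis scores use versus non-use. An overall
sample (the union of all medicinal taxa) is always appended, since "is
medicinal use as such clumped?" is a different question from any single
category.

Taxon names match tree tips exactly after whitespace normalization. Trees
whose tips are sequencing accessions rather than species (several
accessions per species, e.g. `P.angolensis1`, `P.angolensis2`) are handled
by an optional species-to-tip mapping that propagates a species' uses to
**all** of its accession tips; this is the default reading because a use
recorded for a species is evidence about every sampled individual of it.
Whether to instead score at accession level is left to the caller by
supplying a one-to-one mapping. Unmatched taxa are an error unless
`prune_unmatched = TRUE` downgrades them to a logged warning, and outgroup
tips can be dropped before analysis with `run_config(prune = ...)`; since
published analyses do not always state whether outgroups were pruned before
community tests, both modes exist and the output's provenance header
records the choice.

## The synthetic generator

`simulate_yule_tree()` grows a pure-birth tree: with *k* extant lineages
the waiting time to the next speciation is Exp(*k*λ), a uniformly chosen
lineage splits, and growth stops when *N* lineages exist; one further
Exp(*N*λ) waiting time is appended so pendant branches are positive. The
tree is ultrametric by construction. Pure birth (no extinction) was chosen
over birth–death because the clumping tests are scale-invariant and
insensitive to the mild branch-length differences extinction introduces,
and because it has no extra parameter to justify; λ defaults to 1
accordingly.

`simulate_community()` plants known signal: `ceiling(f · n)` members are
drawn uniformly inside one focal clade and the rest uniformly outside it.
The focal clade is chosen uniformly among internal nodes whose descendant
count lies in `[ceiling(f·n), N − (n − ceiling(f·n))]`, which guarantees
both draws are feasible; the ceiling rounding guarantees at least the
requested clumped fraction. At f = 0 the community is a uniform draw and
the null hypothesis is true by construction; at f = 1 it is fully
clade-restricted.

`calibration_experiment()` repeats (new tree, new community, signal test)
and reports rejection rates with exact binomial confidence intervals — the
size of the test at f = 0, its power at f > 0.

What the generator emulates is the *statistical* structure the analysis
assumes: presence communities on an ultrametric tree, from random to fully
clade-restricted. What it does not emulate: non-ultrametric ML trees with
zero-length branches and polytomies (the analysis code accepts these —
zero-length branches produce a warning about possible MNTD ties,
polytomies are preserved — but the calibration does not exercise them);
multiple overlapping categories with correlated membership; errors in the
use records themselves. Passing calibrations therefore certify the
statistics under clean conditions, not robustness to messy data.

Because the focal clade is drawn uniformly among all eligible clade sizes,
f = 1 plants a mixture of shallow and deep signal; in that regime MPD power
can match or exceed MNTD power (both are reported). Pure tip-level signal —
many small clusters — is the regime where MNTD specifically dominates, and
the calibration grid does not isolate it.

## Numerical and reproducibility choices

* Distances come from `ape::cophenetic.phylo` (one tree traversal, no
  per-pair walks); the suite checks them against an independent
  path-enumeration oracle.
* Tie handling is conservative everywhere: null values equal to the
  observed count as "at least as clumped" in the signal test; the
  permutation node flag requires strictly exceeding the null.
* Missing branch lengths are an error by default; `unit_lengths = TRUE`
  substitutes 1 for every branch and is documented as changing all
  distances. Negative lengths are always an error; zero lengths are
  allowed with a warning.
* One base seed governs an invocation; each sample (and each calibration
  replicate) derives a 31-bit substream seed from a hash of its name, so
  adding or reordering samples does not perturb the others' results, and
  all outputs are byte-identical across runs for a fixed seed.
* Exact enumeration and permutation tails agree within Monte-Carlo error by
  construction; the test suite pins this at R = 20,000 within three
  Monte-Carlo standard errors (plus the 1/(R+1) estimator offset).

## Problem sizes used in the checks

The shipped calibrations use 100-tip trees, communities of n = 10, 500
replicates per clumping fraction, and R = 199 randomizations per replicate
(alpha·(R+1) integral, so the f = 0 rejection probability is exactly the
nominal 0.05); oracle-agreement checks run at R = 20,000 on 5–12-tip
trees. These sizes were chosen to put the binomial noise on a 500-replicate
rate (±2.5 percentage points at 99% confidence) well below the effects
being measured while keeping the full suite comfortably fast on one CPU.

## Limitations

* Presence-only: informant-consensus or cultural-importance weighting is
  out of scope, as are abundance-weighted MPD/MNTD and trait-model
  statistics (Blomberg's K, Pagel's λ).
* The node scan counts tips only; branch lengths play no role in it, so a
  long-isolated single user never flags.
* Per-node p-values across one tree are strongly dependent (nested nodes
  share descendants); the optional BH adjustment treats them as a flat
  family and should be read accordingly.
* The hypergeometric identity between the two node-test modes holds for
  the uniform-draw null; under other nulls only the permutation mode is
  exact.
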