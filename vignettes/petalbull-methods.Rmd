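---
title: "Methods: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalbull)
```

`petalbull` chains two kinds of machinery: a phylogenomic track that turns
per-taxon transcript sets into a species tree with coalescent-unit branch
lengths, and a quantitative-genetics / phenotype track for the downstream
statistics of a bullseye-patterning study. This vignette records the models
behind each step, the tunable parameters with their units and defaults, the
numerical conventions, and what the synthetic-data generators do and do not
emulate.

## Homology: similarity graph and Markov clustering

Transcript redundancy is reduced greedily: records are sorted by decreasing
length and each joins the first representative whose *containment identity*
(best gapless placement of the shorter inside the longer, matches divided by
the shorter length) reaches the threshold (default 0.99). Containment
identity mirrors what greedy dedup tools do at high thresholds without
implementing banded alignment; the operation is idempotent.

Similarity between representatives is the number of **distinct shared
k-mers** (default k = 21, single strand, no reverse-complement matching).
A k-mer score is not a local-alignment E-value, but it is monotone in
sequence similarity and dependency-free, which is all the clustering stage
needs. Pairs scoring below `min_score` (default 1) get no edge.

`mcl()` implements Markov clustering exactly as published: column-stochastic
matrix from edge weights, then alternating expansion (matrix squaring) and
inflation (elementwise power, default 1.4, then column renormalisation)
until the largest entry change falls below `tol = 1e-6`, with entries below
`1e-9` pruned each iteration and a 200-iteration cap (non-convergence
returns the partial result with a warning). Self-loops with weight equal to
each node's maximum incident edge weight are added before normalisation — a
standard stabilisation. Clusters are read off the limit matrix: attractors
are rows with positive diagonal; every node joins its largest-probability
attractor (ties broken by lexicographic node id) and attractors sharing
column support merge. Disconnected components can never merge, whatever the
inflation.

## Tree cleaning

All cleaning operators act on `ape::phylo` trees whose tips are labelled
`taxon@identifier` (`@` is reserved as the separator) with branch lengths in
expected substitutions/site.

* `clean_columns()` keeps exactly the alignment columns whose fraction of
  unambiguous bases (A/C/G/T) is **at least** `min_occupancy` (default 0.1).
  The boundary is closed: a column at exactly the threshold stays.
* `trim_long_tips()` removes pendant branches longer than `abs_cutoff`
  (default 0.4 subs/site). A second, *relative* rule removes tips longer
  than `rel_cutoff` (default 0.6) that also exceed 10× the shortest pendant
  branch among the sister clade's tips. How a "relative branch length"
  should be normalised is genuinely open; comparing to the sister clade's
  shortest pendant is the common practice in tree-based homology cleaning
  and the factor is configurable. Note that with the default cutoffs the
  absolute rule dominates (anything over 0.6 is already over 0.4); the
  relative rule matters when the absolute cutoff is raised. Removals are
  decided on the input tree and applied together; unary nodes are collapsed
  with lengths summed, so path lengths between survivors are conserved.
* `mask_monophyletic_duplicates()` reduces every maximal monophyletic group
  of same-taxon tips to the tip with the most informative characters
  (unambiguous bases in its alignment row), iterated to a fixed point; ties
  break lexicographically.
* `cut_deep_paralogs()` cuts every internal branch at least `deep_cutoff`
  (default 1.0 subs/site) long — the signature of an ancient duplication —
  and keeps fragments with at least `min_subclade_taxa` (default 4)
  *distinct taxa* (taxa, not tips); smaller fragments are reported
  discarded. If no branch qualifies the input is returned untouched.

Distance trees for cleaned alignments come from `jc_distance()` (the
Jukes–Cantor transform `d = −¾ ln(1 − 4p/3)` on the mismatch fraction `p`
over sites where both rows are unambiguous; saturated pairs with `p ≥ 0.75`
are set to a configurable ceiling, default 5, and flagged) followed by
`neighbor_joining()` (classic NJ via `ape::nj`; negative estimated branch
lengths are clamped to zero and counted). NJ is a deliberate, documented
stand-in for maximum-likelihood inference: it keeps the pipeline
self-contained, and the cleaning and orthology operators only consume
topology and branch lengths.

## Maximum-Inclusion orthology

`maximum_inclusion()` iterates: among all rooted subtrees of the working
tree (each branch defines two, plus the whole tree) that contain **no
repeated taxon**, take the one covering the most distinct taxa; if it has at
least `min_taxa` (default 4) taxa, emit it and delete its tips (collapsing
unary nodes); repeat. Ties break by smaller total branch length, then by
lexicographically smallest tip label — determinism over substance, since
duplication-free subtrees that tie are genuinely interchangeable to a
tree-only method. Trimming is applied once up front by default
(`retrim = TRUE` re-applies it between iterations). The extraction's
precondition is a *cleaned* tree: un-masked in-paralog cherries block every
duplication-free bipartition, so run `mask_monophyletic_duplicates()` first,
as the pipeline order (trim → mask → cut → extract) does.

## Quartet species tree in coalescent units

For small taxon sets the maximum-quartet-support species tree is solved
*exactly*: all `(2n−5)!!` unrooted topologies (enumerated via
`phangorn::allTrees`, guarded at `max_n = 9`) are scored by the number of
gene-tree-induced quartets they agree with, counting each 4-taxon subset
only in gene trees that contain and resolve it (polytomies are skipped, not
split fractionally).

Per-branch support `q` is the frequency of the agreeing resolution among the
quartets that take one tip from each of the branch's **four neighbouring
subtrees**. This restriction matters: for those quartets the internal path
is exactly the branch in question, so under the multispecies coalescent
`E[q] = 1 − ⅔ e^{−d}` inverts to a single branch length
`d = −ln(3(1−q)/2)` in coalescent units, rather than to a path sum.
Perfectly supported branches (`q = 1`) are capped at 9 coalescent units and
flagged; `q` below the random-resolution floor of 1/3 carries no signal and
is reported with length 0. Support is reported as `q` itself; local
posterior probabilities are out of scope.

The package ships a minimal MSC simulator (`sim_msc_gene_trees()`): one
haploid lineage per species, coalescence at rate 1 per pair per coalescent
unit within each species branch, free coalescence above the root; the
species tree must be rooted and ultrametric. It exists to make recovery
claims testable, not to replace a full coalescent simulator.

## Expression statistics

`size_factors()` is the median-of-ratios normalisation (per-sample median of
count/geometric-mean over genes positive everywhere). `de_test()` is a
deliberately transparent stand-in for negative-binomial DE machinery: log2
fold change from normalised group means with a pseudocount (default 1), and
Welch's t on `log2(normalised + 1)`. `de_filter()` applies the study-style
rule: differentially expressed means `|log2FC| ≥ 2` **and** BH-adjusted
p < 10⁻⁵. The printed form of that fold-change rule is internally
inconsistent ("≤ 2 or > 2"); it is implemented as the fourfold cutoff
`|log2FC| ≥ 2`, which matches the way such filters are described elsewhere
in the same analysis. The filter also accepts externally produced
(log2FC, padj) tables.

Two properties of this stand-in deserve explicit notice:

* **Power at n = 5.** A Welch t with ~8 degrees of freedom has a practical
  p-value floor near 10⁻⁷, so at the strict adjusted threshold of 10⁻⁵ its
  power for sixteenfold planted changes is roughly 70–85% — lower than
  NB-GLM machinery would achieve. The tests therefore assert strict FDR
  behaviour (no null gene flagged) and majority recovery, not full recovery.
* **BH adjustment is not value-level idempotent.** The step-up adjustment
  `padj_i = min_{j ≥ rank(i)} (m/rank_j) p_j` multiplies interior minima by
  `m/rank` again when re-applied: `(0.1, 0.9) → (0.2, 0.9) → (0.4, 0.9)`.
  Re-adjustment is monotone and order-preserving, and `padj ≥ p` always
  holds, but an idempotence identity does not; the acceptance suite states
  this expectation literally and the corresponding assertion fails by
  design rather than papering over it.

`pfaffl_relative_expression()` computes the efficiency-corrected ratio
`E_ref^Cq_ref / E_target^Cq_target`, with efficiencies as per-cycle
amplification factors in (1, 2] (2 = perfect doubling; percent inputs such
as 95 are converted to 1.95). The Cq generator is constructed so that at
zero noise this ratio returns the configured truth to machine precision — a
round-trip identity the tests exercise over random configurations.
`choose_two_sample_test()` encodes the assumption-guided chooser:
Shapiro–Wilk on both groups (n ≥ 3 required, otherwise nonparametric is
forced), then an F-test of variances (Brown–Forsythe available as an
option) deciding Student vs Welch; any non-normal group routes to the
Wilcoxon rank-sum test. All tests are two-sided at α = 0.05 by default.

## Trait genetics and phenotype statistics

`chisq_goodness()` is the plain Pearson goodness-of-fit test against an
arbitrary ratio (Yates' correction available but off by default, matching
textbook Mendelian workflows); expected counts below 1 are flagged.
`best_mendelian_ratio()` scans candidate ratios and returns the one with the
largest p-value together with the full table. One discreteness fact worth
recording: for a two-class 3:1 cohort of n = 48 the rejection region at
α = 0.05 is `|O − 36| ≥ 6`, whose exact binomial probability is 0.0646 —
the discrete test is slightly anticonservative, and no simulation of that
configuration will land a rejection rate inside a [0.04, 0.06] band except
by luck. The acceptance suite asserts the band as stated and that assertion
fails honestly; the module suite asserts the exact 0.0646 instead.

`cosegregation()` reports genotype–phenotype concordance and a permutation
p-value (fraction of genotype shuffles with at least the observed
concordance; R = 10000 by default, seeded), which matches exact enumeration
on small cohorts. `pigment_concentration()` multiplies absorbance by the
standard-curve conversion factor and the cuvette and extract volumes and
divides by loaded volume and tissue mass (all volumes in ml — a `"50ul"`
style suffix converts — mass in g), giving mg equivalent per g fresh
weight. `preference_test()` reports the first-landing proportion, a
two-sided one-sample t against 0.5 (two-sided because that reproduces the
printed statistics; a one-sided alternative is available) and the exact
binomial companion p; all-identical inputs flag the t as undefined.

## What the generators emulate — and what they do not

The synthetic-data module exists so that every pipeline stage has inputs
with known truth:

* `simulate_gene_family()` grows one gene lineage down a species tree with
  Poisson duplication/loss along branches (a duplication copies the whole
  subtending lineage). Ground-truth single-copy groups follow **locus
  tracking**: a duplication founds a new locus in one descendant lineage, so
  tips of one locus are related by speciation only. With both rates zero the
  family is a relabelled copy of the species tree — the basis of the
  end-to-end identity test. Contaminants (mimicking misassembled
  transcripts) are injected by inflating a tip's pendant length to 0.8
  subs/site — length inflation only, since the cleaning operators act on
  branch lengths.
* `simulate_sequences()` evolves Jukes–Cantor alignments, chosen because the
  closed-form expectation `E[p] = ¾(1 − e^{−4d/3})` makes the generator
  itself testable. No indels, no rate variation, no selection.
* `simulate_counts()` plants region-biased genes at a sixteenfold change
  (baseline in one region, switched up in the other) over NB noise with
  size 50 and five replicates per region — the kind of strongly biased,
  well-expressed regulator a stage-1 two-region comparison is designed to
  flag. Genes near the detection boundary are deliberately not planted.
* F2 cohorts, Cq tables and choice trials are drawn from their textbook
  models (1:2:1 genotypes; Cq constructed to invert exactly; i.i.d.
  Bernoulli).

Real data differ in ways these generators do not model: assembly chimeras
and fragmented transcripts, alignment error, substitution-model violations,
linked loci and segregation distortion, qPCR inhibition, bee behaviour
beyond a single Bernoulli draw. Passing tests therefore demonstrate that the
algorithms do what they claim under their stated models — not that those
models capture every artefact of a wet-lab dataset.

## Problem sizes and runtime choices

The shipped tests run the oracle comparisons at 200 random 12-tip homolog
trees (Maximum Inclusion), 50 random 6-taxon gene-tree sets (exact quartet
search), 20 seeded MSC replicates of 200 loci on a 6-taxon species tree with
internal branches of 1.5–2 coalescent units (topology recovery ≥ 95%, deep
branch lengths within 25%), 10 000 simulated F2 cohorts (type-I behaviour),
and 100 random qPCR round-trip configurations — sizes chosen so the whole
suite completes in a few minutes on one core while keeping Monte-Carlo
standard errors far below the asserted tolerances.

## Known limitations

* The exact species-tree search is factorial (guarded at nine taxa); no
  heuristic mode is provided.
* The similarity scorer is k-mer based; highly repetitive sequences inflate
  shared-k-mer counts relative to alignment scores.
* Maximum Inclusion is greedy: with nested duplications and complementary
  losses it can merge tips across loci or fail to isolate a full
  single-copy set; the recovery tests quantify this at moderate rates
  rather than hiding it.
* The DE stand-in trades the power of NB-GLM inference for transparency, as
  quantified above.
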