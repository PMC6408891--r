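---
title: "Detecting lineage-specific expansions and testing their evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific expansions and testing their evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsexpand)
```

Gene family expansions — bursts of duplication confined to one lineage —
are a recurring engine of phenotypic novelty, and receptor superfamilies
such as the G-protein-coupled receptors are classic substrates. `lsexpand`
implements the full analytical chain for studying such expansions from a
gene tree outward: find the lineage-restricted clades, ask whether the
duplicates diverged in tissue expression, test for positive selection with
codon models, and check whether the duplicates form tandem arrays on
genome scaffolds. This vignette explains the models, the parameters that
matter, and the choices made where the design was genuinely open.

## Expansion detection

A clade is *lineage restricted* when every leaf below it belongs to a focal
species set (e.g. three cephalopods inside a bilaterian-wide tree). The
detector scans every internal node of a rooted tree and keeps the **maximal**
restricted nodes: a restricted node nested inside a larger restricted node
describes the same duplication burst twice, so only the outermost node is
reported. Nodes are ranked by descendant gene count, kept at `cutoff` or
more genes, and finally filtered on node support.

Parameters and defaults:

* `cutoff = 10` genes — the outlier threshold separating "expansion" from
  ordinary small families. Must be at least 2.
* `min_support = 0.70` — a fraction in [0, 1] matching the
  Shimodaira–Hasegawa-like local supports that fast ML tree programs emit.
  It is applied as a *final* filter after maximality and ranking, so a
  poorly supported maximal node is dropped rather than replaced by its
  better-supported child; nodes without any support value fail a positive
  threshold. The comparison is `>=`.
* Ties in the ranking are broken by post-order node index, which makes the
  output order stable and reproducible.

Three decisions here were open and deserve explanation. First, *rooting*:
ML trees arrive unrooted, and which clades are "restricted" depends on the
root. The package roots unrooted input at the midpoint of the longest
leaf-to-leaf path by default (`root_gene_tree()`), with an outgroup-species
option; expansion calls should be read with that policy in mind. Second,
*nested clades*: the maximality reduction avoids double counting but means
a well-supported sub-expansion inside a weakly supported larger one is not
reported separately. Third, *polytomies* are treated as genuine
multifurcations and qualify like any other node.

For each detected group, `extract_group_subtree()` recovers the group plus
its closest *well-supported* outgroup: starting from the group's parent
node, the walk continues rootward past nodes below `min_support` until one
qualifies (falling back to the root with a warning). This subtree is the
input for the selection tests. `patristic_divergence_summary()` reports the
median and quartiles of each member's path-length distance to its nearest
reference-lineage leaf, in substitutions per site — a coarse clock for when
the burst happened.

## Tissue specificity

Tau for an expression vector \(x\) over \(n \ge 2\) tissues is
\(\tau = \sum_i (1 - x_i/\max_j x_j)/(n-1)\): 0 for uniform expression, 1
for single-tissue expression, scale invariant, undefined (NA) for all-zero
genes, which are excluded from summaries and counted in a QC report. The
specificity call `tau > 0.8` is strict: a gene at exactly 0.8 is not
specific. Raw normalized values (TPM-like) are used by default; a `log1p`
option exists because the Tau literature is split on log transformation,
but it is off by default and all reported calibrations use raw values.
Expression units differ between studies (transcripts per total counts,
TPM), so matrices from different species are analysed independently and
raw values are never compared across species.

Group comparisons are non-parametric throughout: Kruskal–Wallis on
mid-ranks with tie correction (via `stats::kruskal.test`), then Dunn's
pairwise z tests on mean ranks with the tie-corrected pooled variance and
two-sided p-values, all pairs entering one Holm family. Group mean Tau is
reported with a normal-approximation 95% CI (mean ± 1.96·se); since Tau
distributions can be skewed near the [0, 1] boundaries, a non-parametric
bootstrap option (`bootstrap = n`) is also provided.

## Codon models and selection tests

The selection machinery is a Goldman–Yang-style codon model over the 61
sense codons of the standard genetic code. The generator has
\(q_{ij} = \pi_j \kappa^{\mathrm{ti}} \omega^{\mathrm{ns}}\) for codon
pairs differing at one position (ti = transition, ns = non-synonymous),
zero otherwise. Codon frequencies \(\pi\) are F3×4 empirical estimates by
default (position-wise nucleotide frequencies, floored at 1e-4 so every
sense codon keeps positive mass), with an equal-frequency option.

Scaling: single-class models (M0 and the two-ratio branch model) scale each
generator to unit expected rate, so branch lengths are expected
substitutions per codon under that branch's own ω. Site-mixture models
(M1a/M2a) share one scaling factor — the proportion-weighted mean rate
across classes — because scaling each class separately would erase the rate
differences the mixture is meant to capture.

Likelihoods come from Felsenstein pruning over compressed site patterns,
with per-node rescaling against underflow; gap codons are missing data
(unit partial likelihoods). The pruning implementation is validated in the
test suite against brute-force enumeration of internal-node states on small
trees to |Δlogℓ| < 1e-8.

All codon fits operate on the *unrooted* tree (rooted input is unrooted
first). This is not cosmetic: under a reversible model the two branches
meeting at a root are unidentifiable — only their sum matters (the pulley
principle) — so on a rooted tree a foreground clade whose stem abuts the
root would let the branch model slide substitution mass between the
foreground and background ω classes, an artefactual extra degree of freedom
that inflates the likelihood-ratio statistic. On the unrooted tree the
group's stem is a single edge and foreground labelling resolves the
tip-set bipartition, so the two-ratio model has exactly one extra
parameter, as the χ²₁ reference assumes. Null simulations in the test
suite confirm the test then holds its nominal size.

Model fits maximize over κ, the ω parameters, and all branch lengths.
The optimizer alternates bounded quasi-Newton (L-BFGS-B) steps on log- or
logit-transformed global parameters with Brent line searches on each branch
length using cached outside partial likelihoods, iterating until the
log-likelihood improves by less than 1e-6 (initial values κ = 2, ω = 0.5,
branch lengths from the input tree; `multistart = n` adds jittered
restarts). Since simultaneous branch updates can overshoot, a sweep that
fails to improve the likelihood is geometrically damped and, if necessary,
reverted — fits therefore never decrease the likelihood across iterations.
When the alternation plateaus — typically on the ridge between a foreground
ω and the foreground branch lengths, which trade off almost linearly — the
fit finishes with one joint quasi-Newton pass over all parameters, using an
analytic gradient in the branch lengths (dP/dt follows directly from the
generator's eigendecomposition) and finite differences for the few global
parameters. Fitting the alternative model from the null model's optimum
(the `m0 =` argument of `fit_branch_model()`, and the internal M1a → M2a
seeding) guarantees the nested likelihood ordering in practice.

The three tests:

* **Branch (two-ratio) test**: foreground = every branch inside the
  expanded clade *including its stem* (the stem is part of the expansion
  history); background = the rest. LRT against M0 with df = 1.
* **Sites test**: M1a (purifying class ω₀ < 1 plus neutral class ω₁ = 1)
  against M2a (adds ω₂ > 1), df = 2. Per-site class posteriors are naive
  empirical Bayes at the MLEs — a deliberate approximation to Bayes
  empirical Bayes, which integrates over parameter uncertainty and is out
  of scope; NEB posteriors are anticonservative on small alignments and are
  flagged as such. Sites are reported when P(ω₂ class) ≥ 0.95 and
  ω̂₂ > 1.
* **LRT mechanics**: statistic max(0, 2Δℓ) against plain χ²ₖ — no boundary
  mixture correction, matching standard practice for these tests. A negative
  2Δℓ beyond tolerance triggers an optimizer-failure warning and clamps to 0.

Branch ω estimates above 100 are discarded from positive-selection
reporting (`filter_high_omega()`, strict inequality): such values almost
always reflect alignment noise between deeply diverged sequences, not
biology. A group is flagged "positive selection" when the branch LRT is
significant at α and the foreground ω̂ lies in (1, 100].

The per-group LRTs are reported raw by default — the groups are analysed as
separate hypotheses, as is conventional when each group is its own study
unit — with `adjust_group_lrts = TRUE` applying Holm across groups.

## Genomic co-localization

Coordinates are held 0-based half-open internally; 1-based inclusive tables
convert on input (`one_based = TRUE`). A tandem cluster is a maximal run of
two or more group members on one scaffold with at most `max_intervening`
(default 5) non-member genes between consecutive members. Strand is ignored
for clustering — real tandem arrays contain inversions — but the strand
pattern is reported. Counting intervening genes requires the scaffold's
full gene complement; when only group members are supplied, a distance
fallback (gap ≤ 100 kb) is used and labelled `method = "distance"`.
Scaffold occupancy (`scaffold_summary()`, threshold m = 3 genes) gives the
descriptive contrast between scattered background genes and clustered
expansions; no enrichment test is attached, deliberately — the denominator
(scaffold count, assembly contiguity) is assembly specific, so the summary
is reported descriptively.

## The synthetic-data module

Every analysis stage is exercised end to end on generated data with known
truth (`simulate_study()`); one root seed derives per-generator sub-seeds
so components can be regenerated independently and all outputs are
deterministic under a fixed seed.

* **Gene trees** (`simulate_gene_tree()`): a backbone of background gene
  families, each following the species topology (three focal + three
  outgroup species) with branch-length jitter and occasional within-species
  duplicate cherries (`dup_prob = 0.08`); planted expansions are focal-only
  clades of the requested sizes grafted next to a background family that
  serves as their sister outgroup, with well-supported stems (0.85–1) and
  ordinary nodes at 0.75–1, a `low_support_prob = 0.1` fraction downgraded
  to 0.3–0.7. Because background families always contain outgroup leaves
  and within-family duplications stay far below the cutoff, the planted
  clades are exactly the detectable expansions — which is what makes
  precision/recall against truth well defined.
* **Expression** (`simulate_expression()`): 12 tissue labels modelled on an
  octopus tissue panel; specific genes get one dominant tissue at
  `fold = 50` over a baseline of 5, broad genes near-uniform means with
  lognormal spread 0.3; gamma noise with `dispersion = 0.2`
  (variance = dispersion × mean²). Expanded groups draw a "home" tissue
  shared by 70% of their specific members, emulating expansions converging
  on a novel expression domain; specific fractions default to 0.7 for
  expanded and 0.25 for background genes. With these settings a planted
  specific gene has Tau ≈ 0.95–0.99, comfortably above the 0.8 call.
* **Codon alignments** (`simulate_codon_alignment()`): root sequence from
  the stationary frequencies, branch transitions from the matrix
  exponential of the same scaled generators the fitting code uses —
  simulate-and-recover checks are therefore exact model matches. Per-group
  alignments in the study bundle use ω_bg = 0.2, ω_fg = 1.5, κ = 2 on the
  extracted group + outgroup subtree, with subtree branch lengths rescaled
  (capped at 1, halved) to keep pairwise codon divergences in a regime
  where 60–150 codons are informative.
* **Scaffolds** (`simulate_scaffolds()`): planted tandem arrays with
  Poisson(1) intervening background genes, everything else scattered
  uniformly; intervals are non-overlapping by construction.

What the generator deliberately does *not* emulate: real GPCR sequence
composition or domain structure, alignment error (simulated alignments are
true alignments; back-translation and cleaning are exercised on them rather
than on misaligned data), assembly fragmentation, and cross-species
expression normalization differences. Passing tests therefore demonstrate
correctness of the algorithms and calibration of the statistics under the
generating model — not robustness to upstream alignment or assembly
artefacts.

## Numerical choices and scales used in validation

Pattern compression before pruning; per-node partial rescaling; generator
eigendecomposition via similarity-symmetrization (valid for any reversible
generator with positive π); transition probabilities clamped at 0 against
roundoff; optimizer bounds κ ∈ [0.05, 100], ω ∈ [1e-4, 1000], branch
lengths ∈ [1e-8, 20]; proportions through softmax/logit transforms.

The validation suite runs at desk scale on one CPU: oracle equivalence for
detection on 200 random trees (≤ 64 leaves), planted-expansion recovery on
50 trees, ω recovery on 20 replicates of 8 taxa × 500 codons per setting,
branch-test type-I error on 150 null replicates of 4 taxa × 60 codons, and
co-localization recovery on dozens of layouts. These sizes were chosen so
the whole suite completes in well under half an hour while keeping Monte
Carlo error small relative to the acceptance bands (e.g. a ±2.5% band on a
5% rejection rate at 200 replicates).

## Known limitations

* NEB instead of BEB for site posteriors (above); no branch-site model A
  and no free-ratio model — the branch test answers the group-level
  question.
* Expansion calls depend on rooting for unrooted input; midpoint rooting
  is a heuristic and an outgroup rooting should be preferred when one is
  known.
* The alternating optimizer can, like any local optimizer, stop at a local
  maximum on pathological data; `multistart` mitigates this and the
  convergence flag is always reported.
* The co-localization module reports structure, not significance.
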