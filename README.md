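# lsexpand

Analysis of **lineage-specific gene family expansions** from gene trees,
built around the questions raised by large receptor repertoires such as the
G-protein-coupled receptors (GPCRs) of coleoid cephalopods: where in a gene
tree did a lineage burst into many paralogues, did the duplicates diverge in
tissue expression, are they evolving under positive selection, and do they
sit next to each other in the genome as tandem arrays?

`lsexpand` takes the standard inputs a phylogenomic study produces — a gene
tree in Newick with branch support values, protein and CDS FASTA, a gene ×
tissue expression matrix, and a BED-like table of gene coordinates — and
provides four connected analyses plus a synthetic-data module that generates
all of these inputs with known ground truth.

## What it computes

**Expansion detection.** An internal node of a rooted gene tree is
*lineage-restricted* when every descendant leaf belongs to a focal species
set. `find_lineage_expansions()` returns the maximal such clades, ranked by
the number of genes they contain, kept when they hold at least `cutoff`
paralogues (default 10) and pass a branch-support filter (default
S–H-like support ≥ 0.70). `extract_group_subtree()` pulls out each group
with its closest well-supported sister clade for downstream selection tests,
and `patristic_divergence_summary()` reports median/quartile path-length
divergence (substitutions per site) between group members and their nearest
reference-lineage relatives.

**Tissue specificity.** For a gene expressed at levels
\(x_1, \dots, x_n\) across *n* tissues,

    Tau = sum_i (1 - x_i / max_j x_j) / (n - 1)

ranges from 0 (uniform expression) to 1 (single-tissue expression); genes
with Tau > 0.8 are called tissue specific. Groups are compared with a
Kruskal–Wallis rank test followed by Dunn's pairwise post hoc test with
Holm adjustment (`compare_tau_groups()`), and per-tissue expression
proportions \(x_i / \sum_j x_j\) are summarised per group
(`summarize_by_group()`).

**Positive selection.** `back_translate()` converts a gapped protein
alignment plus unaligned CDS into a codon alignment; `clean_alignment()`
applies TrimAl-style thresholds (0.25 column gap threshold, 0.25 residue
overlap, 90% sequence overlap) on whole codons. The Goldman–Yang codon
model (61 sense codons, transition/transversion ratio κ, dN/dS ratio ω,
F3×4 frequencies) is fitted by maximum likelihood via Felsenstein pruning:
`fit_m0()` (one ω for the whole tree), `fit_branch_model()` (separate
foreground/background ω, foreground = the expanded clade including its stem
branch), and `fit_sites_models()` (M1a vs M2a site classes with naive
empirical Bayes site posteriors). Nested fits are compared with `lrt()`
(2Δℓ against χ²ₖ), and `filter_high_omega()` discards branch estimates with
ω > 100, which typically reflect alignment problems rather than selection.

**Genomic co-localization.** `scaffold_summary()` counts, per group, the
scaffolds occupied and those carrying ≥ m group members (default 3);
`detect_tandem_clusters()` finds maximal runs of group genes separated by at
most `max_intervening` other genes — the signature of local tandem
duplication.

`run_pipeline()` chains everything on one configuration (defaults: cutoff
10, support 0.70, Tau 0.8, α 0.05, ω limit 100) and produces a
machine-readable report; `simulate_study()` generates a complete synthetic
study bundle with planted expansions, expression structure, per-branch ω,
and tandem arrays.

## Worked example

```r
library(lsexpand)

bundle <- simulate_study(seed = 123, n_background = 20,
                         planted_sizes = c(11L, 13L), n_codons = 120)
report <- run_pipeline(pipeline_config_from_bundle(bundle))
tidy(report)[, c("group", "size", "mean_tau", "lrt_p", "omega_foreground",
                 "omega_background", "positive_selection",
                 "n_tandem_clusters")]
```

```
   group size  mean_tau        lrt_p omega_foreground omega_background
1 group1   13 0.8666341 3.559578e-18         1.553270        0.2428848
2 group2   11 0.7349453 5.036547e-21         1.312684        0.1558730
  positive_selection n_tandem_clusters
1               TRUE                 2
2               TRUE                 1
```

Both planted clades (sizes 13 and 11) are detected exactly. Their mean Tau
(0.87, 0.73) reflects the planted excess of tissue-specific genes in the
expansions; the branch test rejects uniform ω with foreground estimates
(1.55, 1.31) well above background (0.24, 0.16) — the generating values
were ω_fg = 1.5 and ω_bg = 0.2 — so both groups are flagged as positively
selected, and the planted tandem arrays appear in the co-localization
columns of the same table.

## Scope

Tree inference, multiple sequence alignment, and support-value computation
are upstream of this package: trees and alignments are consumed as inputs.
Bayes empirical Bayes site posteriors are approximated by naive empirical
Bayes at the maximum-likelihood estimates. See the methods vignette
(`vignettes/expansion-analysis.Rmd`) for model details, tunable parameters,
and limitations.
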