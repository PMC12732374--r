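# fsgdep

Subtype-stratified analysis of CRISPR knockout-screen dependencies, built
to prioritize **essential ferroptosis suppressor genes (FSGs)** in
cholangiocarcinoma (CCA) subtypes — intrahepatic (iCCA) vs extrahepatic
(eCCA) — from DepMap-style inputs, and to test which of them are
*differentially* essential between the subtypes.

It is aimed at cancer functional-genomics analysts who work with
dependency-probability matrices (gene × cell line values in [0, 1], where
a score above 0.5 conventionally marks a gene as essential in that line)
together with matched expression data, model metadata, a common-essential
gene list, and a curated gene list such as the FerrDb ferroptosis
suppressors.

## What it computes

**Prioritization (filter cascade).** Restrict to models with both
dependency and expression profiles; drop genes expressed at ≥ 1 TPM in
fewer than 5% of models; drop genes missing dependency scores in more
than 20% of models. Then, per subtype, a gene is called essential when

- median dependency > 0.5 over the subtype's lines,
- at least 10% of lines depend on it (score > 0.5), and
- it is not a pan-cancer "common essential".

Essential calls are intersected with the FSG list, and each gene gets its
median dependency and fraction-essential per subtype (the two axes of the
standard scatter summary).

**Differential essentiality.** For each candidate gene (the union of the
per-subtype essential-FSG lists), the two subtype groups are compared
with the Wilcoxon rank-sum test — exact enumeration of all
`choose(n_i + n_e, n_i)` group assignments with mid-ranks for ties, or a
tie-corrected normal approximation when the assignment count exceeds the
enumeration cap — and with Hedges' g:

```
g  = J · (x̄_i − x̄_e) / s_p
s_p = sqrt( ((n_i − 1) s_i² + (n_e − 1) s_e²) / (n_i + n_e − 2) )
J  = 1 − 3 / (4 (n_i + n_e) − 9)
```

A gene is subtype-selective when |g| ≥ 0.8 and p < 0.05 (positive g =
more essential in iCCA). Benjamini–Hochberg q-values are reported
alongside.

**Over-representation analysis.** Standard upper hypergeometric tail
P(X ≥ k) of the query/set overlap against a stated background universe,
with set sizes restricted to [5, 2000], BH correction, and both adjusted
and nominal significance flags.

**Synthetic benchmark.** `simulate_screen()` generates the five input
file dialects with planted gene roles (background, pan-essential,
subtype-essential, shared-essential, silent) drawn from Beta
distributions on [0, 1], so every stage is testable without downloads,
and `score_recovery()` scores calls against the planted truth.

## Worked example

The `analysis/` scripts run the whole workflow on the bundled generator
(`01_simulate.R` → `05_recovery.R`, writing tables under `results/`).
In brief:

```r
library(fsgdep)
out <- run_synthetic_pipeline(simulation_config(seed = 42))
out$prioritized$stage_counts
#>   stage              n_genes
#> 1 input                  500
#> 2 expression_filter      485
#> 3 missingness_filter     485
#> 4 essential_iCCA          19
#> 5 essential_eCCA          16
#> 6 essential_fsg_iCCA      19
#> 7 essential_fsg_eCCA      16
```

500 simulated genes enter; 15 silent genes fail the expression filter;
19 and 16 genes are called essential in iCCA and eCCA — exactly the
planted 10 iCCA-only + 9 shared and 7 eCCA-only + 9 shared. The
differential stage then labels the planted subtype-essential genes
selective, e.g.

```
gene      g      p_value   selectivity     planted_role
GENE0030  7.25   3.8e-05   iCCA-selective  i_essential
GENE0045 -8.79   2.7e-04   eCCA-selective  e_essential
```

and the published 26-gene summary table partitions — with the same
median-dependency rule applied to its printed values — into 19 iCCA /
16 eCCA essential FSGs: 9 shared, 10 iCCA-only, 7 eCCA-only:

```r
partition_essential_fsgs(fsg_table1())[c("n_icca", "n_ecca", "n_shared")]
#> $n_icca  [1] 19
#> $n_ecca  [1] 16
#> $n_shared [1] 9
```

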