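# codonpanel

Codon usage bias (CUB) analysis of coding-sequence gene panels, and
attribution of that bias to mutation pressure, selection among synonymous
codons, and compositional constraint.

Synonymous codons are not used evenly. For a panel of genes — say, the
CDS of a disease-gene set — the questions are *which* codons are
preferred, *how strong* the bias is, and *which evolutionary force*
shaped it. `codonpanel` implements the standard toolkit end to end:

* per-gene nucleotide/GC composition by codon position (GC1, GC2, GC3,
  GC12 = (GC1+GC2)/2);
* **RSCU** (relative synonymous codon usage), RSCU(c) =
  count(c)/(family total/degeneracy), with over/under-representation
  calls at RSCU > 1.6 / < 0.6;
* **ENc**, Wright's effective number of codons (20 = one codon per amino
  acid, 61 = uniform synonymous usage), from the homozygosity estimator
  F = (nΣp² − 1)/(n − 1) and ENc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆;
* **CAI59/CAI18**, codon adaptation indices (geometric means of
  w = RSCU/RSCUmax reference weights; CAI18 averages per-family geometric
  means so amino-acid composition cannot dominate);
* **dinucleotide odds ratios** ρ(xy) = f(xy)/(f(x)f(y)) with CpG/TpA
  depletion classes (UNDER < 0.78, OVER > 1.23);
* force attribution: the **ENc–GC3 plot** against the null curve
  ENc\* = 2 + s + 29/(s² + (1−s)²) (genes below the curve ⇒ selection),
  the **neutrality regression** GC12 ~ GC3 (slope ≈ percent mutational
  contribution; 1 − slope ⇒ selection), **parity-rule-2** coordinates
  (A3/(A3+T3), G3/(G3+C3)), and per-nucleotide third-position
  regressions;
* nine **protein indices** (GRAVY, aromaticity, pI, aliphatic index,
  hydrophobicity %, Guruprasad instability index, acidic/basic/neutral
  residue counts);
* covariance **PCA** of the gene × 59-codon RSCU matrix and Pearson
  correlation reports with significance stars;
* a **synthetic CDS panel generator** with known GC3 targets, selection
  strength, CpG/TpA suppression and GC12–GC3 coupling, used to validate
  every estimator by parameter recovery.

## Worked example

```r
library(codonpanel)

# simulate a 42-gene panel with selection toward C/G-ending codons,
# CpG/TpA depletion and a GC12~GC3 neutrality structure
spec <- synthetic_panel_spec(
  n_genes = 42, length_codons_range = c(150, 3000),
  gc3_targets = c(0.31, 0.84), bias_strength = 1.5,
  cpg_suppression = 0.55, tpa_suppression = 0.65,
  neutrality_slope = 0.27, neutrality_intercept = 32.5,
  neutrality_noise_sd = 4, seed = 20240915)
res <- run_study(run_config(spec, "outputs", seed = 20240915))

res$neutrality
#> $slope      0.0835...
#> $pct_mutation   8.35...
#> $pct_selection 91.64...
summary(res$profile$enc)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   28.94   33.33   34.58   34.68   36.33   41.29
table(res$enc_gc3$verdict)
#> BELOW
#>    42
mean(res$dinucleotide$CG)
#> [1] 0.4496...
res$pca$variance_fraction[1:2]
#> [1] 36.59... 10.66...
```

Reading: every gene falls **below** the expected ENc–GC3 curve and the
neutrality slope is far from 1, so selection among synonyms — not
mutation pressure — dominates this panel's codon usage, exactly the
structure the generator was asked to build; the mean CpG odds ratio of
~0.45 reflects the requested CpG depletion.

The same pipeline runs on any CDS FASTA:

```r
res <- run_study(run_config("my_panel.fasta", "outputs"))
```

Step-by-step drivers with commentary live under `analysis/`
(`01_simulate_panel.R` … `05_multivariate.R`); each writes its tables to
`results/`. The methods vignette
(`vignettes/codon-usage-workflow.Rmd`) documents the models, parameter
choices and design decisions.

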