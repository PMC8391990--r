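---
title: "Codon usage bias analysis of CDS gene panels: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis of CDS gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonpanel)
```

## What the package computes

`codonpanel` profiles codon usage bias (CUB) across a panel of coding
sequences and attributes it to three forces: directional **mutation
pressure** (which acts on all codon positions alike and is read off the
largely synonymous third position), **selection among synonymous codons**
(translational or otherwise), and **compositional constraint**. The
statistics are the field's standard set:

* **Composition** — percent A/C/G/T overall and at codon positions 1–3;
  GC, GC1, GC2, GC3; GC12 defined as the arithmetic mean of GC1 and GC2.
* **RSCU** — observed codon count divided by the count expected under
  uniform use within its synonymous family; the family sum equals the
  family degeneracy. Codons with RSCU > 1.6 are called over-represented
  and < 0.6 under-represented. An amino acid absent from a gene yields
  MISSING, not zero: zero usage of a present family is informative,
  absence of the family is not.
* **ENc** — Wright's effective number of codons from the homozygosity
  estimator F = (n·Σp² − 1)/(n − 1) per amino acid with n ≥ 2
  occurrences, averaged within degeneracy classes, ENc = 2 + 9/F̄₂ +
  1/F̄₃ + 5/F̄₄ + 3/F̄₆, clamped to [20, 61]. The three six-fold families
  (Leu, Ser, Arg) are kept whole, Wright's original treatment and the
  CodonW default. If Ile (the only three-fold family) is unusable, F̄₃ is
  interpolated as (F̄₂ + F̄₄)/2, Wright's recommendation; if any other
  class is empty the gene's ENc is reported as undefined and excluded
  from correlations rather than guessed.
* **CAI59 / CAI18** — the classical codon adaptation index (geometric
  mean of relative-adaptiveness weights w = RSCU/RSCUmax over codon
  occurrences, 59-codon set) and an amino-acid-composition-corrected
  variant: per-family geometric means of w averaged over the 18
  degenerate families present in the gene, so a single abundant amino
  acid cannot dominate. The exact formula behind published "CAI18"
  values is not documented by its originating tool; the per-family-mean
  definition used here is a documented choice of this package and should
  not be presented as identical to any external implementation.
* **Dinucleotide odds ratios** — ρ(xy) = f(xy)/(f(x)·f(y)) over all
  overlapping base pairs of the given strand, codon boundaries included
  (the statistic is sequence-level, not codon-level); < 0.78 UNDER,
  > 1.23 OVER. No reverse-complement symmetrisation: CpG and GpC are
  analysed separately.
* **Force attribution** — the ENc–GC3 plot against the null curve
  ENc\*(s) = 2 + s + 29/(s² + (1−s)²); the neutrality regression of GC12
  on GC3 (slope ≈ relative mutational contribution, 100·(1−slope)
  percent attributed to selection); parity-rule-2 coordinates
  x = A3/(A3+T3), y = G3/(G3+C3); and per-nucleotide regressions of
  overall on third-position composition, whose R²·100 is reported under
  the conventional "mutational force percent" label. That label is
  reproduced as the field uses it; R² of such a regression is a measure
  of association, not a causal decomposition, and the package does not
  endorse the stronger reading.
* **Protein indices** — GRAVY (Kyte–Doolittle), aromaticity, pI
  (Bjellqvist pKa set, bisection to 0.001 pH), aliphatic index (Ikai
  coefficients), percent hydrophobic residues (configurable set, default
  A/C/F/I/L/M/V — published "hydrophobicity index" values rarely name
  their scale, so the set is explicit here), and the Guruprasad
  instability index from the bundled DIWV dipeptide table (> 40 =
  unstable). Histidine counts as basic in the residue-class tallies.
* **Multivariate** — column-centred, unscaled PCA of the gene × 59-codon
  RSCU matrix (RSCU values share a scale, so covariance PCA, with axis
  signs fixed by making each axis's largest-magnitude loading positive),
  and Pearson correlation reports with two-tailed t-distribution
  p-values, significance stars at 0.05/0.01/0.001/0.0001 on raw
  p-values, plus a Benjamini–Hochberg column for reference only.

## Input contract

`load_panel()` enforces the panel inclusion rules: length a positive
multiple of three, alphabet restricted to A/C/G/T (U and IUPAC ambiguity
codes are rejected as ambiguous, not silently converted), and no internal
stop codon. A terminal stop codon is retained — composition is a
nucleotide-level statistic over the full CDS — but stripped before every
amino-acid-level computation (RSCU, ENc, CAI, translation). An ATG start
is deliberately not required: panels assembled from annotation sources
legitimately contain non-ATG-initiated CDS, and rejecting on the start
codon would drop genes silently.

## The synthetic panel generator

`generate_panel()` provides panels with known ground truth so every
estimator can be validated by construction. Per gene:

1. a protein of uniformly sampled length is drawn from the amino-acid
   frequencies (uniform by default, configurable);
2. codons are drawn per family from a mixture of a **drift component**
   and a **preferred-codon bias**: the drift component splits probability
   t over the family's G/C-ending codons and 1 − t over its A/T-ending
   codons (a common third-base marginal across families — Wright's null —
   with t adjusted for the G forced by Met/Trp so the gene's expected
   GC3 equals its target), and bias strength κ moves mass
   κ/(1 + κ) onto the family's preferred codon;
3. when `neutrality_slope` is set, the amino-acid frequencies are
   exponentially tilted so the expected GC12 equals
   slope·GC3 + intercept + noise, with GC3 taken as the gene's expected
   realized GC3 under the full mixture (equal to the target at κ = 0);
4. CpG/TpA suppression is applied by Gibbs sweeps of synonymous codon
   resampling — the protein is never altered — with the Gibbs penalty
   calibrated per gene so the realized odds ratio is the requested factor
   times the gene's unsuppressed odds ratio. The calibration is needed
   because synonymous swaps shift mononucleotide frequencies too, so a
   fixed penalty under-delivers on the odds-ratio scale.

Defaults emulate the kind of panel the pipeline is built for: 42 genes of
150–3000 codons, GC3 targets spanning 0.31–0.84, and (in the study
configuration used by `analysis/01_simulate_panel.R` and the acceptance
script) κ = 1.5 toward C/G-ending mammalian preferred codons with
CpG/TpA suppression 0.55/0.65 and neutrality parameters
(0.27, 32.5, σ = 4) — values on the scale reported for mammalian
disease-gene panels. With κ > 0 the realized GC3 rises above the targets
and its spread compresses; that is the intended signature of selection,
not a calibration defect, and it is why the GC3-target contract
(realized within ±3 points at ≥ 1000 codons) is stated for κ = 0.

### What the null panels do and do not show

Two structural facts about the standard genetic code matter when reading
the generator's null behaviour:

* Under uniform amino-acid frequencies and uniform synonymous usage the
  third position is **not** at parity-rule-2 equilibrium: six two-fold
  families end in T/C but only three in A/G, so an unbiased panel sits
  near x ≈ 0.43, y ≈ 0.52 — not (0.5, 0.5). A PR2-equilibrium null
  therefore needs a balanced protein composition;
  `pr2_balanced_aa_freqs()` (13 residues whose third-base contributions
  cancel) provides one, and under it a no-force panel lands on
  (0.5, 0.5) within sampling error while keeping mean ENc at the
  null-curve value ≈ 60.5. Forcing PR2 equilibrium through codon weights
  instead was evaluated and rejected: the unique reweighting costs
  within-family evenness (mean ENc drops by ≈ 1–2 units) and detaches
  drift genes from the expected ENc–GC3 curve.
* Met and Trp always contribute a G at the third position. The expected
  ENc–GC3 curve models synonymous families only, so drift genes track the
  curve when GC3 is computed over the degenerate families
  (`gc3_policy = "degenerate_families"` in `enc_gc3_assessment()`); with
  the default include-all policy, panels whose Met+Trp fraction is large
  (10% under uniform amino-acid frequencies) sit a few ENc units off the
  curve at extreme GC3. Real proteomes have Met+Trp ≈ 3%, where the
  difference is small. The default output policy remains include-all and
  the policy used is recorded in the output metadata.

The generator emulates composition, synonymous-choice bias, dinucleotide
depletion and the GC12–GC3 coupling. It does not emulate splice
structure, isochore context, codon-pair bias, amino-acid-level selection
or phylogenetic correlation between genes; passing recovery tests on
synthetic panels therefore validates the estimators, not any biological
claim about real panels.

## Numerical and design choices

* GC12 is the arithmetic mean of GC1 and GC2 (identical to the GC
  fraction of the concatenated positions because the position classes
  have equal size, but the definition is fixed for documentation).
* Thresholds (RSCU 0.6/1.6, odds 0.78/1.23, instability 40) are strict
  inequalities; values exactly at a threshold fall in the middle class.
* The ENc–GC3 "ON the curve" verdict uses a configurable ±0.5 ENc band —
  exact equality never occurs for finite genes.
* CAI reference weights come from pooled panel counts by default;
  unobserved codons get weight 0.5/(family total) to keep geometric means
  finite, and families absent from the reference get w = 1 (no
  information, neutral contribution).
* The pI bisection brackets [0, 14] and stops at 0.001 pH; the charge
  model uses single terminal pKa values (3.55/7.50), not the
  residue-specific terminal corrections some tools apply, so values can
  differ from web-tool output by ~0.1–0.3 pH units.
* Degenerate inputs error loudly rather than guess: zero GC3 variance in
  the neutrality fit, fewer than 3 genes for any regression or PCA,
  empty reference panels, non-standard amino-acid letters.
* The tests validate estimators against independently coded brute-force
  oracles (with the genetic code derived from a second source) at 1e-6,
  and validate the generator by parameter recovery — the neutrality slope
  within ±0.05 at 500 genes of 300–800 codons (shorter genes attenuate
  the OLS slope through GC3 sampling noise, a standard errors-in-variables
  effect), and the CpG suppression factor within ±0.05 at ~10 kb of
  sequence, measured as the ratio of suppressed to unsuppressed odds
  ratio.

## Workflow

The `analysis/` scripts run the whole study over a simulated panel:

```
Rscript analysis/01_simulate_panel.R   # panel FASTA + ground truth
Rscript analysis/02_codon_usage.R      # composition, RSCU, ENc, CAI
Rscript analysis/03_dinucleotides.R    # odds ratios + correlations
Rscript analysis/04_forces.R           # ENc-GC3, neutrality, parity
Rscript analysis/05_multivariate.R     # PCA + correlation reports
```

`run_study()` performs the same stages in one call on any FASTA or
generator spec and writes every table plus a resolved configuration, a
run log and a checksum manifest; reruns with the same configuration are
byte-identical.

```{r example, eval = FALSE}
res <- run_study(run_config("panel.fasta", "outputs"))
res$neutrality$pct_selection
```

## Known limitations

* ENc for very short genes (< ~100 codons) is noisy and often undefined
  for a missing degeneracy class; such genes propagate NA and are dropped
  pairwise from correlations.
* CAI18 here is this package's definition (see above).
* The per-nucleotide "mutational force percent" inherits the field's
  interpretation of regression R²; treat it as descriptive.
* PCA is the analysis implemented and reported; correspondence analysis,
  which some codon-usage tools use for the same plot, is out of scope.
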