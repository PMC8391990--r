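Package: codonpanel
Title: Codon Usage Bias Analysis of Coding-Sequence Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Computes the full codon-usage-bias profile of a panel of coding
    sequences: nucleotide and GC composition by codon position, relative
    synonymous codon usage (RSCU) with over/under-representation calls,
    Wright's effective number of codons (ENc), codon adaptation indices
    (CAI59 and a per-family CAI18 variant), dinucleotide odds ratios with
    CpG/TpA suppression classes, mutation/selection force attribution
    (neutrality regression of GC12 on GC3, parity-rule-2 plots, the ENc-GC3
    null curve, per-nucleotide third-position regressions), protein indices
    (GRAVY, aromaticity, pI, aliphatic and instability indices, residue
    charge classes), and covariance PCA of gene-by-codon RSCU matrices.
    Includes a synthetic CDS panel generator with known compositional,
    selectional and dinucleotide structure so that every estimator can be
    validated by parameter recovery, plus a one-call pipeline that writes
    all per-gene and panel-level tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
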