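#!/usr/bin/env Rscript
# Step 2: composition and codon-usage profile of the panel.
#
# Per-gene nucleotide/GC composition by codon position, the gene x 59-codon
# RSCU matrix with over/under-representation calls (thresholds 1.6 / 0.6),
# Wright's ENc and CAI59/CAI18 against the pooled-panel reference.

library(codonpanel)

panel <- load_panel("results/panel.fasta")$accepted
cat(sprintf("loaded %d genes\n", length(panel)))

comp <- panel_composition(panel)
write.table(comp, "results/composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

m <- t(vapply(panel, function(cds) rscu(cds)$values, numeric(59)))
rownames(m) <- vapply(panel, function(x) x$gene_id, character(1))
write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
            "results/rscu_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

over_pct <- 100 * colMeans(m > 1.6, na.rm = TRUE)
top <- sort(over_pct, decreasing = TRUE)[1:5]
cat("codons most often over-represented (% of genes):\n")
print(round(top, 1))

ref <- build_reference_weights(panel)
profile <- data.frame(
  gene_id = rownames(m),
  enc = vapply(panel, function(x) enc(x)$enc, numeric(1)),
  cai59 = vapply(panel, function(x) cai(x, ref)$cai59, numeric(1)),
  cai18 = vapply(panel, function(x) cai(x, ref)$cai18, numeric(1)),
  GC3 = comp$GC3, GC12 = comp$GC12
)
write.table(profile, "results/codon_usage_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("ENc range %.1f-%.1f (mean %.1f); mean CAI59 %.3f\n",
            min(profile$enc, na.rm = TRUE), max(profile$enc, na.rm = TRUE),
            mean(profile$enc, na.rm = TRUE),
            mean(profile$cai59, na.rm = TRUE)))
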