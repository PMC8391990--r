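#!/usr/bin/env Rscript
# Step 5: multivariate structure and protein-index correlations.
#
# Covariance PCA of the gene x 59-codon RSCU matrix (axis fractions, most
# influential loadings), the GC-component correlation table, and the
# correlations of CAI18/ENc with the nine protein indices.

library(codonpanel)

panel <- load_panel("results/panel.fasta")$accepted
m <- rscu_matrix(panel)
pca <- pca_rscu(m)
write.table(data.frame(axis = seq_along(pca$variance_fraction),
                       variance_pct = pca$variance_fraction),
            "results/pca_variance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = rownames(pca$scores), pca$scores,
                       check.names = FALSE),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PCA: first four axes carry %.2f%%, %.2f%%, %.2f%%, %.2f%% of RSCU variance\n",
            pca$variance_fraction[1], pca$variance_fraction[2],
            pca$variance_fraction[3], pca$variance_fraction[4]))
l1 <- sort(abs(pca$loadings[, 1]), decreasing = TRUE)[1:4]
cat("highest-loading codons on axis 1:",
    paste(names(l1), collapse = ", "), "\n")

comp <- panel_composition(panel)
ref <- build_reference_weights(panel)
prof <- data.frame(
  GC = comp$GC, GC1 = comp$GC1, GC2 = comp$GC2, GC12 = comp$GC12,
  GC3 = comp$GC3,
  CAI59 = vapply(panel, function(x) cai(x, ref)$cai59, numeric(1)),
  ENc = vapply(panel, function(x) enc(x)$enc, numeric(1))
)
write.table(correlate(prof, "all"), "results/correlation_gc_components.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

prot <- panel_protein_indices(panel)
tab <- cbind(
  data.frame(CAI18 = vapply(panel, function(x) cai(x, ref)$cai18,
                            numeric(1)),
             ENc = prof$ENc),
  prot[, c("gravy", "aroma", "pi", "aliphatic_index", "hydrophobicity_pct",
           "instability_index", "n_acidic", "n_basic", "n_neutral")]
)
pairs <- unlist(lapply(c("CAI18", "ENc"), function(a) {
  lapply(setdiff(names(tab), c("CAI18", "ENc")), function(b) c(a, b))
}), recursive = FALSE)
rep <- correlate(tab, pairs)
write.table(rep, "results/correlation_protein_indices.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- rep[rep$significance != "NS", ]
cat(sprintf("%d of %d protein-index correlations significant at p < 0.05\n",
            nrow(sig), nrow(rep)))
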