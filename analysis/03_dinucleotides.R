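#!/usr/bin/env Rscript
# Step 3: dinucleotide representation and its relation to expression/bias.
#
# Odds ratios for the 16 dinucleotides (UNDER < 0.78, OVER > 1.23), then
# Pearson correlations of each dinucleotide's odds ratio with CAI59 (the
# expression proxy) and ENc (inverse bias).

library(codonpanel)

panel <- load_panel("results/panel.fasta")$accepted
odds <- panel_dinucleotide_odds(panel)
write.table(odds, "results/dinucleotide_odds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("CpG: mean odds %.3f (UNDER in %d/%d genes); TpA: mean %.3f (UNDER in %d/%d)\n",
            mean(odds$CG), sum(odds$CG_class == "UNDER"), nrow(odds),
            mean(odds$TA), sum(odds$TA_class == "UNDER"), nrow(odds)))

ref <- build_reference_weights(panel)
tab <- data.frame(
  CAI59 = vapply(panel, function(x) cai(x, ref)$cai59, numeric(1)),
  ENc = vapply(panel, function(x) enc(x)$enc, numeric(1)),
  odds[, c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
           "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")]
)
pairs <- unlist(lapply(c("CAI59", "ENc"), function(a) {
  lapply(setdiff(names(tab), c("CAI59", "ENc")), function(b) c(a, b))
}), recursive = FALSE)
rep <- correlate(tab, pairs)
write.table(rep, "results/dinucleotide_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- rep[rep$significance != "NS" & rep$variable_a == "CAI59", ]
cat("dinucleotides whose odds ratio tracks CAI59 (p < 0.05):",
    paste(sprintf("%s (r=%.2f)", sig$variable_b, sig$pearson_r),
          collapse = ", "), "\n")
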