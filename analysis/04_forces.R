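#!/usr/bin/env Rscript
# Step 4: attribute codon usage to mutation, selection and composition.
#
# ENc-GC3 null-curve assessment (genes below the curve = selection among
# synonyms), the neutrality regression of GC12 on GC3 (slope = relative
# mutational contribution), parity-rule-2 coordinates, and per-nucleotide
# regressions of overall on third-position composition.

library(codonpanel)

panel <- load_panel("results/panel.fasta")$accepted
comp <- panel_composition(panel)

assess <- enc_gc3_assessment(panel)
write.table(assess, "results/enc_gc3.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("ENc-GC3: %d/%d genes BELOW the expected curve, %d ABOVE, %d ON\n",
            sum(assess$verdict == "BELOW", na.rm = TRUE), nrow(assess),
            sum(assess$verdict == "ABOVE", na.rm = TRUE),
            sum(assess$verdict == "ON", na.rm = TRUE)))

fit <- neutrality_fit(comp)
jsonlite::write_json(fit, "results/neutrality.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("neutrality: GC12 = %.4f GC3 + %.2f (R2 = %.3f) -> mutation %.1f%%, selection %.1f%%\n",
            fit$slope, fit$intercept, fit$r_squared, fit$pct_mutation,
            fit$pct_selection))

par <- panel_parity(comp)
write.table(par$points, "results/parity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(par$summary, "results/parity_summary.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("parity: x = %.3f +/- %.3f, y = %.3f +/- %.3f\n",
            par$summary$x_mean, par$summary$x_sd,
            par$summary$y_mean, par$summary$y_sd))

reg <- third_position_regressions(comp)
write.table(reg, "results/third_position_regressions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("per-nucleotide mutational force percent (R2 x 100):",
    paste(sprintf("%s %.1f", reg$nucleotide, reg$mutational_force_pct),
          collapse = ", "), "\n")
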