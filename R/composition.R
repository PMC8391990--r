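#' Nucleotide and GC composition of a coding sequence
#'
#' Computes overall and codon-position-specific base composition: percent
#' A/C/G/T overall and at codon positions 1-3, GC percent overall and per
#' position, and GC12 — the arithmetic mean of GC1 and GC2, the quantity
#' regressed on GC3 in the neutrality analysis. All percentages are over the
#' full sequence including a terminal stop codon when present (composition is
#' a nucleotide-level statistic); nothing is rounded.
#'
#' @param cds A [coding_sequence()].
#' @return A one-row data.frame with columns `gene_id`, `pA`, `pC`, `pG`,
#'   `pT`, `pA1`...`pT3` (percent of each base at each codon position),
#'   `GC`, `GC1`, `GC2`, `GC3`, `GC12`.
#' @examples
#' composition_profile(coding_sequence("toy", "ATGGCC"))
#' @export
composition_profile <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  bases <- strsplit(cds$seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  pos <- rep_len(1:3, n)
  out <- list(gene_id = cds$gene_id)
  for (b in c("A", "C", "G", "T")) {
    out[[paste0("p", b)]] <- 100 * sum(bases == b) / n
  }
  for (b in c("A", "C", "G", "T")) {
    for (k in 1:3) {
      sel <- pos == k
      out[[paste0("p", b, k)]] <- 100 * sum(bases[sel] == b) / sum(sel)
    }
  }
  gc <- bases %in% c("G", "C")
  out$GC <- 100 * sum(gc) / n
  for (k in 1:3) {
    sel <- pos == k
    out[[paste0("GC", k)]] <- 100 * sum(gc[sel]) / sum(sel)
  }
  out$GC12 <- (out$GC1 + out$GC2) / 2
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Composition table for a whole panel
#'
#' @param panel List of [coding_sequence()] objects.
#' @return data.frame, one row per gene, columns as in
#'   [composition_profile()].
#' @export
panel_composition <- function(panel) {
  do.call(rbind, lapply(panel, composition_profile))
}
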