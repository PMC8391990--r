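AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) hydropathy scale.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

ACIDIC_AAS <- c("D", "E")
BASIC_AAS <- c("K", "R", "H")
AROMATIC_AAS <- c("F", "Y", "W")
# Residues counted as hydrophobic for the percent-hydrophobicity index;
# configurable in protein_indices().
HYDROPHOBIC_AAS_DEFAULT <- c("A", "C", "F", "I", "L", "M", "V")

# pKa values for the isoelectric-point charge model (Bjellqvist et al. 1993
# as adopted by the ExPASy tools; single terminal values, no
# residue-specific termini).
PKA_BJELLQVIST <- list(
  positive = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
)

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weights, loaded
# from the bundled table on first use.
diwv_cache <- new.env(parent = emptyenv())
diwv_matrix <- function() {
  if (is.null(diwv_cache$m)) {
    path <- system.file("extdata", "diwv_guruprasad1990.tsv",
                        package = "codonpanel", mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#", row.names = 1,
                             check.names = FALSE)
    diwv_cache$m <- as.matrix(tab)
  }
  diwv_cache$m
}

#' Translate a coding sequence
#'
#' Standard genetic code; the terminal stop codon, when present, is dropped.
#' Internal stops cannot occur in a valid [coding_sequence()].
#'
#' @param cds A [coding_sequence()].
#' @return Single-letter amino-acid string.
#' @examples
#' translate_cds(coding_sequence("toy", "ATGAAATAA"))
#' @export
translate_cds <- function(cds) {
  codons <- sense_codon_vector(cds)
  paste(STANDARD_CODE[codons], collapse = "")
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionisable groups: the N-terminus and
#' K/R/H side chains contribute 1/(1+10^(pH-pKa)) each, the C-terminus and
#' D/E/C/Y side chains contribute -1/(1+10^(pKa-pH)).
#'
#' @param protein Amino-acid string (standard 20 letters).
#' @param ph pH at which to evaluate the charge.
#' @return Net charge (elementary charges).
#' @export
protein_charge <- function(protein, ph) {
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  pos <- PKA_BJELLQVIST$positive
  neg <- PKA_BJELLQVIST$negative
  counts_pos <- c(Nterm = 1, K = sum(aa == "K"), R = sum(aa == "R"),
                  H = sum(aa == "H"))
  counts_neg <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
                  C = sum(aa == "C"), Y = sum(aa == "Y"))
  sum(counts_pos / (1 + 10^(ph - pos[names(counts_pos)]))) -
    sum(counts_neg / (1 + 10^(neg[names(counts_neg)] - ph)))
}

#' Isoelectric point by bisection
#'
#' pH at which [protein_charge()] crosses zero, located by bisection on
#' \[0, 14\] to a width of `tol` pH units.
#'
#' @param protein Amino-acid string.
#' @param tol Bisection convergence width in pH units (default 0.001).
#' @return Estimated pI.
#' @export
isoelectric_point <- function(protein, tol = 0.001) {
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(protein, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Protein indices of an amino-acid sequence
#'
#' Computes the nine indices used to relate protein properties to codon
#' usage and expression:
#' \describe{
#'   \item{gravy}{grand average of Kyte-Doolittle hydropathy (positive =
#'     hydrophobic); bounded by the scale extremes -4.5 (poly-R) and 4.5
#'     (poly-I)}
#'   \item{aroma}{aromaticity: combined frequency of Phe, Tyr, Trp}
#'   \item{pi}{isoelectric point (Bjellqvist pKa set, bisection)}
#'   \item{aliphatic_index}{100 * (xAla + 2.9 xVal + 3.9 (xIle + xLeu)),
#'     x = mole fractions (Ikai 1980)}
#'   \item{hydrophobicity_pct}{percent of residues in `hydrophobic_set`}
#'   \item{instability_index}{(10/L) * sum of Guruprasad DIWV dipeptide
#'     weights over adjacent residue pairs; > 40 predicts an unstable
#'     protein (`stability` label)}
#'   \item{n_acidic/n_basic/n_neutral}{residue counts with acidic = D,E;
#'     basic = K,R,H; neutral = the rest}
#' }
#'
#' @param protein Amino-acid string over the standard 20 letters.
#' @param hydrophobic_set Residues counted as hydrophobic for
#'   `hydrophobicity_pct` (default A,C,F,I,L,M,V).
#' @return One-row data.frame with the indices, `length_aa` and `stability`
#'   (`"UNSTABLE"` if instability_index > 40 else `"STABLE"`).
#' @examples
#' protein_indices("MKWVTFISLLLLFSSAYS")
#' @export
protein_indices <- function(protein, hydrophobic_set = HYDROPHOBIC_AAS_DEFAULT) {
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) stop("empty protein")
  bad <- which(!(aa %in% AA20))
  if (length(bad) > 0L) {
    stop(sprintf("non-standard amino acid '%s' at position %d",
                 aa[bad[1]], bad[1]))
  }
  L <- length(aa)
  x <- table(factor(aa, levels = AA20)) / L
  instab <- if (L >= 2L) {
    m <- diwv_matrix()
    (10 / L) * sum(m[cbind(aa[-L], aa[-1L])])
  } else {
    0
  }
  pi_val <- isoelectric_point(protein)
  data.frame(
    gravy = mean(KD_HYDROPATHY[aa]),
    aroma = sum(aa %in% AROMATIC_AAS) / L,
    pi = pi_val,
    aliphatic_index = 100 * (x[["A"]] + 2.9 * x[["V"]] +
                               3.9 * (x[["I"]] + x[["L"]])),
    hydrophobicity_pct = 100 * sum(aa %in% hydrophobic_set) / L,
    instability_index = instab,
    n_acidic = sum(aa %in% ACIDIC_AAS),
    n_basic = sum(aa %in% BASIC_AAS),
    n_neutral = sum(!(aa %in% c(ACIDIC_AAS, BASIC_AAS))),
    length_aa = L,
    stability = if (instab > 40) "UNSTABLE" else "STABLE",
    stringsAsFactors = FALSE
  )
}

#' Protein-index table for a panel of coding sequences
#'
#' @param panel List of [coding_sequence()] objects.
#' @param ... Passed to [protein_indices()].
#' @return data.frame, one row per gene with a leading `gene_id` column.
#' @export
panel_protein_indices <- function(panel, ...) {
  rows <- lapply(panel, function(cds) {
    cbind(data.frame(gene_id = cds$gene_id, stringsAsFactors = FALSE),
          protein_indices(translate_cds(cds), ...))
  })
  do.call(rbind, rows)
}
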