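# Standard genetic code (NCBI translation table 1), DNA alphabet.
# Kept as an explicit table so every downstream statistic (RSCU families,
# ENc degeneracy classes, CAI codon sets) is auditable in one place.

STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- names(STANDARD_CODE)[STANDARD_CODE == "*"]
SENSE_CODONS <- names(STANDARD_CODE)[STANDARD_CODE != "*"]

# Synonymous families: amino acid -> codons. Six-fold families (Leu, Ser,
# Arg) are kept whole, Wright's original treatment, so degeneracy classes
# are 2 (9 families), 3 (Ile), 4 (5 families) and 6 (3 families).
SYN_FAMILIES <- split(SENSE_CODONS, STANDARD_CODE[SENSE_CODONS])

FAMILY_DEGENERACY <- vapply(SYN_FAMILIES, length, integer(1))

# The 18 degenerate families and the 59 codons they contain (61 sense codons
# minus the single-codon ATG/Met and TGG/Trp).
DEGENERATE_AAS <- names(FAMILY_DEGENERACY)[FAMILY_DEGENERACY > 1]
CODONS_59 <- unname(unlist(SYN_FAMILIES[DEGENERATE_AAS]))

codon_family <- function(codon) STANDARD_CODE[[codon]]

#' Split a coding sequence into codons
#'
#' @param seq Nucleotide string whose length is a multiple of 3.
#' @return Character vector of codons in order.
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# Codons of a gene that enter amino-acid-level statistics: terminal stop
# (if present) dropped; internal stops are excluded by the CDS invariant.
sense_codon_vector <- function(cds) {
  codons <- split_codons(cds$seq)
  k <- length(codons)
  if (k > 0L && codons[k] %in% STOP_CODONS) codons <- codons[-k]
  codons
}
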