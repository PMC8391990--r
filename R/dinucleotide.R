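# Dinucleotide representation thresholds: odds ratios below 0.78 are called
# under-represented and above 1.23 over-represented.
DINUC_UNDER <- 0.78
DINUC_OVER <- 1.23

DINUCLEOTIDES <- as.vector(outer(c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T"), paste0))

#' Dinucleotide odds ratios of a coding sequence
#'
#' For each of the 16 dinucleotides xy, the odds ratio
#' rho(xy) = f(xy) / (f(x) * f(y)), where f(xy) is the frequency of xy among
#' all overlapping adjacent base pairs of the single given strand (no
#' wrap-around, codon boundaries included) and f(x), f(y) are mononucleotide
#' frequencies over all bases. Values below 0.78 are classed UNDER, above
#' 1.23 OVER, otherwise NORMAL; pairs involving a base absent from the
#' sequence are undefined and classed MISSING.
#'
#' @param cds A [coding_sequence()], or a plain A/C/G/T string (the odds
#'   ratio is a sequence-level statistic and needs no reading frame); at
#'   least 2 nt.
#' @return List with `rho` (named numeric over the 16 dinucleotides, `NA`
#'   when undefined), `class` (named character), and `f_dinuc` (observed
#'   dinucleotide frequencies, summing to 1).
#' @examples
#' dinucleotide_odds("ATATATAT")$rho["AT"]
#' @export
dinucleotide_odds <- function(cds) {
  seq <- if (inherits(cds, "coding_sequence")) cds$seq else toupper(cds)
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 2L,
            !grepl("[^ACGT]", seq))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  mono <- vapply(c("A", "C", "G", "T"),
                 function(b) sum(bases == b) / n, numeric(1))
  pairs <- paste0(bases[-n], bases[-1L])
  f_dinuc <- vapply(DINUCLEOTIDES,
                    function(d) sum(pairs == d) / (n - 1L), numeric(1))
  expected <- vapply(DINUCLEOTIDES, function(d) {
    mono[[substr(d, 1, 1)]] * mono[[substr(d, 2, 2)]]
  }, numeric(1))
  rho <- ifelse(expected > 0, f_dinuc / expected, NA_real_)
  names(rho) <- DINUCLEOTIDES
  cls <- ifelse(is.na(rho), "MISSING",
                ifelse(rho < DINUC_UNDER, "UNDER",
                       ifelse(rho > DINUC_OVER, "OVER", "NORMAL")))
  names(cls) <- DINUCLEOTIDES
  list(rho = rho, class = cls, f_dinuc = f_dinuc)
}

#' Panel table of dinucleotide odds ratios
#'
#' @param panel List of [coding_sequence()] objects.
#' @return data.frame: one row per gene; for each dinucleotide a ratio
#'   column (`AA` ... `TT`) and a class column (`AA_class` ...).
#' @export
panel_dinucleotide_odds <- function(panel) {
  rows <- lapply(panel, function(cds) {
    d <- dinucleotide_odds(cds)
    row <- c(list(gene_id = cds$gene_id), as.list(d$rho))
    cls <- as.list(d$class)
    names(cls) <- paste0(DINUCLEOTIDES, "_class")
    as.data.frame(c(row, cls), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
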