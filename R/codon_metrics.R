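# RSCU classification thresholds: codons with RSCU above 1.6 are called
# over-represented and below 0.6 under-represented, the conventional cutoffs
# for codon-usage panels.
RSCU_OVER <- 1.6
RSCU_UNDER <- 0.6

#' Codon occurrence counts of a coding sequence
#'
#' Counts over the 61 sense codons; the terminal stop codon (if any) is
#' excluded, internal stops cannot occur in a valid [coding_sequence()].
#'
#' @param cds A [coding_sequence()].
#' @return Named integer vector over all 61 sense codons (zeros included).
#' @export
codon_counts <- function(cds) {
  codons <- sense_codon_vector(cds)
  counts <- integer(length(SENSE_CODONS))
  names(counts) <- SENSE_CODONS
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon c in a synonymous family of degeneracy d with family total
#' n is count(c) / (n / d): the ratio of the observed count to the count
#' expected under uniform use within the family, so RSCU sums to d over each
#' family present in the gene. Computed for the 59 codons of the 18
#' degenerate families (ATG, TGG and stops excluded). Codons of an amino
#' acid absent from the gene are `NA` (MISSING) rather than 0: zero usage of
#' a present family is informative, absence of the family is not.
#'
#' @param cds A [coding_sequence()].
#' @return List with `values` (named numeric over the 59 codons, `NA` when
#'   the amino acid is absent) and `classification` (named character:
#'   `"OVER"` RSCU > 1.6, `"UNDER"` RSCU < 0.6 including 0, `"RANDOM"`
#'   otherwise, `"MISSING"` when the family is absent).
#' @examples
#' rscu(coding_sequence("toy", "CTGCTGCTT"))$values[c("CTG", "CTT")]
#' @export
rscu <- function(cds) {
  counts <- codon_counts(cds)
  values <- rep(NA_real_, length(CODONS_59))
  names(values) <- CODONS_59
  for (aa in DEGENERATE_AAS) {
    fam <- SYN_FAMILIES[[aa]]
    total <- sum(counts[fam])
    if (total == 0L) next
    values[fam] <- counts[fam] / (total / length(fam))
  }
  classification <- ifelse(
    is.na(values), "MISSING",
    ifelse(values > RSCU_OVER, "OVER",
           ifelse(values < RSCU_UNDER, "UNDER", "RANDOM"))
  )
  names(classification) <- CODONS_59
  list(values = values, classification = classification)
}

#' Wright's effective number of codons (ENc)
#'
#' Homozygosity estimator of synonymous codon-usage evenness. For each amino
#' acid with n >= 2 codon occurrences, F = (n * sum(p_i^2) - 1) / (n - 1)
#' where p_i are within-family codon proportions. F-bar_k is the mean F over
#' amino acids of degeneracy k (six-fold families kept whole), and
#' ENc = 2 + 9/F-bar_2 + 1/F-bar_3 + 5/F-bar_4 + 3/F-bar_6, clamped to
#' \[20, 61\]. 20 means a single codon per amino acid (maximal bias), 61
#' uniform synonymous usage (no bias).
#'
#' Amino acids with fewer than two occurrences are excluded (F is undefined
#' at n = 1). If the three-fold class (Ile) is unavailable its F-bar is
#' replaced by (F-bar_2 + F-bar_4)/2, Wright's recommendation; if any other
#' degeneracy class has no usable family the gene's ENc is undefined and
#' `NA` is returned with the reason in `reason`.
#'
#' @param cds A [coding_sequence()].
#' @return List with `enc` (numeric in \[20, 61\] or `NA`), `family_means`
#'   (named numeric, F-bar for degeneracy classes "2","3","4","6") and
#'   `reason` (`NA` or a message when ENc is undefined).
#' @export
enc <- function(cds) {
  counts <- codon_counts(cds)
  f_by_class <- list(`2` = numeric(0), `3` = numeric(0),
                     `4` = numeric(0), `6` = numeric(0))
  for (aa in DEGENERATE_AAS) {
    fam <- SYN_FAMILIES[[aa]]
    n <- sum(counts[fam])
    if (n < 2L) next
    p <- counts[fam] / n
    f_aa <- (n * sum(p^2) - 1) / (n - 1)
    k <- as.character(length(fam))
    f_by_class[[k]] <- c(f_by_class[[k]], f_aa)
  }
  fbar <- vapply(f_by_class, function(f) {
    if (length(f) == 0L) NA_real_ else mean(f)
  }, numeric(1))
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  missing_class <- names(fbar)[is.na(fbar)]
  if (length(missing_class) > 0L) {
    return(list(enc = NA_real_, family_means = fbar,
                reason = paste0("no usable family of degeneracy ",
                                paste(missing_class, collapse = ","))))
  }
  # F can be 0 when a family's n occurrences... cannot: F >= (n*1/n - 1)/(n-1)
  # is reached only in the uniform limit; F = 0 occurs for n=2 split 1/1 in a
  # 2-fold family? (2*0.5-1)/1 = 0. Guard the division.
  if (any(fbar <= 0)) {
    return(list(enc = 61, family_means = fbar, reason = NA_character_))
  }
  value <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  list(enc = min(61, max(20, value)), family_means = fbar,
       reason = NA_character_)
}

#' Build CAI reference weights from a reference panel or usage table
#'
#' Relative adaptiveness w(c) = RSCU(c) / max RSCU within c's synonymous
#' family, computed on pooled codon counts of a reference gene set (or a
#' supplied named count vector). Every family has at least one codon with
#' w = 1. Codons unobserved in the reference get the small positive weight
#' 0.5 / (family reference total) so that genes using them keep a finite
#' geometric mean.
#'
#' Families entirely absent from the reference carry no usage information
#' and get w = 1 for every codon (neutral contribution to any CAI).
#'
#' @param reference List of [coding_sequence()] objects, or a named numeric
#'   vector of codon counts covering the 59 degenerate-family codons.
#' @param reference_id Label stored with downstream CAI results.
#' @return List with `w` (named numeric over the 59 codons, in (0, 1\]) and
#'   `reference_id`.
#' @export
build_reference_weights <- function(reference, reference_id = "pooled_panel") {
  if (is.list(reference)) {
    if (length(reference) == 0L) stop("empty reference panel")
    counts <- Reduce(`+`, lapply(reference, codon_counts))
  } else if (is.numeric(reference) && !is.null(names(reference))) {
    counts <- numeric(length(SENSE_CODONS))
    names(counts) <- SENSE_CODONS
    keep <- intersect(names(reference), SENSE_CODONS)
    counts[keep] <- reference[keep]
  } else {
    stop("reference must be a panel (list) or a named codon-count vector")
  }
  w <- rep(NA_real_, length(CODONS_59))
  names(w) <- CODONS_59
  for (aa in DEGENERATE_AAS) {
    fam <- SYN_FAMILIES[[aa]]
    total <- sum(counts[fam])
    if (total == 0) {
      w[fam] <- 1
      next
    }
    rscu_fam <- counts[fam] / (total / length(fam))
    w_fam <- rscu_fam / max(rscu_fam)
    w_fam[counts[fam] == 0] <- 0.5 / total
    w[fam] <- w_fam
  }
  list(w = w, reference_id = reference_id)
}

#' Codon adaptation index (CAI59 and CAI18)
#'
#' CAI59, the classical index, is the geometric mean of the reference
#' weights w(c) over every codon occurrence of the gene, excluding ATG, TGG
#' and stop codons (the 59-codon set). CAI18 corrects for amino-acid
#' composition: the geometric mean of w is taken within each of the 18
#' degenerate families present in the gene, and those per-family means are
#' averaged, so an amino acid contributes equally regardless of how often it
#' occurs.
#'
#' @param cds A [coding_sequence()].
#' @param ref Reference weights from [build_reference_weights()].
#' @return List with `cai59`, `cai18` (both in \[0, 1\], `NA` with an error
#'   message in `reason` for a gene with no degenerate-family codons) and
#'   `reference_id`.
#' @export
cai <- function(cds, ref) {
  counts <- codon_counts(cds)[CODONS_59]
  w <- ref$w[CODONS_59]
  used <- counts > 0
  if (!any(used)) {
    return(list(cai59 = NA_real_, cai18 = NA_real_,
                reference_id = ref$reference_id,
                reason = "gene has no codons outside Met/Trp"))
  }
  cai59 <- exp(sum(counts[used] * log(w[used])) / sum(counts[used]))
  fam_means <- vapply(DEGENERATE_AAS, function(aa) {
    fam <- SYN_FAMILIES[[aa]]
    cf <- counts[fam]
    if (sum(cf) == 0) return(NA_real_)
    nz <- cf > 0
    exp(sum(cf[nz] * log(w[fam][nz])) / sum(cf))
  }, numeric(1))
  cai18 <- mean(fam_means, na.rm = TRUE)
  list(cai59 = cai59, cai18 = cai18, reference_id = ref$reference_id,
       reason = NA_character_)
}
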