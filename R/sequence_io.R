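#' Construct a validated coding sequence
#'
#' A `coding_sequence` is a CDS that has passed the panel inclusion filters:
#' length a positive multiple of three, alphabet restricted to A/C/G/T, and
#' no stop codon at any internal codon position. A stop codon in the final
#' position is allowed and retained (it contributes to nucleotide-level
#' composition but is stripped before any amino-acid-level statistic).
#'
#' @param gene_id Short gene label (e.g. a gene symbol). Must be non-empty.
#' @param seq Nucleotide string; case-insensitive, normalised to upper case.
#' @return An object of class `coding_sequence` with fields `gene_id`,
#'   `seq` and `codon_count` (= nchar(seq)/3, terminal stop included).
#' @seealso [load_panel()] for reading and filtering a FASTA panel.
#' @examples
#' cds <- coding_sequence("demo", "ATGAAATAA")
#' cds$codon_count
#' @export
coding_sequence <- function(gene_id, seq) {
  reason <- cds_rejection_reason(seq)
  if (!is.na(reason)) {
    stop(sprintf("invalid coding sequence '%s': %s", gene_id, reason))
  }
  if (!is.character(gene_id) || length(gene_id) != 1L || !nzchar(gene_id)) {
    stop("gene_id must be a non-empty string")
  }
  seq <- toupper(seq)
  structure(
    list(gene_id = gene_id, seq = seq, codon_count = nchar(seq) %/% 3L),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons)\n",
              x$gene_id, nchar(x$seq), x$codon_count))
  invisible(x)
}

# Returns NA when the sequence passes every filter, otherwise one of the
# rejection reason codes. U is deliberately an ambiguous base, not silently
# converted to T: the inclusion rule admits A, T, C, G only.
cds_rejection_reason <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    return("EMPTY")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) return("AMBIGUOUS_BASE")
  if (nchar(seq) %% 3L != 0L) return("NOT_MULTIPLE_OF_3")
  codons <- split_codons(seq)
  internal <- codons[-length(codons)]
  if (any(internal %in% STOP_CODONS)) return("INTERNAL_STOP")
  NA_character_
}

#' Load a FASTA panel of coding sequences with inclusion filtering
#'
#' Reads a multi-FASTA file (or connection) of CDS records and partitions
#' them into accepted [coding_sequence()] objects and a rejection report.
#' A record is rejected when it is empty, contains a base other than
#' A/T/C/G (including U and IUPAC ambiguity codes), has a length not
#' divisible by three, or carries a stop codon before its final codon.
#' Input order is preserved and every record lands in exactly one of the
#' two partitions.
#'
#' @param fasta_source Path to a FASTA file. The record id is the header
#'   token before the first whitespace; the remainder of the description
#'   line is ignored.
#' @return A list with components:
#'   \describe{
#'     \item{accepted}{list of `coding_sequence` objects, input order}
#'     \item{rejected}{data.frame with columns `gene_id`, `reason`
#'       (one of NOT_MULTIPLE_OF_3, AMBIGUOUS_BASE, INTERNAL_STOP, EMPTY)}
#'   }
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">ok", "ATGAAATAA", ">bad", "ATGTAAAAA"), fa)
#' panel <- load_panel(fa)
#' panel$rejected
#' @export
load_panel <- function(fasta_source) {
  records <- tryCatch(
    seqinr::read.fasta(fasta_source, seqtype = "AA", as.string = TRUE,
                       whole.header = FALSE),
    error = function(e) stop("malformed FASTA input: ", conditionMessage(e))
  )
  ids <- names(records)
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in FASTA input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  accepted <- list()
  rej_id <- character(0)
  rej_reason <- character(0)
  for (i in seq_along(records)) {
    seq <- as.character(records[[i]])
    reason <- cds_rejection_reason(seq)
    if (is.na(reason)) {
      accepted[[length(accepted) + 1L]] <- coding_sequence(ids[i], seq)
    } else {
      rej_id <- c(rej_id, ids[i])
      rej_reason <- c(rej_reason, reason)
    }
  }
  list(
    accepted = accepted,
    rejected = data.frame(gene_id = rej_id, reason = rej_reason,
                          stringsAsFactors = FALSE)
  )
}

#' Write a panel of coding sequences to FASTA
#'
#' @param panel List of [coding_sequence()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  seqinr::write.fasta(
    sequences = lapply(panel, function(cds) cds$seq),
    names = vapply(panel, function(cds) cds$gene_id, character(1)),
    file.out = path, as.string = TRUE, nbchar = 70
  )
  invisible(path)
}

#' Write a rejection report as TSV
#'
#' @param rejected Rejection data.frame as returned by [load_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

panel_ids <- function(panel) vapply(panel, function(x) x$gene_id, character(1))
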