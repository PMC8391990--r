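# Independent brute-force oracles. The genetic code here is derived from
# seqinr::translate, not from the package's tables, so table and algorithm
# errors cannot cancel.

oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                            function(ab, c) paste0(ab, c)))
  aa <- vapply(codons, function(c) {
    seqinr::translate(seqinr::s2c(c))
  }, character(1))
  names(aa) <- codons
  aa
})

oracle_families <- local({
  sense <- names(oracle_code)[oracle_code != "*"]
  split(sense, oracle_code[sense])
})

oracle_split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
}

# Codons entering amino-acid-level statistics: terminal stop dropped.
oracle_sense_codons <- function(seq) {
  cod <- oracle_split_codons(seq)
  if (oracle_code[cod[length(cod)]] == "*") cod <- cod[-length(cod)]
  cod
}

oracle_rscu <- function(seq) {
  cod <- oracle_sense_codons(seq)
  out <- c()
  for (aa in names(oracle_families)) {
    fam <- oracle_families[[aa]]
    if (length(fam) < 2) next
    n <- sum(cod %in% fam)
    for (c in fam) {
      out[c] <- if (n == 0) NA_real_ else sum(cod == c) * length(fam) / n
    }
  }
  out
}

oracle_enc <- function(seq) {
  cod <- oracle_sense_codons(seq)
  f_list <- list()
  for (aa in names(oracle_families)) {
    fam <- oracle_families[[aa]]
    if (length(fam) < 2) next
    n <- sum(cod %in% fam)
    if (n < 2) next
    p <- vapply(fam, function(c) sum(cod == c) / n, numeric(1))
    f <- (n * sum(p^2) - 1) / (n - 1)
    k <- as.character(length(fam))
    f_list[[k]] <- c(f_list[[k]], f)
  }
  fbar <- function(k) if (is.null(f_list[[k]])) NA else mean(f_list[[k]])
  f2 <- fbar("2"); f3 <- fbar("3"); f4 <- fbar("4"); f6 <- fbar("6")
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  if (any(c(f2, f3, f4, f6) <= 0)) return(61)
  min(61, max(20, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6))
}

oracle_odds <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- c()
  for (x in c("A", "C", "G", "T")) {
    for (y in c("A", "C", "G", "T")) {
      fxy <- sum(ch[-n] == x & ch[-1] == y) / (n - 1)
      fx <- sum(ch == x) / n
      fy <- sum(ch == y) / n
      out[paste0(x, y)] <- if (fx * fy > 0) fxy / (fx * fy) else NA_real_
    }
  }
  out
}

oracle_pca_varfrac <- function(m) {
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  100 * ev / sum(ev)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Random valid CDS: uniform sense codons, optional terminal stop.
random_cds <- function(n_codons, gene_id = "rnd", with_stop = TRUE,
                       codon_pool = NULL) {
  if (is.null(codon_pool)) {
    codon_pool <- names(oracle_code)[oracle_code != "*"]
  }
  body <- sample(codon_pool, n_codons, replace = TRUE)
  tail <- if (with_stop) sample(c("TAA", "TAG", "TGA"), 1) else character(0)
  coding_sequence(gene_id, paste(c(body, tail), collapse = ""))
}
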