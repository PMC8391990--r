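#' Gene-by-codon RSCU matrix of a panel
#'
#' Rows are genes, columns the 59 codons of the degenerate families (stops,
#' ATG and TGG excluded). MISSING values (amino acid absent from a gene)
#' are imputed as 0 for multivariate analysis.
#'
#' @param panel List of [coding_sequence()] objects.
#' @param impute_missing Value substituted for MISSING RSCU entries
#'   (default 0).
#' @return Numeric matrix genes x 59 with gene ids as rownames.
#' @export
rscu_matrix <- function(panel, impute_missing = 0) {
  m <- t(vapply(panel, function(cds) rscu(cds)$values,
                numeric(length(CODONS_59))))
  rownames(m) <- panel_ids(panel)
  m[is.na(m)] <- impute_missing
  m
}

#' PCA of an RSCU matrix
#'
#' Column-mean-centred, unscaled (covariance) PCA via singular value
#' decomposition. RSCU values share a common scale, so no per-codon
#' standardisation is applied. Axis signs are fixed by forcing the
#' largest-magnitude loading on each axis to be positive, making runs
#' reproducible across SVD implementations.
#'
#' @param m Numeric matrix (genes x codons), e.g. from [rscu_matrix()].
#' @return List: `variance_fraction` (percent per axis, non-increasing),
#'   `scores` (genes x axes), `loadings` (codons x axes), `center`
#'   (column means).
#' @export
pca_rscu <- function(m) {
  if (nrow(m) < 3L) stop("PCA needs at least 3 genes")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  var_frac <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(variance_fraction = var_frac, scores = scores, loadings = loadings,
       center = p$center)
}

P_STARS <- c(0.05, 0.01, 0.001, 0.0001)

significance_stars <- function(p) {
  if (is.na(p)) return("NS")
  k <- sum(p < P_STARS)
  if (k == 0) "NS" else paste(rep("*", k), collapse = "")
}

#' Pairwise Pearson correlation report
#'
#' Pearson r with a two-tailed p-value from the t distribution on n-2
#' degrees of freedom for each requested column pair; rows with a missing
#' value in either column are dropped pairwise. Significance is coded NS /
#' * / ** / *** / **** for p below 0.05 / 0.01 / 0.001 / 0.0001. A
#' Benjamini-Hochberg adjusted p column (`p_bh`) is included for reference;
#' the star codes are based on the raw p-values.
#'
#' @param table data.frame of numeric columns.
#' @param pairs `"all"` for every unordered pair, or a list of 2-element
#'   character vectors naming column pairs.
#' @return data.frame: `variable_a`, `variable_b`, `n`, `pearson_r`,
#'   `p_value`, `significance`, `p_bh`.
#' @export
correlate <- function(table, pairs = "all") {
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  if (identical(pairs, "all")) {
    cmb <- utils::combn(num_cols, 2, simplify = FALSE)
  } else {
    cmb <- pairs
  }
  rows <- lapply(cmb, function(pr) {
    x <- table[[pr[1]]]
    y <- table[[pr[2]]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) < 3L) stop("fewer than 3 complete observations for ",
                             pr[1], " vs ", pr[2])
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      return(data.frame(variable_a = pr[1], variable_b = pr[2],
                        n = length(x), pearson_r = NA_real_,
                        p_value = NA_real_, significance = "NS",
                        zero_variance = TRUE, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(variable_a = pr[1], variable_b = pr[2], n = length(x),
               pearson_r = unname(ct$estimate), p_value = ct$p.value,
               significance = significance_stars(ct$p.value),
               zero_variance = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
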