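#' Expected ENc under pure compositional constraint
#'
#' Wright's null curve: the ENc a gene would show if codon choice depended
#' only on its third-position GC content s, with no selection among
#' synonyms: ENc*(s) = 2 + s + 29 / (s^2 + (1 - s)^2). Symmetric about
#' s = 0.5 up to the small linear term; maximum near the midpoint where
#' ENc*(0.5) = 60.5.
#'
#' @param s GC3 as a fraction in \[0, 1\] (vectorised).
#' @return Expected ENc value(s).
#' @examples
#' expected_enc(0.5)
#' @export
expected_enc <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Classify genes against the ENc-GC3 null curve
#'
#' Genes on the expected curve are consistent with purely compositional
#' codon choice; genes below it use fewer codons than their GC3 predicts
#' (selection among synonyms); genes above it are attributed to mutational
#' forces. "On" is a band of +/- `tolerance` ENc units around the curve
#' since exact equality never occurs for finite genes.
#'
#' @param panel List of [coding_sequence()] objects.
#' @param tolerance Half-width of the ON band in ENc units (default 0.5).
#' @param gc3_policy `"all_codons"` (default: GC3 over every codon of the
#'   gene, terminal stop included) or `"degenerate_families"` (GC3 over
#'   codons of the 18 synonymous families only, excluding Met, Trp and the
#'   stop). The second is the composition the null curve actually models --
#'   Met and Trp have no synonymous choice yet always contribute a G -- and
#'   matters when their combined frequency is large. The policy used is
#'   recorded in the `gc3_policy` attribute of the result.
#' @param gc3_fraction Optional numeric vector overriding the computed GC3
#'   fractions.
#' @return data.frame: `gene_id`, `gc3`, `enc`, `expected_enc`, `residual`
#'   (observed - expected), `verdict` in BELOW/ABOVE/ON (NA when ENc is
#'   undefined for the gene).
#' @export
enc_gc3_assessment <- function(panel, tolerance = 0.5,
                               gc3_policy = c("all_codons",
                                              "degenerate_families"),
                               gc3_fraction = NULL) {
  gc3_policy <- match.arg(gc3_policy)
  if (is.null(gc3_fraction)) {
    if (gc3_policy == "all_codons") {
      gc3_fraction <- vapply(panel, function(cds) {
        composition_profile(cds)$GC3 / 100
      }, numeric(1))
    } else {
      gc3_fraction <- vapply(panel, function(cds) {
        cod <- sense_codon_vector(cds)
        cod <- cod[!(cod %in% c("ATG", "TGG"))]
        mean(substr(cod, 3, 3) %in% c("G", "C"))
      }, numeric(1))
    }
    policy <- gc3_policy
  } else {
    policy <- "user_supplied"
  }
  enc_obs <- vapply(panel, function(cds) enc(cds)$enc, numeric(1))
  exp_enc <- expected_enc(gc3_fraction)
  residual <- enc_obs - exp_enc
  verdict <- ifelse(is.na(residual), NA_character_,
                    ifelse(abs(residual) <= tolerance, "ON",
                           ifelse(residual < 0, "BELOW", "ABOVE")))
  out <- data.frame(gene_id = panel_ids(panel), gc3 = gc3_fraction,
                    enc = enc_obs, expected_enc = exp_enc,
                    residual = residual, verdict = verdict,
                    stringsAsFactors = FALSE)
  attr(out, "gc3_policy") <- policy
  out
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 percent (response) on GC3 percent
#' (predictor) across the genes of a panel. The slope is read as the
#' relative weight of directional mutation pressure (acting on all codon
#' positions alike) versus selection at the non-synonymous positions:
#' 100 * slope percent mutation, 100 * (1 - slope) percent selection; a
#' slope near 1 means mutational dominance, near 0 selectional dominance.
#'
#' @param profiles data.frame with columns `GC12` and `GC3` (percent), as
#'   from [panel_composition()].
#' @return List: `slope`, `intercept`, `r_squared`, `pct_mutation`,
#'   `pct_selection`, `n`.
#' @export
neutrality_fit <- function(profiles) {
  stopifnot(all(c("GC12", "GC3") %in% names(profiles)))
  ok <- stats::complete.cases(profiles[, c("GC12", "GC3")])
  d <- profiles[ok, ]
  if (nrow(d) < 3L) stop("neutrality fit needs at least 3 genes")
  if (stats::var(d$GC3) == 0) stop("GC3 has zero variance; slope undefined")
  fit <- stats::lm(GC12 ~ GC3, data = d)
  slope <- unname(stats::coef(fit)[["GC3"]])
  list(
    slope = slope,
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = summary(fit)$r.squared,
    pct_mutation = 100 * slope,
    pct_selection = 100 * (1 - slope),
    n = nrow(d)
  )
}

#' Parity-rule-2 point of a gene
#'
#' Under parity rule 2 (within-strand Chargaff), A = T and G = C at the
#' synonymous third codon position, so x = A3/(A3+T3) and y = G3/(G3+C3)
#' both sit at 0.5. Deviations reveal asymmetric mutation/selection: x < 0.5
#' with y > 0.5 reads as a preference for T and G over A and C.
#'
#' @param profile One-row data.frame from [composition_profile()] (columns
#'   `pA3`, `pT3`, `pG3`, `pC3`).
#' @return List with `x`, `y` (each `NA` when its denominator is zero).
#' @export
parity_point <- function(profile) {
  at <- profile$pA3 + profile$pT3
  gc <- profile$pG3 + profile$pC3
  list(
    x = if (at > 0) profile$pA3 / at else NA_real_,
    y = if (gc > 0) profile$pG3 / gc else NA_real_
  )
}

#' Panel parity table and summary
#'
#' @param profiles data.frame from [panel_composition()].
#' @return List: `points` (data.frame gene_id, x, y) and `summary`
#'   (mean and SD per axis over genes with defined coordinates).
#' @export
panel_parity <- function(profiles) {
  pts <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
    p <- parity_point(profiles[i, ])
    data.frame(gene_id = profiles$gene_id[i], x = p$x, y = p$y,
               stringsAsFactors = FALSE)
  }))
  list(
    points = pts,
    summary = list(
      x_mean = mean(pts$x, na.rm = TRUE), x_sd = stats::sd(pts$x, na.rm = TRUE),
      y_mean = mean(pts$y, na.rm = TRUE), y_sd = stats::sd(pts$y, na.rm = TRUE)
    )
  )
}

#' Per-nucleotide regressions of overall on third-position composition
#'
#' For each nucleotide N in A, C, G, T: OLS of overall percent N on percent
#' N at the third codon position across genes, with Pearson r and its
#' two-tailed p-value. R-squared x 100 is reported as the conventional
#' "mutational force percent" reading of these regressions.
#'
#' @param profiles data.frame from [panel_composition()].
#' @return data.frame: `nucleotide`, `slope`, `intercept`, `r_squared`, `r`,
#'   `p_value`, `mutational_force_pct`.
#' @export
third_position_regressions <- function(profiles) {
  if (nrow(profiles) < 3L) stop("needs at least 3 genes")
  rows <- lapply(c("A", "C", "G", "T"), function(b) {
    y <- profiles[[paste0("p", b)]]
    x <- profiles[[paste0("p", b, 3)]]
    if (stats::var(x) == 0) stop("zero variance in %", b, "3")
    fit <- stats::lm(y ~ x)
    ct <- stats::cor.test(x, y)
    data.frame(
      nucleotide = b,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = summary(fit)$r.squared,
      r = unname(ct$estimate),
      p_value = ct$p.value,
      mutational_force_pct = 100 * summary(fit)$r.squared,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
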