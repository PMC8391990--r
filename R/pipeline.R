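#' Configuration of a full panel study
#'
#' Collects every tunable of the pipeline with the conventional defaults:
#' RSCU over/under thresholds 1.6/0.6, dinucleotide odds thresholds
#' 1.23/0.78, instability cutoff 40, the ENc missing-class policy
#' (interpolate the three-fold class from the two- and four-fold means) and
#' the GC3 codon-inclusion policy for the null curve (all codons). The
#' resolved configuration is echoed beside every run's outputs.
#'
#' @param input Path to a FASTA file of CDS, or a [synthetic_panel_spec()].
#' @param output_dir Directory for the run's tables (created if absent).
#' @param rscu_over,rscu_under RSCU classification thresholds.
#' @param odds_over,odds_under Dinucleotide odds classification thresholds.
#' @param instability_cutoff Instability-index cutoff for the UNSTABLE label.
#' @param cai_reference `"pooled_panel"` (weights from the panel's pooled
#'   codon counts) or a precomputed [build_reference_weights()] object.
#' @param enc_on_tolerance Half-width of the ON band for the ENc-GC3 verdict.
#' @param seed Seed forwarded to synthetic generation when `input` is a spec.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, output_dir,
                       rscu_over = 1.6, rscu_under = 0.6,
                       odds_over = 1.23, odds_under = 0.78,
                       instability_cutoff = 40,
                       cai_reference = "pooled_panel",
                       enc_on_tolerance = 0.5,
                       seed = 1L) {
  structure(
    list(input = input, output_dir = output_dir,
         rscu_over = rscu_over, rscu_under = rscu_under,
         odds_over = odds_over, odds_under = odds_under,
         instability_cutoff = instability_cutoff,
         cai_reference = cai_reference,
         enc_on_tolerance = enc_on_tolerance,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the complete codon-usage study on a panel
#'
#' Loads (or generates) the panel, applies the inclusion filters, and runs
#' every stage: composition, RSCU matrix with classifications, ENc, CAI,
#' dinucleotide odds, protein indices, ENc-GC3 assessment, neutrality fit,
#' parity analysis, third-position regressions, RSCU PCA, and the
#' GC-component and protein-index correlation reports. All tables are
#' written as TSV (panel summaries as JSON) into `config$output_dir`,
#' together with the resolved configuration, a gene-level warning report and
#' a checksum manifest. Reruns with the same config and input are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`panel`,
#'   `composition`, `rscu_matrix`, `profile`, `dinucleotide`, `enc_gc3`,
#'   `neutrality`, `parity`, `third_position`, `pca`, `correlations`,
#'   `output_dir`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$output_dir
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # --- load or generate -----------------------------------------------
  if (inherits(config$input, "synthetic_panel_spec")) {
    spec <- config$input
    spec$seed <- config$seed
    gen <- generate_panel(spec)
    panel <- gen$panel
    rejected <- data.frame(gene_id = character(0), reason = character(0))
    write_synthetic_panel(gen, file.path(out, "panel.fasta"),
                          file.path(out, "panel_truth.json"))
    say("stage load: generated %d synthetic genes (seed %d)",
        length(panel), spec$seed)
  } else {
    loaded <- load_panel(config$input)
    panel <- loaded$accepted
    rejected <- loaded$rejected
    say("stage load: %d accepted, %d rejected", length(panel), nrow(rejected))
  }
  write_rejection_report(rejected, file.path(out, "rejected.tsv"))
  if (length(panel) == 0L) stop("stage load: empty accepted panel")

  # --- per-gene stages -------------------------------------------------
  comp <- panel_composition(panel)
  write_tsv(comp, out, "composition.tsv")

  rm_full <- t(vapply(panel, function(cds) rscu(cds)$values,
                      numeric(length(CODONS_59))))
  rownames(rm_full) <- panel_ids(panel)
  rscu_df <- data.frame(gene_id = rownames(rm_full), rm_full,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(rscu_df, out, "rscu_matrix.tsv")
  rscu_class <- ifelse(is.na(rm_full), "MISSING",
                       ifelse(rm_full > config$rscu_over, "OVER",
                              ifelse(rm_full < config$rscu_under, "UNDER",
                                     "RANDOM")))
  write_tsv(data.frame(gene_id = rownames(rm_full), rscu_class,
                       check.names = FALSE, stringsAsFactors = FALSE),
            out, "rscu_classification.tsv")

  enc_res <- lapply(panel, enc)
  enc_vals <- vapply(enc_res, function(e) e$enc, numeric(1))
  undef <- vapply(enc_res, function(e) !is.na(e$reason), logical(1))
  if (any(undef)) {
    say("warning: ENc undefined for %s",
        paste(panel_ids(panel)[undef], collapse = ","))
  }

  ref <- if (identical(config$cai_reference, "pooled_panel")) {
    build_reference_weights(panel, "pooled_panel")
  } else {
    config$cai_reference
  }
  write_tsv(data.frame(codon = names(ref$w),
                       amino_acid = STANDARD_CODE[names(ref$w)],
                       weight = unname(ref$w), stringsAsFactors = FALSE),
            out, "cai_reference_weights.tsv")
  cai_res <- lapply(panel, cai, ref = ref)

  prot <- panel_protein_indices(panel)
  prot$stability <- ifelse(prot$instability_index > config$instability_cutoff,
                           "UNSTABLE", "STABLE")

  dinuc <- panel_dinucleotide_odds(panel)
  write_tsv(dinuc, out, "dinucleotide_odds.tsv")

  profile <- data.frame(
    gene_id = panel_ids(panel),
    codon_count = vapply(panel, function(x) x$codon_count, integer(1)),
    GC = comp$GC, GC12 = comp$GC12, GC3 = comp$GC3,
    enc = enc_vals,
    cai59 = vapply(cai_res, function(x) x$cai59, numeric(1)),
    cai18 = vapply(cai_res, function(x) x$cai18, numeric(1)),
    stringsAsFactors = FALSE
  )
  profile <- cbind(profile, prot[, setdiff(names(prot), "gene_id")])
  write_tsv(profile, out, "gene_profile.tsv")

  # --- force attribution ----------------------------------------------
  assessment <- enc_gc3_assessment(panel, tolerance = config$enc_on_tolerance)
  write_tsv(assessment, out, "enc_gc3.tsv")
  say("stage forces: %d/%d genes below the expected ENc curve",
      sum(assessment$verdict == "BELOW", na.rm = TRUE), nrow(assessment))

  neut <- neutrality_fit(comp)
  jsonlite::write_json(neut, file.path(out, "neutrality.json"),
                       auto_unbox = TRUE, digits = NA)
  say("stage forces: neutrality slope %.4f (mutation %.2f%%, selection %.2f%%)",
      neut$slope, neut$pct_mutation, neut$pct_selection)

  parity <- panel_parity(comp)
  write_tsv(parity$points, out, "parity.tsv")
  jsonlite::write_json(parity$summary, file.path(out, "parity_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  third <- third_position_regressions(comp)
  write_tsv(third, out, "third_position_regressions.tsv")

  # --- multivariate ----------------------------------------------------
  rm0 <- rm_full
  rm0[is.na(rm0)] <- 0
  pca <- pca_rscu(rm0)
  write_tsv(data.frame(axis = seq_along(pca$variance_fraction),
                       variance_pct = pca$variance_fraction),
            out, "pca_variance.tsv")
  write_tsv(data.frame(gene_id = rownames(pca$scores), pca$scores,
                       check.names = FALSE, stringsAsFactors = FALSE),
            out, "pca_scores.tsv")
  write_tsv(data.frame(codon = rownames(pca$loadings), pca$loadings,
                       check.names = FALSE, stringsAsFactors = FALSE),
            out, "pca_loadings.tsv")
  say("stage pca: axis 1 carries %.2f%% of RSCU variance",
      pca$variance_fraction[1])

  gc_cols <- data.frame(GC = comp$GC, GC1 = comp$GC1, GC2 = comp$GC2,
                        GC12 = comp$GC12, GC3 = comp$GC3,
                        CAI59 = profile$cai59, ENc = profile$enc)
  cor_gc <- correlate(gc_cols, "all")
  write_tsv(cor_gc, out, "correlation_gc_components.tsv")

  prot_cols <- cbind(data.frame(CAI18 = profile$cai18, ENc = profile$enc),
                     prot[, c("gravy", "aroma", "pi", "aliphatic_index",
                              "hydrophobicity_pct", "instability_index",
                              "n_acidic", "n_basic", "n_neutral")])
  cor_prot <- correlate(
    prot_cols,
    pairs = unlist(lapply(c("CAI18", "ENc"), function(a) {
      lapply(setdiff(names(prot_cols), c("CAI18", "ENc")),
             function(b) c(a, b))
    }), recursive = FALSE)
  )
  write_tsv(cor_prot, out, "correlation_protein_indices.tsv")

  # --- bookkeeping ------------------------------------------------------
  cfg_lines <- c(
    sprintf("input=%s", if (inherits(config$input, "synthetic_panel_spec"))
      "synthetic_panel_spec" else config$input),
    sprintf("output_dir=%s", out),
    sprintf("rscu_over=%g", config$rscu_over),
    sprintf("rscu_under=%g", config$rscu_under),
    sprintf("odds_over=%g", config$odds_over),
    sprintf("odds_under=%g", config$odds_under),
    sprintf("instability_cutoff=%g", config$instability_cutoff),
    sprintf("cai_reference=%s", ref$reference_id),
    sprintf("enc_on_tolerance=%g", config$enc_on_tolerance),
    sprintf("gc3_policy=%s", attr(assessment, "gc3_policy")),
    sprintf("seed=%d", config$seed)
  )
  writeLines(cfg_lines, file.path(out, "resolved_config.txt"))
  writeLines(log_lines, file.path(out, "run_log.txt"))

  artifacts <- setdiff(list.files(out), "manifest.tsv")
  manifest <- data.frame(
    file = artifacts,
    md5 = unname(tools::md5sum(file.path(out, artifacts))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, out, "manifest.tsv")

  invisible(list(panel = panel, composition = comp, rscu_matrix = rm_full,
                 profile = profile, dinucleotide = dinuc,
                 enc_gc3 = assessment, neutrality = neut, parity = parity,
                 third_position = third, pca = pca,
                 correlations = list(gc_components = cor_gc,
                                     protein_indices = cor_prot),
                 output_dir = out))
}
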