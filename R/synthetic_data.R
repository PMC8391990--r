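# Static codon geometry used by the generator.
CODON_THIRD <- substr(SENSE_CODONS, 3, 3)
names(CODON_THIRD) <- SENSE_CODONS
CODON_FIRST <- substr(SENSE_CODONS, 1, 1)
names(CODON_FIRST) <- SENSE_CODONS

# GC fraction of codon positions 1+2 for every sense codon.
CODON_GC12 <- vapply(SENSE_CODONS, function(c) {
  sum(strsplit(substr(c, 1, 2), "")[[1]] %in% c("G", "C")) / 2
}, numeric(1))

count_pattern <- function(s, pattern) {
  lengths(regmatches(s, gregexpr(paste0("(?=", pattern, ")"), s,
                                 perl = TRUE)))
}
# CG / TA dinucleotides fully inside each codon.
INTERNAL_CG <- count_pattern(SENSE_CODONS, "CG")
INTERNAL_TA <- count_pattern(SENSE_CODONS, "TA")
names(INTERNAL_CG) <- names(INTERNAL_TA) <- SENSE_CODONS

#' C/G-ending preferred codons typical of mammalian coding sequences
#'
#' One codon per degenerate family, the variant favoured in GC-rich
#' mammalian genes (CTG for Leu, GCC for Ala, ...). Used as the default
#' target of the generator's selection-bias mixture.
#'
#' @return Named character vector: amino acid -> preferred codon.
#' @export
mammalian_preferred_codons <- function() {
  c(F = "TTC", L = "CTG", I = "ATC", V = "GTG", S = "AGC", P = "CCC",
    T = "ACC", A = "GCC", Y = "TAC", H = "CAC", Q = "CAG", N = "AAC",
    K = "AAG", D = "GAC", E = "GAG", C = "TGC", R = "CGC", G = "GGC")
}

#' Specification of a synthetic CDS panel
#'
#' Defines a panel with known compositional, selectional and dinucleotide
#' structure. Each gene gets a random protein (no internal stops by
#' construction), back-translated with per-family codon probabilities that
#' mix a GC3-target-driven drift component (Wright's null) with a
#' preferred-codon bias of strength `bias_strength`, followed by
#' protein-preserving synonymous resampling that thins CpG and/or TpA
#' dinucleotides.
#'
#' @param n_genes Number of genes.
#' @param length_codons_range Integer range (min, max) of amino-acid lengths
#'   sampled uniformly per gene; a terminal stop codon is appended, so the
#'   nucleotide length is 3*(L+1).
#' @param gc3_targets Either a length-2 range from which per-gene GC3
#'   targets (fractions) are sampled uniformly, or a vector of length
#'   `n_genes` of explicit targets. Under no bias (`bias_strength = 0`) the
#'   expected GC3 of a gene equals its target and the gene tracks Wright's
#'   expected ENc-GC3 curve; see [pr2_balanced_aa_freqs()] for a null that
#'   is additionally at parity-rule-2 equilibrium.
#' @param bias_strength Non-negative selection strength kappa: per family
#'   the codon distribution is (p_GC3 + kappa * indicator(preferred)) /
#'   (1 + kappa), so kappa = 0 gives pure composition-driven choice and
#'   large kappa concentrates usage on the preferred codon. Bias pulls
#'   realized GC3 away from the target; the target is honoured exactly only
#'   at kappa = 0.
#' @param preferred_codons Named map amino acid -> codon receiving the bias;
#'   default [mammalian_preferred_codons()]. Families absent from the map
#'   stay purely composition-driven.
#' @param cpg_suppression,tpa_suppression Factors in (0, 1] scaling the
#'   realized CpG (resp. TpA) odds ratio relative to the unsuppressed
#'   generator; 1 = no suppression. Enforced by calibrated Gibbs sweeps of
#'   synonymous codon resampling, so the protein is never changed.
#' @param neutrality_slope,neutrality_intercept,neutrality_noise_sd When
#'   `neutrality_slope` is not `NA`, each gene's amino-acid frequencies are
#'   exponentially tilted so its expected GC12 percent equals
#'   slope * GC3_percent + intercept + N(0, noise_sd), emulating coupled
#'   mutation pressure across codon positions.
#' @param aa_freqs Optional named base amino-acid frequencies (default
#'   uniform over the 20 standard residues).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return Object of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(n_genes = 42,
                                 length_codons_range = c(150, 3000),
                                 gc3_targets = c(0.31, 0.84),
                                 bias_strength = 0,
                                 preferred_codons = mammalian_preferred_codons(),
                                 cpg_suppression = 1,
                                 tpa_suppression = 1,
                                 neutrality_slope = NA_real_,
                                 neutrality_intercept = NA_real_,
                                 neutrality_noise_sd = 0,
                                 aa_freqs = NULL,
                                 seed = 1L) {
  stopifnot(n_genes >= 1,
            length(length_codons_range) == 2,
            length_codons_range[1] >= 2,
            length_codons_range[1] <= length_codons_range[2],
            cpg_suppression > 0, cpg_suppression <= 1,
            tpa_suppression > 0, tpa_suppression <= 1,
            bias_strength >= 0)
  if (!(length(gc3_targets) %in% c(2L, n_genes))) {
    stop("gc3_targets must be a length-2 range or one value per gene")
  }
  stopifnot(all(gc3_targets >= 0 & gc3_targets <= 1))
  if (is.null(aa_freqs)) {
    aa_freqs <- stats::setNames(rep(1 / 20, 20), AA20)
  } else {
    stopifnot(all(names(aa_freqs) %in% AA20), all(aa_freqs >= 0),
              sum(aa_freqs) > 0)
    full <- stats::setNames(rep(0, 20), AA20)
    full[names(aa_freqs)] <- aa_freqs
    aa_freqs <- full / sum(full)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         length_codons_range = as.integer(length_codons_range),
         gc3_targets = gc3_targets,
         bias_strength = bias_strength,
         preferred_codons = preferred_codons,
         cpg_suppression = cpg_suppression,
         tpa_suppression = tpa_suppression,
         neutrality_slope = neutrality_slope,
         neutrality_intercept = neutrality_intercept,
         neutrality_noise_sd = neutrality_noise_sd,
         aa_freqs = aa_freqs,
         seed = as.integer(seed)),
    class = "synthetic_panel_spec"
  )
}

# Codon distribution of the compositional-drift null at third-position GC
# weight t: within every family, mass t is split equally over its G/C-ending
# codons and (1 - t) over its A/T-ending codons (all mass to the only class
# present when a family lacks one). This reproduces Wright's null -- a
# common third-base marginal across families -- so drift genes track the
# expected ENc-GC3 curve, and makes the family-level expected GC3 equal t
# exactly for every family with both ending classes (including Ile).
null_family_probs <- function(t) {
  probs <- list()
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    gc <- CODON_THIRD[fam] %in% c("C", "G")
    p <- numeric(length(fam))
    if (any(gc) && any(!gc)) {
      p[gc] <- t / sum(gc)
      p[!gc] <- (1 - t) / sum(!gc)
    } else {
      p[] <- 1 / length(fam)
    }
    probs[[aa]] <- stats::setNames(p, fam)
  }
  probs
}

# Gene-level GC3 equals the target after compensating the G forced at the
# third position of Met and Trp codons. Infeasible targets (below the
# Met/Trp floor) error.
solve_null_probs <- function(t, aa_freqs) {
  f_mw <- sum(aa_freqs[c("M", "W")])
  if (t < f_mw - 0.02) {
    stop(sprintf(paste0("infeasible constraints: gc3_target %.3f below the ",
                        "Met/Trp GC3 floor %.3f implied by aa_freqs"),
                 t, f_mw))
  }
  t_eff <- min(max((t - f_mw) / (1 - f_mw), 0), 1)
  null_family_probs(t_eff)
}

#' Amino-acid frequencies at parity-rule-2 equilibrium
#'
#' Uniform amino-acid usage leaves the genetic code's third positions
#' unbalanced even under uniform codon choice (six 2-fold families end in
#' T/C but only three in A/G), so an unbiased panel sits near x = 0.43 on
#' the PR2 plot. This composition restricts to families whose third-base
#' contributions cancel -- the three T/C-ending and three A/G-ending 2-fold
#' pairs, the five 4-fold families, and Leu + Ser (whose 6-fold asymmetries
#' are opposite) -- so a no-force panel generated from it has expected
#' A3 = T3 and G3 = C3 at any GC3 target. Useful for calibrating parity
#' analyses against a true PR2-equilibrium null.
#'
#' @return Named numeric vector of amino-acid frequencies (uniform over 13
#'   residues).
#' @export
pr2_balanced_aa_freqs <- function() {
  aas <- c("F", "Y", "H", "Q", "K", "E", "V", "P", "T", "A", "G", "L", "S")
  stats::setNames(rep(1 / length(aas), length(aas)), aas)
}

# Mix base codon probabilities with the preferred-codon bias of strength
# kappa.
family_codon_probs <- function(base_probs, kappa, preferred) {
  probs <- list()
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    p <- base_probs[[aa]]
    pref <- if (!is.null(preferred) && aa %in% names(preferred)) {
      preferred[[aa]]
    } else {
      NA_character_
    }
    if (kappa > 0 && !is.na(pref) && pref %in% fam) {
      p <- p / (1 + kappa)
      p[pref] <- p[pref] + kappa / (1 + kappa)
    }
    probs[[aa]] <- p
  }
  probs
}

# Expected GC3 fraction of a gene under given per-family codon
# probabilities and amino-acid frequencies.
expected_gc3 <- function(codon_probs, aa_freqs) {
  per_aa <- vapply(names(aa_freqs), function(aa) {
    p <- codon_probs[[aa]]
    sum(p[CODON_THIRD[names(p)] %in% c("C", "G")])
  }, numeric(1))
  sum(aa_freqs * per_aa)
}

# Exponential tilt of amino-acid frequencies so the expected GC12 fraction
# (averaged over the per-family codon distribution) matches the target.
tilt_aa_freqs <- function(base, target_gc12, codon_probs) {
  g <- vapply(names(base), function(aa) {
    p <- codon_probs[[aa]]
    sum(p * CODON_GC12[names(p)])
  }, numeric(1))
  active <- base > 0
  lo <- min(g[active])
  hi <- max(g[active])
  target <- min(max(target_gc12, lo + 0.005), hi - 0.005)
  mean_g <- function(lambda) {
    w <- base * exp(lambda * g)
    sum(w * g) / sum(w)
  }
  root <- stats::uniroot(function(l) mean_g(l) - target, lower = -80,
                         upper = 80, tol = 1e-9)
  w <- base * exp(root$root * g)
  w / sum(w)
}

# One Gibbs sweep of protein-preserving synonymous resampling targeting
# pi(codons) proportional to prod p(c_i) * w_cg^(#CG) * w_ta^(#TA), where
# the dinucleotide counts include codon-internal and codon-boundary pairs.
suppression_sweep <- function(codons, protein, codon_probs, w_cg, w_ta,
                              stop_codon) {
  n <- length(codons)
  for (i in seq_len(n)) {
    fam <- SYN_FAMILIES[[protein[i]]]
    if (length(fam) == 1L) next
    left <- if (i == 1L) "" else substr(codons[i - 1L], 3, 3)
    right <- if (i == n) substr(stop_codon, 1, 1) else CODON_FIRST[[codons[i + 1L]]]
    n_cg <- INTERNAL_CG[fam] +
      (left == "C") * (CODON_FIRST[fam] == "G") +
      (CODON_THIRD[fam] == "C") * (right == "G")
    n_ta <- INTERNAL_TA[fam] +
      (left == "T") * (CODON_FIRST[fam] == "A") +
      (CODON_THIRD[fam] == "T") * (right == "A")
    w <- codon_probs[[protein[i]]] * w_cg^n_cg * w_ta^n_ta
    codons[i] <- sample(fam, 1L, prob = w)
  }
  codons
}

mean_rho <- function(codons, stop_codon, dinuc) {
  seq <- paste(c(codons, stop_codon), collapse = "")
  unname(dinucleotide_odds(seq)$rho[dinuc])
}

# Apply calibrated CpG/TpA suppression to one gene: Gibbs weights are tuned
# so the realized odds ratio is s times the gene's unsuppressed odds ratio.
# (Synonymous swaps shift mononucleotide frequencies too, so the Gibbs
# penalty w is not itself the realized odds-ratio factor; a short
# multiplicative-update loop closes the gap.)
apply_suppression <- function(codons, protein, codon_probs, s_cg, s_ta,
                              stop_codon, max_rounds = 5, tol = 0.02) {
  rho0_cg <- mean_rho(codons, stop_codon, "CG")
  rho0_ta <- mean_rho(codons, stop_codon, "TA")
  target_cg <- s_cg * rho0_cg
  target_ta <- s_ta * rho0_ta
  w_cg <- s_cg
  w_ta <- s_ta
  out <- codons
  for (round in seq_len(max_rounds)) {
    out <- suppression_sweep(out, protein, codon_probs, w_cg, w_ta,
                             stop_codon)
    out <- suppression_sweep(out, protein, codon_probs, w_cg, w_ta,
                             stop_codon)
    err_cg <- if (s_cg < 1) mean_rho(out, stop_codon, "CG") / target_cg else 1
    err_ta <- if (s_ta < 1) mean_rho(out, stop_codon, "TA") / target_ta else 1
    if (abs(err_cg - 1) < tol && abs(err_ta - 1) < tol) break
    if (s_cg < 1) w_cg <- max(1e-4, min(1, w_cg / err_cg^1.5))
    if (s_ta < 1) w_ta <- max(1e-4, min(1, w_ta / err_ta^1.5))
  }
  out
}

#' Generate a synthetic CDS panel
#'
#' Draws the panel defined by a [synthetic_panel_spec()]: per gene, a random
#' protein of sampled length; drift codon probabilities with a common
#' third-base marginal across families, compensated for the G forced by
#' Met/Trp so the gene's expected GC3 equals its target; optional
#' preferred-codon bias;
#' optional amino-acid tilt tying expected GC12 to GC3 (neutrality
#' structure); and, when suppression factors are below 1, calibrated Gibbs
#' sweeps of synonymous resampling that scale the CpG/TpA odds ratios by the
#' requested factors without ever changing the protein. A terminal stop
#' codon is appended to every gene. Output is a pure function of the spec
#' (the seed drives a private RNG stream; the caller's RNG state is
#' untouched).
#'
#' @param spec A [synthetic_panel_spec()].
#' @return List: `panel` (list of [coding_sequence()]), `truth` (data.frame
#'   of per-gene targets and realized values: `gene_id`, `length_codons`,
#'   `gc3_target`, `gc12_target`, `realized_gc3`, `realized_gc12`) and
#'   `spec`.
#' @examples
#' out <- generate_panel(synthetic_panel_spec(n_genes = 5,
#'   length_codons_range = c(100, 200), seed = 7))
#' out$truth$realized_gc3
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_genes
  len_range <- spec$length_codons_range[1]:spec$length_codons_range[2]
  lens <- len_range[sample.int(length(len_range), n, replace = TRUE)]
  targets <- if (length(spec$gc3_targets) == 2L) {
    stats::runif(n, spec$gc3_targets[1], spec$gc3_targets[2])
  } else {
    spec$gc3_targets
  }
  gc12_noise <- if (!is.na(spec$neutrality_slope)) {
    stats::rnorm(n, 0, spec$neutrality_noise_sd)
  } else {
    rep(NA_real_, n)
  }
  gc12_targets <- rep(NA_real_, n)

  panel <- vector("list", n)
  realized_gc3 <- realized_gc12 <- numeric(n)
  for (i in seq_len(n)) {
    aa_f <- spec$aa_freqs
    base <- solve_null_probs(targets[i], aa_f)
    probs <- family_codon_probs(base, spec$bias_strength,
                                spec$preferred_codons)
    if (!is.na(spec$neutrality_slope)) {
      # GC12 is tied to the gene's expected realized GC3 under the full
      # codon mixture (equal to the target when bias_strength = 0, shifted
      # toward the preferred codons otherwise). The amino-acid tilt changes
      # the composition the third-base weights were solved for, so one
      # re-solve/re-tilt round removes most of the coupling (Leu/Ser/Arg
      # codon choice links positions 1-2 to 3).
      e_gc3 <- expected_gc3(probs, aa_f)
      gc12_targets[i] <- (spec$neutrality_slope * 100 * e_gc3 +
                            spec$neutrality_intercept + gc12_noise[i]) / 100
      aa_f <- tilt_aa_freqs(aa_f, gc12_targets[i], probs)
      base <- solve_null_probs(targets[i], aa_f)
      probs <- family_codon_probs(base, spec$bias_strength,
                                  spec$preferred_codons)
      e_gc3 <- expected_gc3(probs, aa_f)
      gc12_targets[i] <- (spec$neutrality_slope * 100 * e_gc3 +
                            spec$neutrality_intercept + gc12_noise[i]) / 100
      aa_f <- tilt_aa_freqs(spec$aa_freqs, gc12_targets[i], probs)
    }
    protein <- sample(AA20, lens[i], replace = TRUE, prob = aa_f)
    codons <- character(lens[i])
    for (aa in unique(protein)) {
      idx <- which(protein == aa)
      p <- probs[[aa]]
      codons[idx] <- if (length(p) == 1L) names(p) else {
        sample(names(p), length(idx), replace = TRUE, prob = p)
      }
    }
    stop_codon <- sample(STOP_CODONS, 1L)
    if (spec$cpg_suppression < 1 || spec$tpa_suppression < 1) {
      codons <- apply_suppression(codons, protein, probs,
                                  spec$cpg_suppression,
                                  spec$tpa_suppression, stop_codon)
    }
    cds <- coding_sequence(sprintf("synth%04d", i),
                           paste(c(codons, stop_codon), collapse = ""))
    prof <- composition_profile(cds)
    realized_gc3[i] <- prof$GC3 / 100
    realized_gc12[i] <- prof$GC12 / 100
    panel[[i]] <- cds
  }
  list(
    panel = panel,
    truth = data.frame(
      gene_id = panel_ids(panel),
      length_codons = lens,
      gc3_target = targets,
      gc12_target = gc12_targets,
      realized_gc3 = realized_gc3,
      realized_gc12 = realized_gc12,
      stringsAsFactors = FALSE
    ),
    spec = spec
  )
}

#' Write a synthetic panel as FASTA plus ground-truth JSON
#'
#' @param generated Output of [generate_panel()].
#' @param fasta_path,truth_path Output file paths.
#' @return Invisible list of the two paths.
#' @export
write_synthetic_panel <- function(generated, fasta_path, truth_path) {
  write_panel(generated$panel, fasta_path)
  truth <- list(
    spec = generated$spec[setdiff(names(generated$spec), "aa_freqs")],
    aa_freqs = as.list(generated$spec$aa_freqs),
    genes = generated$truth
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(fasta = fasta_path, truth = truth_path))
}
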