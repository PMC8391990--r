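# A gene as a codon-count recipe keeps expected values auditable.
cds_from_codons <- function(...) {
  coding_sequence("toy", paste(c(...), collapse = ""))
}

test_that("RSCU matches hand-evaluated examples and thresholds", {
  # sole codon of the 6-fold Leu family
  r <- rscu(cds_from_codons(rep("CTG", 4)))
  expect_equal(unname(r$values["CTG"]), 6)
  expect_equal(unname(r$classification["CTG"]), "OVER")
  expect_equal(unname(r$values["CTT"]), 0)
  expect_equal(unname(r$classification["CTT"]), "UNDER")

  # Leu {CTG:2, CTT:1}: RSCU(CTG) = 2/(3/6) = 4, RSCU(CTT) = 2
  r <- rscu(cds_from_codons("CTG", "CTG", "CTT"))
  expect_equal(unname(r$values[c("CTG", "CTT", "CTA", "TTA")]), c(4, 2, 0, 0))

  # uniform usage within a family -> RSCU 1, RANDOM
  r <- rscu(cds_from_codons("GGT", "GGC", "GGA", "GGG"))
  expect_equal(unname(r$values[c("GGT", "GGC", "GGA", "GGG")]), rep(1, 4))
  expect_equal(unname(r$classification["GGT"]), "RANDOM")

  # absent amino acid -> MISSING, not zero
  expect_true(is.na(r$values["AAA"]))
  expect_equal(unname(r$classification["AAA"]), "MISSING")

  # thresholds are strict inequalities at exactly 1.6 and 0.6:
  # Phe {TTT:4, TTC:1}: RSCU(TTT) = 1.6 -> RANDOM; {TTT:3, TTC:7}:
  # RSCU(TTT) = 0.6 -> RANDOM
  r <- rscu(cds_from_codons(rep("TTT", 4), "TTC"))
  expect_equal(unname(r$values["TTT"]), 1.6)
  expect_equal(unname(r$classification["TTT"]), "RANDOM")
  r <- rscu(cds_from_codons(rep("TTT", 3), rep("TTC", 7)))
  expect_equal(unname(r$values["TTT"]), 0.6)
  expect_equal(unname(r$classification["TTT"]), "RANDOM")
})

test_that("RSCU family sums equal degeneracy and match seqinr on random genes", {
  set.seed(11)
  fams <- split(names(codonpanel:::STANDARD_CODE),
                codonpanel:::STANDARD_CODE)
  fams <- fams[!(names(fams) %in% c("*", "M", "W"))]
  for (i in 1:20) {
    cds <- random_cds(sample(20:300, 1))
    vals <- rscu(cds)$values
    for (aa in names(fams)) {
      fam_vals <- vals[fams[[aa]]]
      if (all(is.na(fam_vals))) next
      expect_equal(sum(fam_vals), length(fams[[aa]]), tolerance = 1e-9)
    }
    # independent cross-check against seqinr::uco (it reports 0, not NA,
    # for absent families, so compare only where defined)
    uco <- seqinr::uco(seqinr::s2c(paste(
      codonpanel:::sense_codon_vector(cds), collapse = "")), index = "rscu")
    names(uco) <- toupper(names(uco))
    defined <- !is.na(vals)
    expect_equal(vals[defined], uco[names(vals)[defined]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("ENc hits both theoretical limits", {
  # one codon per degenerate family, each used twice -> maximal bias, 20
  one_each <- unlist(lapply(codonpanel:::SYN_FAMILIES, function(f) {
    rep(f[1], 2)
  }))
  expect_equal(enc(cds_from_codons(one_each))$enc, 20)
  # every codon of every family equally often -> no bias, 61
  all_equal <- unlist(lapply(codonpanel:::SYN_FAMILIES, function(f) {
    rep(f, 25)
  }))
  expect_equal(enc(cds_from_codons(all_equal))$enc, 61)
})

test_that("ENc equals the brute-force estimator on random genes", {
  set.seed(23)
  for (i in 1:15) {
    cds <- random_cds(300)
    expect_equal(enc(cds)$enc, oracle_enc(cds$seq), tolerance = 1e-6)
  }
})

test_that("ENc missing-class rules work", {
  # no Ile: F-bar_3 interpolated as (F2+F4)/2; all other classes present
  no_ile <- unlist(lapply(codonpanel:::SYN_FAMILIES[
    setdiff(names(codonpanel:::SYN_FAMILIES), c("I", "M", "W"))],
    function(f) rep(f, 2)))
  e <- enc(cds_from_codons(no_ile))
  expect_false(is.na(e$enc))
  expect_equal(e$family_means[["3"]],
               (e$family_means[["2"]] + e$family_means[["4"]]) / 2)
  # amino acids with a single occurrence are excluded: a gene with only
  # n=1 families in the 6-fold class has no usable 6-fold family
  e <- enc(cds_from_codons(rep("TTT", 2), rep("ATT", 2), rep("GGT", 2),
                           "CTG"))
  expect_true(is.na(e$enc))
  expect_match(e$reason, "degeneracy 6")
})

test_that("reference weights follow pooled RSCU ratios", {
  # uniform pooled counts -> every codon is its family maximum, w = 1
  uniform_counts <- setNames(rep(10, length(codonpanel:::SENSE_CODONS)),
                             codonpanel:::SENSE_CODONS)
  w <- build_reference_weights(uniform_counts)$w
  expect_true(all(abs(w - 1) < 1e-12))

  # two-gene toy panel, hand-computed: pooled Phe counts TTT=3, TTC=1
  # -> w(TTT)=1, w(TTC)=1/3; pooled Gly GGT=2,GGC=2 -> both 1
  panel <- list(cds_from_codons(rep("TTT", 2), "TTC", "GGT", "GGC"),
                cds_from_codons("TTT", "GGT", "GGC"))
  w <- build_reference_weights(panel)$w
  expect_equal(unname(w["TTT"]), 1)
  expect_equal(unname(w["TTC"]), 1 / 3)
  expect_equal(unname(w[c("GGT", "GGC")]), c(1, 1))
  # zero-count codon gets 0.5/(family total), small but positive
  expect_equal(unname(w["GGA"]), 0.5 / 4)
  expect_true(all(w > 0 & w <= 1))
  # families absent from the reference are uninformative: w = 1 throughout
  expect_equal(unname(w[c("CTG", "CTT", "AAA")]), rep(1, 3))
  # every family carries at least one w = 1
  for (aa in names(codonpanel:::SYN_FAMILIES)) {
    fam <- codonpanel:::SYN_FAMILIES[[aa]]
    if (length(fam) > 1) expect_equal(max(w[fam]), 1)
  }
  expect_error(build_reference_weights(list()), "empty")
})

test_that("CAI59 and CAI18 match hand-computed geometric means", {
  uniform_counts <- setNames(rep(10, length(codonpanel:::SENSE_CODONS)),
                             codonpanel:::SENSE_CODONS)
  ref <- build_reference_weights(uniform_counts, "uniform")
  # uniform reference: every codon has w=1 -> CAI = 1 whatever the gene
  res <- cai(random_cds(100), ref)
  expect_equal(res$cai59, 1)
  expect_equal(res$cai18, 1)
  expect_equal(res$reference_id, "uniform")

  # single-family gene with w(CTG)=1, w(CTT)=0.5: both CAI = sqrt(0.5)
  ref2 <- ref
  ref2$w["CTT"] <- 0.5
  res <- cai(cds_from_codons("CTG", "CTT"), ref2)
  expect_equal(res$cai59, sqrt(0.5))
  expect_equal(res$cai18, sqrt(0.5))

  # CAI18 weighs families equally while CAI59 weighs occurrences:
  # 9 x CTG (w=1) + 1 x TTT with w(TTT)=0.25
  ref3 <- ref
  ref3$w["TTT"] <- 0.25
  res <- cai(cds_from_codons(rep("CTG", 9), "TTT"), ref3)
  expect_equal(res$cai59, 0.25^(1 / 10))
  expect_equal(res$cai18, (1 + 0.25) / 2)

  # Met/Trp-only gene is undefined
  res <- cai(cds_from_codons("ATG", "TGG"), ref)
  expect_true(is.na(res$cai59))
})

test_that("replacing a codon with a higher-weight synonym never lowers CAI59", {
  set.seed(41)
  panel <- lapply(1:5, function(i) random_cds(150, paste0("g", i)))
  ref <- build_reference_weights(panel)
  for (i in 1:10) {
    cds <- random_cds(60)
    base <- cai(cds, ref)$cai59
    codons <- codonpanel:::split_codons(cds$seq)
    j <- sample(seq_along(codons), 1)
    aa <- codonpanel:::STANDARD_CODE[[codons[j]]]
    if (aa %in% c("M", "W", "*")) next
    fam <- codonpanel:::SYN_FAMILIES[[aa]]
    better <- fam[ref$w[fam] >= ref$w[codons[j]]]
    codons[j] <- better[which.max(ref$w[better])]
    upgraded <- cai(coding_sequence("up", paste(codons, collapse = "")), ref)
    expect_gte(upgraded$cai59 + 1e-12, base)
  }
})
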