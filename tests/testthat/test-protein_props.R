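test_that("translation follows the standard code and drops the terminal stop", {
  expect_equal(translate_cds(coding_sequence("a", "ATGAAATAA")), "MK")
  expect_equal(translate_cds(coding_sequence("b", "ATG")), "M")
  # cross-check against seqinr on random genes
  set.seed(3)
  for (i in 1:10) {
    cds <- random_cds(sample(10:100, 1), with_stop = (i %% 2 == 0))
    ours <- translate_cds(cds)
    ref <- paste(seqinr::translate(seqinr::s2c(cds$seq)), collapse = "")
    ref <- sub("\\*$", "", ref)
    expect_equal(ours, ref)
  }
})

test_that("single-residue limits of the published scales are exact", {
  p <- protein_indices("IIII")
  expect_equal(p$gravy, 4.5)           # Kyte-Doolittle maximum
  expect_equal(p$aliphatic_index, 390) # 100 * 3.9 for pure Ile
  expect_equal(p$aroma, 0)
  expect_equal(protein_indices("RRRR")$gravy, -4.5)
  p <- protein_indices("FYW")
  expect_equal(p$aroma, 1)
  expect_equal(p$n_neutral, 3)
  p <- protein_indices("DKE")
  expect_equal(c(p$n_acidic, p$n_basic, p$n_neutral), c(2, 1, 0))
  expect_equal(p$n_acidic + p$n_basic + p$n_neutral, p$length_aa)
})

test_that("indices reproduce independent reference values", {
  # frozen from Biopython ProtParam (same Kyte-Doolittle and Guruprasad
  # DIWV tables)
  cases <- list(
    list(seq = "MKWVTFISLLLLFSSAYS", gravy = 1.288889, aroma = 4 / 18,
         instab = 17.566667),
    list(seq = "ACDEFGHIKLMNPQRSTVWY", gravy = -0.49, aroma = 3 / 20,
         instab = 84.74),
    list(seq = "GGGG", gravy = -0.4, aroma = 0, instab = 100.05),
    list(seq = "IRAQDDVV", gravy = -0.0375, aroma = 0, instab = 32.825)
  )
  for (cs in cases) {
    p <- protein_indices(cs$seq)
    expect_equal(p$gravy, cs$gravy, tolerance = 1e-5)
    expect_equal(p$aroma, cs$aroma, tolerance = 1e-9)
    expect_equal(p$instability_index, cs$instab, tolerance = 1e-5)
  }
})

test_that("the isoelectric point is a root of the charge function", {
  set.seed(29)
  for (i in 1:8) {
    prot <- paste(sample(codonpanel:::AA20, 60, replace = TRUE),
                  collapse = "")
    pi <- isoelectric_point(prot)
    expect_lt(abs(protein_charge(prot, pi)), 0.01)
    # charge is decreasing in pH around the root
    expect_gt(protein_charge(prot, pi - 1), protein_charge(prot, pi + 1))
  }
  # acidic proteins have lower pI than basic ones
  expect_lt(isoelectric_point("DDEEDDEE"), isoelectric_point("KKRRKKRR"))
})

test_that("composition indices are permutation-invariant, instability is not", {
  set.seed(37)
  prot <- paste(sample(codonpanel:::AA20, 80, replace = TRUE), collapse = "")
  shuffled <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
  a <- protein_indices(prot)
  b <- protein_indices(shuffled)
  for (f in c("gravy", "aroma", "pi", "aliphatic_index",
              "hydrophobicity_pct", "n_acidic", "n_basic", "n_neutral")) {
    expect_equal(a[[f]], b[[f]])
  }
  # order sensitivity of the dipeptide statistic: reversing a sequence with
  # asymmetric DIWV weights changes the value
  expect_false(isTRUE(all.equal(
    protein_indices("DGGPC")$instability_index,
    protein_indices("CPGGD")$instability_index)))
})

test_that("stability label flips at instability 40", {
  expect_equal(protein_indices("GGGG")$stability, "UNSTABLE")   # 100.05
  expect_equal(protein_indices("MKWVTFISLLLLFSSAYS")$stability, "STABLE")
})

test_that("non-standard residues are rejected with their position", {
  expect_error(protein_indices("MKXK"), "position 3")
  expect_error(protein_indices(""), "empty")
})

test_that("hydrophobicity percent uses the configurable residue set", {
  expect_equal(protein_indices("AILV")$hydrophobicity_pct, 100)
  expect_equal(protein_indices("ADKE")$hydrophobicity_pct, 25)
  expect_equal(protein_indices("AILV",
                               hydrophobic_set = c("D"))$hydrophobicity_pct, 0)
})
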