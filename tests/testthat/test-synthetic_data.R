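test_that("every generated gene passes the panel inclusion filters", {
  g <- generate_panel(synthetic_panel_spec(n_genes = 15,
                                           length_codons_range = c(50, 200),
                                           seed = 2))
  fa <- tempfile(fileext = ".fasta")
  write_panel(g$panel, fa)
  back <- load_panel(fa)
  expect_equal(nrow(back$rejected), 0)
  expect_equal(length(back$accepted), 15)
})

test_that("generation is a pure function of the spec seed", {
  spec <- synthetic_panel_spec(n_genes = 5, length_codons_range = c(80, 120),
                               cpg_suppression = 0.7, seed = 10)
  fa1 <- tempfile(); fa2 <- tempfile(); fa3 <- tempfile()
  write_panel(generate_panel(spec)$panel, fa1)
  write_panel(generate_panel(spec)$panel, fa2)
  spec$seed <- 11L
  write_panel(generate_panel(spec)$panel, fa3)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_false(identical(readLines(fa1), readLines(fa3)))
  # the caller's RNG stream is not consumed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_panel(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("realized GC3 tracks its target within 3 points at 1000+ codons", {
  g <- generate_panel(synthetic_panel_spec(
    n_genes = 12, length_codons_range = c(1000, 1500),
    gc3_targets = c(0.31, 0.84), bias_strength = 0, seed = 6))
  expect_true(all(abs(g$truth$realized_gc3 - g$truth$gc3_target) < 0.03))
})

test_that("strong preferred-codon bias makes the preferred codon OVER", {
  g <- generate_panel(synthetic_panel_spec(
    n_genes = 20, length_codons_range = c(200, 400), bias_strength = 30,
    seed = 8))
  ctg <- vapply(g$panel, function(x) rscu(x)$classification[["CTG"]],
                character(1))
  expect_gte(mean(ctg == "OVER"), 0.95)
})

test_that("realized CpG odds decrease monotonically in the suppression factor", {
  rho_at <- function(s) {
    g <- generate_panel(synthetic_panel_spec(
      n_genes = 4, length_codons_range = c(700, 900),
      gc3_targets = c(0.5, 0.5), cpg_suppression = s, seed = 12))
    mean(vapply(g$panel, function(x) dinucleotide_odds(x)$rho[["CG"]],
                numeric(1)))
  }
  r <- vapply(c(0.3, 0.6, 1), rho_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("infeasible GC3 targets raise an error naming the conflict", {
  expect_error(generate_panel(synthetic_panel_spec(
    n_genes = 2, length_codons_range = c(50, 60), gc3_targets = c(0, 0),
    seed = 1)), "infeasible.*Met/Trp")
  # feasible when Met and Trp are absent from the proteins
  aaf <- setNames(rep(1, 18), setdiff(codonpanel:::AA20, c("M", "W")))
  g <- generate_panel(synthetic_panel_spec(
    n_genes = 2, length_codons_range = c(200, 200), gc3_targets = c(0.02, 0.02),
    aa_freqs = aaf, seed = 1))
  expect_lt(mean(g$truth$realized_gc3), 0.05)
})

test_that("ground-truth JSON round-trips the per-gene targets", {
  g <- generate_panel(synthetic_panel_spec(n_genes = 4,
                                           length_codons_range = c(60, 90),
                                           seed = 3))
  fa <- tempfile(fileext = ".fasta")
  js <- tempfile(fileext = ".json")
  write_synthetic_panel(g, fa, js)
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(truth$genes$gene_id, g$truth$gene_id)
  expect_equal(truth$genes$gc3_target, g$truth$gc3_target)
  expect_equal(truth$spec$seed, 3)
})

test_that("supplied amino-acid frequencies shape the proteins", {
  aaf <- setNames(c(0.5, 0.5), c("K", "L"))
  g <- generate_panel(synthetic_panel_spec(
    n_genes = 3, length_codons_range = c(300, 300), gc3_targets = c(0.5, 0.5),
    aa_freqs = aaf, seed = 4))
  prots <- vapply(g$panel, translate_cds, character(1))
  expect_true(all(grepl("^[KL]+$", prots)))
})
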