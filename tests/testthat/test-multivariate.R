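test_that("PCA handles the rank-1 case and duplication invariance", {
  m <- matrix(1, nrow = 6, ncol = 5)
  m[, 3] <- c(1, 2, 3, 4, 5, 6)   # only one column varies
  p <- pca_rscu(m)
  expect_equal(p$variance_fraction[1], 100)
  expect_equal(unname(abs(p$loadings[3, 1])), 1, tolerance = 1e-9)
  expect_equal(unname(abs(p$loadings[-3, 1])), rep(0, 4), tolerance = 1e-9)
  # sign convention: the largest-magnitude loading on each axis is positive
  expect_gt(p$loadings[3, 1], 0)

  # duplicating every gene row leaves variance fractions unchanged
  set.seed(2)
  m <- matrix(rnorm(8 * 6), 8, 6)
  expect_equal(pca_rscu(rbind(m, m))$variance_fraction,
               pca_rscu(m)$variance_fraction, tolerance = 1e-9)
})

test_that("PCA variance fractions match the eigendecomposition oracle", {
  set.seed(8)
  m <- matrix(runif(5 * 6), 5, 6)
  p <- pca_rscu(m)
  o <- oracle_pca_varfrac(m)
  expect_equal(p$variance_fraction[1:4], o[1:4], tolerance = 1e-6)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_equal(sum(p$variance_fraction), 100, tolerance = 1e-9)
})

test_that("scores and loadings reconstruct the input matrix", {
  set.seed(14)
  m <- matrix(rnorm(10 * 7), 10, 7)
  p <- pca_rscu(m)
  rec <- p$scores %*% t(p$loadings) + rep(1, 10) %o% p$center
  expect_equal(unname(rec), unname(m), tolerance = 1e-8)
})

test_that("rscu_matrix imputes missing families and keeps gene order", {
  panel <- list(coding_sequence("g1", "CTGCTGTTTTAA"),
                coding_sequence("g2", "GGTGGCGGA"),
                coding_sequence("g3", "AAAAAGCTG"))
  m <- rscu_matrix(panel)
  expect_equal(rownames(m), c("g1", "g2", "g3"))
  expect_equal(ncol(m), 59)
  expect_equal(unname(m["g2", "CTG"]), 0)  # Leu absent from g2 -> imputed
  expect_equal(unname(m["g1", "CTG"]), 6)
})

test_that("correlation report matches the t-distribution oracle", {
  set.seed(21)
  x <- rnorm(40)
  tab <- data.frame(x = x, y = 2 * x + 1, z = rnorm(40), w = -x)
  rep <- correlate(tab, "all")
  get <- function(a, b) rep[rep$variable_a == a & rep$variable_b == b, ]
  expect_equal(get("x", "y")$pearson_r, 1, tolerance = 1e-12)
  expect_lt(get("x", "y")$p_value, 1e-12)
  expect_equal(get("x", "y")$significance, "****")
  expect_equal(get("x", "w")$pearson_r, -1, tolerance = 1e-12)
  o <- oracle_pearson(tab$x, tab$z)
  expect_equal(get("x", "z")$pearson_r, o$r, tolerance = 1e-6)
  expect_equal(get("x", "z")$p_value, o$p, tolerance = 1e-6)
})

test_that("correlation is invariant to affine rescaling and drops NA pairwise", {
  set.seed(25)
  tab <- data.frame(a = rnorm(30), b = rnorm(30))
  r1 <- correlate(tab, list(c("a", "b")))$pearson_r
  tab2 <- data.frame(a = 100 * tab$a - 3, b = tab$b / 7 + 2)
  expect_equal(correlate(tab2, list(c("a", "b")))$pearson_r, r1,
               tolerance = 1e-12)
  tab$a[1:5] <- NA
  rep <- correlate(tab, list(c("a", "b")))
  expect_equal(rep$n, 25)
  # zero-variance column flagged, not an error
  tab$c <- 1
  rep <- correlate(data.frame(a = rnorm(10), c = rep(1, 10)),
                   list(c("a", "c")))
  expect_true(is.na(rep$pearson_r))
  expect_true(rep$zero_variance)
  expect_equal(rep$significance, "NS")
})

test_that("null correlations are small and significance stars map p thresholds", {
  set.seed(33)
  x <- rnorm(1000)
  y <- rnorm(1000)
  rep <- correlate(data.frame(x = x, y = y), list(c("x", "y")))
  expect_lt(abs(rep$pearson_r), 0.1)
  expect_equal(codonpanel:::significance_stars(0.2), "NS")
  expect_equal(codonpanel:::significance_stars(0.04), "*")
  expect_equal(codonpanel:::significance_stars(0.005), "**")
  expect_equal(codonpanel:::significance_stars(5e-4), "***")
  expect_equal(codonpanel:::significance_stars(5e-5), "****")
})
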