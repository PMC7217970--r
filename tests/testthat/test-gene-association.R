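test_that("snpChisq inverts the 1-df chi-square survival function", {
  expect_equal(snpChisq(1), 0)
  # oracle: numeric inversion of the chi-square survival function
  oracle <- function(p) uniroot(function(x)
    pchisq(x, 1, lower.tail = FALSE) - p, c(0, 100), tol = 1e-12)$root
  expect_equal(snpChisq(0.3173), oracle(0.3173), tolerance = 1e-8)
  expect_equal(snpChisq(0.05), oracle(0.05), tolerance = 1e-8)
  expect_equal(round(snpChisq(0.05), 4), 3.8415)
  # monotone decreasing in p
  ps <- sort(runif(20, 0.001, 1))
  expect_true(all(diff(snpChisq(ps)) <= 0))
  expect_error(snpChisq(0), "0, 1")
  expect_error(snpChisq(1.2), "0, 1")
})

test_that("geneStat is the arithmetic mean with an empty-input guard", {
  expect_equal(geneStat(0), 0)
  expect_equal(geneStat(c(3.8415, 3.8415)), 3.8415)
  expect_equal(geneStat(1:3), 2)
  expect_error(geneStat(numeric()), "no chi-square")
})

test_that("ldAndSpectrum returns a unit-diagonal R with conserved trace", {
  p <- simulatePanel(12, 300, ld = list(structure = "ar1", rho = 0.8),
                     seed = 5)
  ld <- ldAndSpectrum(p, variants(p)$snp_id)
  expect_equal(unname(diag(ld$R)), rep(1, 12), tolerance = 1e-3)
  expect_equal(sum(ld$lambda), 12, tolerance = 1e-8)
  expect_true(all(diff(ld$lambda) <= 1e-12))       # descending
  expect_true(all(ld$lambda >= 1e-8))
  expect_warning(ldAndSpectrum(p, c(variants(p)$snp_id[1], "nope")),
                 "absent from the panel")
  expect_error(suppressWarnings(ldAndSpectrum(p, "nope")),
               "no gene SNP")
})

test_that("weightedChisqSf matches chi-square special cases", {
  # one unit weight: plain 1-df chi-square tail
  x1 <- qchisq(0.05, 1, lower.tail = FALSE)
  expect_equal(as.numeric(weightedChisqSf(x1, 1)),
               pchisq(x1, 1, lower.tail = FALSE), tolerance = 1e-6)
  # two unit weights: 2-df chi-square tail
  x2 <- qchisq(0.05, 2, lower.tail = FALSE)
  expect_equal(as.numeric(weightedChisqSf(x2, c(1, 1))),
               pchisq(x2, 2, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(as.numeric(weightedChisqSf(0, c(1, 2))), 1)
  # few/equal weights use the exact conditioning quadrature; larger
  # spectra go through Imhof integration
  expect_equal(attr(weightedChisqSf(4, c(1.5, 0.5)), "method"), "exact")
  expect_equal(attr(weightedChisqSf(6, c(2, 1.5, 1, 0.5, 0.3)), "method"),
               "imhof")
})

test_that("Imhof tail agrees with a Monte-Carlo oracle for uneven weights", {
  set.seed(7)
  lambda <- c(1.5, 0.5)
  x <- 4
  n <- 1e6
  draws <- matrix(rchisq(n * 2, 1), ncol = 2) %*% lambda
  mc <- mean(draws > x)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(as.numeric(weightedChisqSf(x, lambda)) - mc), 3 * se)
})

test_that("gene p-value: one-SNP identity and independent-SNP reduction", {
  # a one-SNP gene reduces exactly to the SNP test
  r <- genePvalue(0.01, matrix(1))
  expect_identical(r$p, 0.01)
  expect_equal(r$stat, snpChisq(0.01))

  # two independent SNPs at p = 0.05: 2-df chi-square survival oracle
  r2 <- genePvalue(c(0.05, 0.05), diag(2))
  expect_equal(r2$p, pchisq(2 * qchisq(0.05, 1, lower.tail = FALSE), 2,
                            lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(r2$z, qnorm(r2$p, lower.tail = FALSE))
  expect_error(genePvalue(c(0.1, 0.2), matrix(1)), "dimension mismatch")
})

test_that("lowering any SNP p never increases the gene p", {
  set.seed(11)
  R <- ar1Matrix(5, 0.6)
  ps <- runif(5, 0.05, 0.9)
  base <- genePvalue(ps, R)$p
  for (j in 1:5) {
    ps2 <- ps
    ps2[j] <- ps[j] / 10
    expect_lte(genePvalue(ps2, R)$p, base + 1e-12)
  }
})

test_that("gene p is uniform under the multivariate-normal null", {
  set.seed(19)
  R <- ar1Matrix(6, 0.8)
  L <- t(chol(R))
  ps <- replicate(1200, {
    z <- drawZ(L)
    genePvalue(twoSidedP(z), R)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("geneTest runs over an annotation and skips panel-less genes", {
  panel <- simulatePanel(30, 300, ld = list(structure = "ar1", rho = 0.8),
                         seed = 3)
  genes <- simulateGeneLoc(panel, snpsPerGene = c(4, 6), seed = 3)
  windows <- extendWindow(genes)
  pair <- simulateDisorderPair(panel, genes, seed = 3)
  ann <- annotateGenes(pair$ss1, windows, panel)
  res <- geneTest(pair$ss1, ann, panel)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$stat >= 0))
  expect_equal(res$gene_id, annotatedGenes(ann)$gene_id)
  expect_true(all(res$tail_method %in% c("imhof", "gamma", "exact")))
})

test_that("Bonferroni arithmetic and display truncation", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 18297), 0.05 / 18297)
  expect_error(bonferroniThreshold(0.05, 0), ">= 1")
  expect_equal(displayThreshold(bonferroniThreshold(0.05, 18297), 2),
               2.7e-6)
  expect_equal(displayThreshold(bonferroniThreshold(0.05, 5420), 3),
               9.22e-6)
})
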