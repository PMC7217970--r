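test_that("twasZ identities: single SNP, hand arithmetic, degeneracy", {
  expect_equal(twasZ(1, 3.2, matrix(1)), 3.2)
  expect_equal(twasZ(c(0.5, 0.5), c(2, 2), diag(2)), 2 / sqrt(0.5),
               tolerance = 1e-12)
  expect_error(twasZ(c(0, 0), c(1, 1), diag(2)), "degenerate")
})

test_that("twasZ is sign-equivariant and scale-invariant in the weights", {
  set.seed(2)
  R <- ar1Matrix(4, 0.5)
  w <- rnorm(4); z <- rnorm(4)
  expect_equal(twasZ(-w, z, R), -twasZ(w, z, R), tolerance = 1e-12)
  expect_equal(twasZ(3.7 * w, z, R), twasZ(w, z, R), tolerance = 1e-12)
})

test_that("twas Z is standard normal under the null", {
  set.seed(17)
  R <- ar1Matrix(5, 0.7)
  L <- t(chol(R))
  w <- rnorm(5)
  zs <- replicate(5000, twasZ(w, drawZ(L), R))
  expect_gt(suppressWarnings(ks.test(zs, "pnorm"))$p.value, 0.01)
})

test_that("model Bonferroni reproduces the printed display thresholds", {
  expect_equal(displayThreshold(modelBonferroni(5420), 3), 9.22e-6)
  expect_equal(displayThreshold(modelBonferroni(4701), 3), 1.06e-5)
  expect_equal(modelBonferroni(1), 0.05)
})

# Build a toy TWAS setting: panel, two gene models, summary stats with Z.
twasSetting <- function(seed, wB = NULL, zShift = 0, nSnps = 6,
                        sameLocus = TRUE) {
  panel <- simulatePanel(nSnps, 400,
                         ld = list(structure = "blocks",
                                   size = nSnps, rho = 0.6),
                         seed = seed)
  vt <- variants(panel)
  R <- regulariseLd(stats::cor(dosages(panel)))$R
  L <- t(chol(R))
  wA <- c(1, 1, rep(0, nSnps - 2))
  if (is.null(wB)) wB <- c(0, 1, 1, rep(0, nSnps - 3))
  z <- drawZ(L, mu = zShift * as.numeric(R %*% wA) /
               sqrt(as.numeric(t(wA) %*% R %*% wA)))
  ss <- SumStats(data.frame(
    snp_id = vt$snp_id, chrom = vt$chrom, pos = vt$pos,
    a1 = "A", a2 = "G", p = twoSidedP(z), z = z, n = 1e5, info = 1),
    "SZ", 1e5)
  weights <- rbind(
    data.frame(gene_id = "GA", tissue = "DLPFC",
               snp_id = vt$snp_id[wA != 0], weight = wA[wA != 0]),
    data.frame(gene_id = "GB", tissue = "DLPFC",
               snp_id = vt$snp_id[wB != 0], weight = wB[wB != 0])
  )
  win <- if (sameLocus)
    data.frame(gene_id = c("GA", "GB"), start = c(vt$pos[1], vt$pos[2]),
               end = c(vt$pos[2], vt$pos[3]))
  else
    data.frame(gene_id = c("GA", "GB"), start = c(vt$pos[1], vt$pos[2] +
                                                    5e6),
               end = c(vt$pos[2], vt$pos[3] + 5e6))
  list(panel = panel, ss = ss, weights = weights, win = win, R = R)
}

test_that("conditional analysis: orthogonal predictors keep marginal p", {
  # two single-SNP models on uncorrelated SNPs
  panel <- simulatePanel(4, 400, ld = list(structure = "identity"),
                         seed = 31)
  vt <- variants(panel)
  set.seed(31)
  z <- rnorm(4) + c(6, 0, 6, 0)
  ss <- SumStats(data.frame(
    snp_id = vt$snp_id, chrom = vt$chrom, pos = vt$pos,
    a1 = "A", a2 = "G", p = twoSidedP(z), z = z, n = 1e5, info = 1),
    "SZ", 1e5)
  weights <- data.frame(gene_id = c("GA", "GB"), tissue = "DLPFC",
                        snp_id = vt$snp_id[c(1, 3)], weight = 1)
  tw <- runTwas(weights, ss, panel)
  ct <- conditionalTwas(tw, panel, window = 1e7, threshold = 0.05)
  # same locus, near-orthogonal predictors: conditional ~ marginal
  expect_equal(ct$conditional_p, ct$p, tolerance = 0.05)
})

test_that("a duplicated predictor gets conditional Z 0 and p near 1", {
  s <- twasSetting(41, wB = c(1, 1, 0, 0, 0, 0), zShift = 8)
  tw <- runTwas(s$weights, s$ss, s$panel, geneWindows = s$win)
  expect_equal(tw$z_twas[1], tw$z_twas[2], tolerance = 1e-10)
  ct <- conditionalTwas(tw, s$panel, window = 1e5, threshold = 1e-3)
  dup <- which(!ct$conditionally_independent)
  expect_length(dup, 1L)
  expect_equal(ct$conditional_z[dup], 0, tolerance = 1e-6)
  expect_gt(ct$conditional_p[dup], 0.99)
})

test_that("a singleton locus keeps its marginal statistics", {
  s <- twasSetting(43, sameLocus = FALSE, zShift = 6)
  tw <- runTwas(s$weights, s$ss, s$panel, geneWindows = s$win)
  ct <- conditionalTwas(tw, s$panel, window = 1e5, threshold = 1e-3)
  expect_equal(ct$conditional_z, ct$z_twas)
  expect_equal(ct$conditional_p, ct$p)
  expect_equal(length(unique(ct$locus_id)), 2L)
})

test_that("conditional analysis demotes a correlated bystander", {
  # planted causal gene A plus a bystander B whose predictor correlates
  # with A's; over replicates A must stay conditionally significant while
  # B loses significance once conditioned on A.
  panel <- simulatePanel(6, 400,
                         ld = list(structure = "blocks", size = 6,
                                   rho = 0.75), seed = 53)
  vt <- variants(panel)
  R <- regulariseLd(stats::cor(dosages(panel)))$R
  L <- t(chol(R))
  wA <- c(1, 1, 0, 0, 0, 0)
  wB <- c(0, 0.9, 1, 0, 0, 0)       # overlapping weights -> C ~ 0.8
  vA <- as.numeric(R %*% wA) / sqrt(as.numeric(t(wA) %*% R %*% wA))
  weights <- rbind(
    data.frame(gene_id = "GA", tissue = "DLPFC",
               snp_id = vt$snp_id[wA != 0], weight = wA[wA != 0]),
    data.frame(gene_id = "GB", tissue = "DLPFC",
               snp_id = vt$snp_id[wB != 0], weight = wB[wB != 0]))
  thr <- 9.22e-6
  # predicted-expression correlation between the two models is ~0.8
  cAB <- as.numeric(t(wA) %*% R %*% wB) /
    sqrt(as.numeric(t(wA) %*% R %*% wA) * as.numeric(t(wB) %*% R %*% wB))
  expect_gt(abs(cAB), 0.7)
  set.seed(53)
  aKept <- 0; bDropped <- 0; nRep <- 100
  for (i in seq_len(nRep)) {
    z <- drawZ(L, mu = 8 * vA)
    ss <- SumStats(data.frame(
      snp_id = vt$snp_id, chrom = vt$chrom, pos = vt$pos,
      a1 = "A", a2 = "G", p = twoSidedP(z), z = z, n = 1e5, info = 1),
      "SZ", 1e5)
    ct <- conditionalTwas(runTwas(weights, ss, panel), panel,
                          window = 1e6, threshold = thr)
    a <- ct[ct$gene_id == "GA", ]; b <- ct[ct$gene_id == "GB", ]
    if (a$conditionally_independent) aKept <- aKept + 1
    if (!b$conditionally_independent) bDropped <- bDropped + 1
  }
  expect_gte(aKept / nRep, 0.9)
  expect_gte(bDropped / nRep, 0.9)
})
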