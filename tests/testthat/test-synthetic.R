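test_that("panel generator hits the requested LD structure", {
  p <- simulatePanel(50, 500, ld = list(structure = "ar1", rho = 0.8),
                     seed = 7)
  d <- dosages(p)
  adj <- vapply(1:49, function(j) cor(d[, j], d[, j + 1]), 1.0)
  expect_lt(abs(mean(abs(adj)) - 0.8), 0.05)

  pid <- simulatePanel(50, 500, ld = list(structure = "identity"),
                       seed = 7)
  Ri <- cor(dosages(pid))
  expect_lt(mean(abs(Ri[upper.tri(Ri)])), 0.1)

  expect_error(simulatePanel(10, 1), "at least 2")
  expect_error(simulatePanel(10, 50, ld = list(structure = "ar1",
                                               rho = 1.2)), "rho")
})

test_that("every generator is a pure function of (parameters, seed)", {
  p1 <- simulatePanel(20, 100, seed = 5)
  p2 <- simulatePanel(20, 100, seed = 5)
  expect_identical(dosages(p1), dosages(p2))
  p3 <- simulatePanel(20, 100, seed = 6)
  expect_false(identical(dosages(p1), dosages(p3)))

  g <- simulateGeneLoc(p1, seed = 5)
  pair1 <- simulateDisorderPair(p1, g, seed = 5)
  pair2 <- simulateDisorderPair(p1, g, seed = 5)
  expect_identical(variants(pair1$ss1), variants(pair2$ss1))

  d1 <- file.path(tempdir(), "bundleA")
  d2 <- file.path(tempdir(), "bundleB")
  unlink(c(d1, d2), recursive = TRUE)
  b1 <- writeFixtureBundle(d1, "planted", seed = 9, nSnpsPerChrom = 60L,
                           nInd = 120L)
  b2 <- writeFixtureBundle(d2, "planted", seed = 9, nSnpsPerChrom = 60L,
                           nInd = 120L)
  for (k in names(b1))
    expect_identical(unname(tools::md5sum(b1[[k]])),
                     unname(tools::md5sum(b2[[k]])),
                     label = paste("hash of", k))
})

test_that("disorder pair plants disjoint effects with sqrt(N) scaling", {
  p <- simulatePanel(40, 200, seed = 13)
  g <- simulateGeneLoc(p, seed = 13)
  ids <- S4Vectors::mcols(g)$gene_id
  expect_error(
    simulateDisorderPair(p, g, sharedGenes = ids[1], specificGenes = ids[1]),
    "disjoint")
  pair <- simulateDisorderPair(p, g, sharedGenes = ids[1],
                               specificGenes = ids[2], effectSize = 12,
                               seed = 13)
  expect_equal(pair$truth$shift1, 12)
  expect_equal(pair$truth$shift2, 12 * sqrt(51710 / 105318))
  v1 <- variants(pair$ss1); v2 <- variants(pair$ss2)
  body1 <- v1$pos >= GenomicRanges::start(g)[1] &
    v1$pos <= GenomicRanges::end(g)[1] & v1$chrom == "1"
  body2 <- v1$pos >= GenomicRanges::start(g)[2] &
    v1$pos <= GenomicRanges::end(g)[2] & v1$chrom == "1"
  expect_gt(mean(v1$z[body1]), 6)       # shared gene shifted in focal
  expect_gt(mean(v2$z[body1]), 4)       # ... and in comparison
  expect_gt(mean(v1$z[body2]), 6)       # specific gene shifted in focal
  expect_lt(abs(mean(v2$z[body2])), 4)  # ... but not in comparison
  expect_error(simulateDisorderPair(p, g, sharedGenes = "NOPE"),
               "no SNPs")
})

test_that("background rg drives the cross-disorder correlation", {
  # At the SNP level the generator's contract is direct: the two
  # disorders' null Z-scores correlate at rg. At the gene level the mean
  # chi-square discards sign, so the gene-Z correlation attenuates toward
  # roughly rg^2 — asserted as a band, and ~0 under independence.
  snpCor <- function(rg, s) {
    p <- simulatePanel(150, 300, seed = 100 + s)
    g <- simulateGeneLoc(p, seed = 100 + s)
    pair <- simulateDisorderPair(p, g, rgBackground = rg, seed = 100 + s)
    cor(variants(pair$ss1)$z, variants(pair$ss2)$z)
  }
  expect_lt(abs(mean(vapply(1:3, snpCor, 1.0, rg = 0))), 0.1)
  expect_lt(abs(mean(vapply(1:3, snpCor, 1.0, rg = 0.7)) - 0.7), 0.07)

  geneCor <- function(rg) {
    zs <- matrix(NA_real_, 0, 2)
    for (s in 1:3) {
      p <- simulatePanel(120, 300, seed = 100 + s)
      g <- simulateGeneLoc(p, seed = 100 + s)
      w <- extendWindow(g)
      pair <- simulateDisorderPair(p, g, rgBackground = rg,
                                   seed = 100 + s)
      r1 <- geneTest(pair$ss1, annotateGenes(pair$ss1, w, p), p)
      r2 <- geneTest(pair$ss2, annotateGenes(pair$ss2, w, p), p)
      common <- intersect(r1$gene_id, r2$gene_id)
      zs <- rbind(zs, cbind(r1$z[match(common, r1$gene_id)],
                            r2$z[match(common, r2$gene_id)]))
    }
    cor(zs[, 1], zs[, 2])
  }
  expect_lt(abs(geneCor(0)), 0.25)
  g7 <- geneCor(0.7)
  expect_gt(g7, 0.7^2 - 0.15)
  expect_lt(g7, 0.7 + 0.1)
})

test_that("planted TWAS effects have the advertised expectation", {
  p <- simulatePanel(30, 300, seed = 23)
  g <- simulateGeneLoc(p, snpsPerGene = c(5, 5), seed = 23)
  gid <- S4Vectors::mcols(g)$gene_id[1]
  zt <- vapply(1:400, function(s) {
    sim <- simulateEqtlModels(p, extendWindow(g), nCausalSnps = 3,
                              alpha = setNames(6, gid), seed = 2000 + s)
    m <- sim$weights[sim$weights$gene_id == gid, ]
    ld <- ldAndSpectrum(p, m$snp_id)
    twasZ(m$weight, sim$snpZ[m$snp_id], ld$R)
  }, 1.0)
  expect_lt(abs(mean(zt) - 6), 0.2)
  expect_lt(abs(sd(zt) - 1), 0.15)

  # alpha = 0: z_twas is standard normal
  z0 <- vapply(1:400, function(s) {
    sim <- simulateEqtlModels(p, extendWindow(g), nCausalSnps = 3,
                              seed = 4000 + s)
    m <- sim$weights[sim$weights$gene_id == gid, ]
    ld <- ldAndSpectrum(p, m$snp_id)
    twasZ(m$weight, sim$snpZ[m$snp_id], ld$R)
  }, 1.0)
  expect_gt(suppressWarnings(ks.test(z0, "pnorm"))$p.value, 0.01)
})

test_that("fixture bundles parse through the io module and carry truth", {
  dir <- file.path(tempdir(), "bundleC")
  unlink(dir, recursive = TRUE)
  b <- writeFixtureBundle(dir, "planted", seed = 3, nSnpsPerChrom = 80L,
                          nInd = 150L)
  ss <- readSumstats(b$sumstats1, disorder = "SZ")
  expect_gt(nrow(variants(ss)), 100)
  expect_equal(totalN(ss), 105318)
  panel <- readPanel(b$panel)
  expect_equal(ncol(dosages(panel)), 160L)
  genes <- readGeneLoc(b$genes)
  expect_gt(length(genes), 10)
  sets <- readGmt(b$gmt)
  expect_true(all(c("pLI_ge_0.9_like", "FMRP_targets_like") %in%
                    names(sets)))
  expect_gt(nrow(readExpression(b$expression)), 10)
  expect_gt(nrow(readWeights(b$weights)), 10)
  truth <- jsonlite::read_json(b$truth)
  expect_equal(truth$scenario, "planted")
  expect_length(unlist(truth$shared_genes), 3L)
  expect_equal(truth$expected_counts$novel, 0L)
})
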