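test_that("readSumstats parses well-formed files and counts skips", {
  path <- writeToySumstats(toyVariants(3))
  ss <- readSumstats(path, disorder = "SZ", totalN = 1000)
  expect_s4_class(ss, "SumStats")
  expect_equal(nrow(variants(ss)), 3L)
  expect_equal(disorderLabel(ss), "SZ")
  expect_equal(totalN(ss), 1000)

  # header only -> 0 records with warning
  empty <- writeToySumstats(toyVariants(0))
  expect_warning(ss0 <- readSumstats(empty), "no usable records")
  expect_equal(nrow(variants(ss0)), 0L)

  # unparseable p-value skipped and counted
  df <- toyVariants(3)
  df$p <- c("0.1", "NA", "0.3")
  ssna <- readSumstats(writeToySumstats(df))
  expect_equal(nrow(variants(ssna)), 2L)
  expect_equal(qcLog(ssna)$skipped_unparseable, 1L)

  # missing mandatory column is a configuration error
  df2 <- toyVariants(2)
  df2$p <- NULL
  expect_error(readSumstats(writeToySumstats(df2)), "mandatory column")
})

test_that("readSumstats clamps p = 0 and normalises chromosomes", {
  df <- toyVariants(4)
  df$p <- c(0, 0.5, 0.2, 0.9)
  df$chrom <- c("chr1", "1", "X", "2")
  ss <- readSumstats(writeToySumstats(df))
  v <- variants(ss)
  expect_equal(nrow(v), 3L)              # X dropped
  expect_equal(qcLog(ss)$dropped_non_autosomal, 1L)
  expect_equal(min(v$p), 1e-300)         # zero clamped
  expect_equal(qcLog(ss)$clamped_p_zero, 1L)
  expect_true(all(v$chrom %in% c("1", "2")))
})

test_that("munge applies the INFO/SNP/p/duplicate filters in order", {
  v <- data.frame(
    snp_id = sprintf("rs%d", 1:5),
    chrom = "1", pos = 1:5 * 100,
    a1 = c("A", "C", "A", "G", "T"),
    a2 = c("G", "T", "AT", "C", "A"),
    p = c(0.01, 0.2, 0.3, 0.4, NA),
    info = c(0.95, 0.85, 0.99, 0.92, 0.99),
    stringsAsFactors = FALSE
  )
  ss <- mungeSumstats(SumStats(v, "SZ", 100))
  out <- variants(ss)
  expect_equal(out$snp_id, c("rs1", "rs4"))
  lg <- qcLog(ss)
  # retained + per-rule removals partition the input
  expect_equal(lg$retained + lg$removed_low_info + lg$removed_not_snp +
                 lg$removed_bad_p + lg$removed_duplicate_id, 5L)
  expect_equal(lg$removed_low_info, 1L)
  expect_equal(lg$removed_not_snp, 1L)
  expect_equal(lg$removed_bad_p, 1L)
})

test_that("munge removes all copies of a duplicated ID and is idempotent", {
  v <- toyVariants(4)
  v$snp_id <- c("rs1", "rs2", "rs2", "rs3")
  v$info <- rep(0.99, 4)
  ss1 <- mungeSumstats(SumStats(v, "SZ", 100))
  expect_equal(variants(ss1)$snp_id, c("rs1", "rs3"))
  expect_equal(qcLog(ss1)$removed_duplicate_id, 2L)

  ss2 <- mungeSumstats(ss1)
  expect_identical(variants(ss2), variants(ss1))

  # clean input returned unchanged
  clean <- SumStats(toyVariants(5), "SZ", 100)
  expect_identical(variants(mungeSumstats(clean))[names(toyVariants(5))],
                   variants(clean)[names(toyVariants(5))])
})

test_that("munge handles missing INFO and strand-ambiguous SNPs", {
  v <- toyVariants(3)                      # no info column: all retained
  ss <- mungeSumstats(SumStats(v, "SZ", 100))
  expect_equal(nrow(variants(ss)), 3L)
  expect_true(isTRUE(qcLog(ss)$info_column_absent))

  amb <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
                    pos = c(100, 200), a1 = c("A", "C"),
                    a2 = c("T", "A"), p = c(0.1, 0.2))
  kept <- mungeSumstats(SumStats(amb, "SZ", 10))
  expect_equal(variants(kept)$ambiguous, c(TRUE, FALSE))
  expect_equal(nrow(variants(kept)), 2L)
  dropped <- mungeSumstats(SumStats(amb, "SZ", 10), dropAmbiguous = TRUE)
  expect_equal(variants(dropped)$snp_id, "rs2")
})

test_that("write/read round-trip reproduces numeric fields bit-identically", {
  v <- toyVariants(6)
  v$p <- c(1e-300, 0.123456789123456, 2.7e-6, 1, 0.05, 1 / 3)
  v$z <- rnorm(6)
  v$n <- rep(105318, 6)
  v$info <- runif(6, 0.9, 1)
  ss <- SumStats(v, "SZ", 105318)
  path <- tempfile(fileext = ".tsv")
  writeSumstats(ss, path)
  back <- readSumstats(path, disorder = "SZ")
  vb <- variants(back)
  expect_identical(vb$p, v$p)
  expect_identical(vb$z, v$z)
  expect_identical(vb$pos, as.numeric(v$pos))
  expect_identical(vb$snp_id, v$snp_id)
})

test_that("readGmt enforces the GMT contract", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2", "setB\tdesc\tG3"), path)
  sets <- readGmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA, c("G1", "G2"))

  writeLines(c("setA\tdesc\tG1", "setA\tdesc\tG2"), path)
  expect_error(readGmt(path), "duplicate")
  writeLines(c("setA\tdesc\tG1", "short\tonly"), path)
  expect_error(readGmt(path), "line 2")

  # a catalogue-sized file parses set-per-line
  big <- tempfile(fileext = ".gmt")
  writeLines(sprintf("set%04d\td\tG%d\tG%d", 1:7296, 1:7296, 7297:14592),
             big)
  expect_length(readGmt(big), 7296L)
})

test_that("readPanel drops monomorphic variants and filters regions", {
  set.seed(1)
  dos <- matrix(rbinom(10 * 10, 2, 0.3), 10, 10)
  dos[, 3] <- 0; dos[, 7] <- 2          # monomorphic
  path <- tempfile(fileext = ".tsv")
  vt <- data.frame(snp_id = sprintf("rs%d", 1:10), chrom = "1",
                   pos = 1000 + (0:9) * 100)
  colnames(dos) <- vt$snp_id
  write.table(dos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(vt, paste0(path, ".variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  p <- readPanel(path)
  expect_equal(ncol(dosages(p)), 8L)
  expect_equal(p@nDropped, 2L)

  # half-open region on 1-based coordinates: start <= pos < end
  pr <- readPanel(path, region = list(chrom = "1", start = 1000,
                                      end = 1200))
  expect_equal(variants(pr)$pos, c(1000, 1100))
  expect_error(readPanel(path, region = list(chrom = "9", start = 1,
                                             end = 100)),
               "no panel variants overlap")
})

test_that("readPanel ingests VCF genotypes and dosage fields", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tI1\tI2\tI3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/1",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0"
  ), vcf)
  p <- readPanel(vcf)
  expect_equal(variants(p)$snp_id, c("rs1", "rs2"))  # rs3 monomorphic
  expect_equal(unname(dosages(p)[, "rs1"]), c(0, 1, 2))

  # DS dosage values in [0, 2] are accepted
  vcfd <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tI1\tI2\tI3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tDS\t0.1\t0.9\t1.8",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tDS\t1.2\t0.3\t0.7"
  ), vcfd)
  pd <- readPanel(vcfd)
  expect_equal(unname(dosages(pd)[, "rs1"]), c(0.1, 0.9, 1.8))
})
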