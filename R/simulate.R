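## Synthetic-data generators with known truth. Every generator is a pure
## function of (parameters, seed); a master seed fans out to per-component
## sub-streams (see substreamSeed) so adding a generator never perturbs the
## draws of another.

# Latent (tetrachoric-style) correlation needed between two thresholded
# Gaussians so that the realised correlation of the binary indicators hits
# `target`. Solved by 1-D integration of the bivariate normal density along
# the correlation path (Plackett's identity) plus uniroot.
latentCorrForBinary <- function(target, t1, t2) {
  if (target <= 0) return(target)
  p1 <- pnorm(t1, lower.tail = FALSE)
  p2 <- pnorm(t2, lower.tail = FALSE)
  sd12 <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  phi2 <- function(r) exp(-(t1^2 - 2 * r * t1 * t2 + t2^2) /
                            (2 * (1 - r^2))) / (2 * pi * sqrt(1 - r^2))
  binCorr <- function(r) {
    if (r <= 0) return(0)
    integrate(Vectorize(phi2), 0, r, rel.tol = 1e-9)$value / sd12
  }
  if (binCorr(0.9999) < target) return(0.9999)
  uniroot(function(r) binCorr(r) - target, c(1e-6, 0.9999),
          tol = 1e-7)$root
}

#' Simulate an LD reference panel
#'
#' Dosages are generated from a latent Gaussian threshold model: two
#' haplotypes per individual, each allele the indicator of a latent normal
#' exceeding the MAF threshold, summed to a dosage in \{0,1,2\}. The latent
#' correlation between adjacent SNPs is calibrated (tetrachoric inversion)
#' so that the \emph{realised} dosage correlation targets the requested
#' \eqn{\rho} — thresholding attenuates correlation, so the latent value is
#' deliberately larger. Structures: \code{identity} (independent SNPs),
#' \code{ar1} (first-order autoregressive decay), \code{blocks}
#' (equicorrelated blocks of the given size, independent across blocks).
#' MAFs are uniform in \code{mafRange}. The rare monomorphic column is
#' repaired by flipping one haplotype allele.
#'
#' @param mSnps number of SNPs.
#' @param nInd number of individuals (>= 2).
#' @param ld list: \code{structure} one of \code{"identity"}, \code{"ar1"},
#'   \code{"blocks"}; \code{rho} in (0,1) for ar1/blocks; \code{size} for
#'   blocks.
#' @param mafRange MAF bounds inside (0, 0.5].
#' @param seed master seed.
#' @param chrom chromosome label.
#' @param posStart,spacing 1-based position grid for the variants.
#' @return A \code{\linkS4class{ReferencePanel}}.
#' @export
simulatePanel <- function(mSnps, nInd,
                          ld = list(structure = "ar1", rho = 0.8),
                          mafRange = c(0.05, 0.5), seed = 1,
                          chrom = "1", posStart = 1e6, spacing = 2000) {
  if (nInd < 2) stop("need at least 2 individuals")
  stopifnot(mafRange[1] > 0, mafRange[2] <= 0.5)
  structure <- ld$structure %||% "identity"
  rho <- ld$rho %||% 0
  if (structure != "identity" && (rho <= 0 || rho >= 1))
    stop("rho must lie in (0, 1)")
  withSeed(substreamSeed(seed, paste0("panel/", chrom)), {
    # MAFs: iid uniform for independent SNPs; for correlated structures a
    # reflected random walk (ar1) or per-block value (blocks), since SNPs
    # in strong LD necessarily have similar allele frequencies — a very
    # different MAF bounds the attainable dosage correlation well below 1.
    maf <- switch(structure,
      identity = runif(mSnps, mafRange[1], mafRange[2]),
      ar1 = {
        m <- numeric(mSnps)
        m[1] <- runif(1, mafRange[1], mafRange[2])
        for (j in seq_len(mSnps - 1L)) {
          step <- m[j] + rnorm(1, 0, 0.015)
          # reflect at the range boundaries
          while (step < mafRange[1] || step > mafRange[2])
            step <- ifelse(step < mafRange[1], 2 * mafRange[1] - step,
                           2 * mafRange[2] - step)
          m[j + 1] <- step
        }
        m
      },
      blocks = {
        size <- ld$size %||% 5L
        blk <- rep(seq_len(ceiling(mSnps / size)), each = size)[1:mSnps]
        base <- runif(max(blk), mafRange[1], mafRange[2])
        pmin(pmax(base[blk] + runif(mSnps, -0.01, 0.01),
                  mafRange[1]), mafRange[2])
      }
    )
    thr <- qnorm(1 - maf)
    nHap <- 2L * nInd

    drawLatent <- switch(structure,
      identity = function() matrix(rnorm(nHap * mSnps), nHap, mSnps),
      ar1 = {
        rstar <- vapply(seq_len(max(mSnps - 1L, 0L)), function(j)
          latentCorrForBinary(rho, thr[j], thr[j + 1]), 1.0)
        function() {
          x <- matrix(0, nHap, mSnps)
          x[, 1] <- rnorm(nHap)
          for (j in seq_len(mSnps - 1L))
            x[, j + 1] <- rstar[j] * x[, j] +
              sqrt(1 - rstar[j]^2) * rnorm(nHap)
          x
        }
      },
      blocks = {
        size <- ld$size %||% 5L
        blk <- rep(seq_len(ceiling(mSnps / size)), each = size)[1:mSnps]
        rstar <- vapply(unique(blk), function(b) {
          tb <- mean(thr[blk == b])
          latentCorrForBinary(rho, tb, tb)
        }, 1.0)
        function() {
          x <- matrix(rnorm(nHap * mSnps), nHap, mSnps)
          for (b in unique(blk)) {
            j <- which(blk == b)
            f <- rnorm(nHap)
            x[, j] <- sqrt(rstar[b]) * f +
              sqrt(1 - rstar[b]) * x[, j, drop = FALSE]
          }
          x
        }
      },
      stop("unknown LD structure: ", structure)
    )
    hap <- drawLatent() > matrix(thr, nHap, mSnps, byrow = TRUE)
    dos <- hap[seq_len(nInd), , drop = FALSE] +
      hap[nInd + seq_len(nInd), , drop = FALSE]
    storage.mode(dos) <- "double"
    mono <- apply(dos, 2L, function(x) stats::var(x) < .Machine$double.eps)
    for (j in which(mono)) {
      i <- sample.int(nInd, 1L)
      dos[i, j] <- if (dos[i, j] > 0) dos[i, j] - 1 else 1
    }
    vt <- data.frame(
      snp_id = sprintf("rs%s_%d", chrom, seq_len(mSnps)),
      chrom = chrom,
      pos = posStart + (seq_len(mSnps) - 1L) * spacing,
      maf = maf,
      stringsAsFactors = FALSE
    )
    colnames(dos) <- vt$snp_id
    new("ReferencePanel", variants = vt, dosages = dos, nDropped = 0L)
  })
}

#' Simulate gene models tiling a panel
#'
#' Lays non-overlapping gene bodies over consecutive runs of panel
#' variants: each gene body spans a number of adjacent SNPs drawn
#' uniformly from \code{snpsPerGene} (so gene lengths and SNP counts vary,
#' as in real annotations), with \code{gapSnps} intergenic SNPs between
#' genes, alternating strand.
#'
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param snpsPerGene integer range (min, max) of SNPs per gene body.
#' @param gapSnps intergenic SNPs between genes (default 1).
#' @param seed seed for the per-gene size draws.
#' @return A \code{GRanges} with \code{gene_id}, \code{symbol}.
#' @export
simulateGeneLoc <- function(panel, snpsPerGene = c(4L, 10L), gapSnps = 1L,
                            seed = 1) {
  vt <- variants(panel)
  if (length(snpsPerGene) == 1L) snpsPerGene <- rep(snpsPerGene, 2L)
  out <- withSeed(substreamSeed(seed, "geneloc"), lapply(
    unique(vt$chrom), function(chr) {
      pos <- vt$pos[vt$chrom == chr]
      starts <- integer(); ends <- integer()
      j <- 1L
      while (TRUE) {
        size <- sample(snpsPerGene[1]:snpsPerGene[2], 1L)
        if (j + size - 1L > length(pos)) break
        starts <- c(starts, pos[j])
        ends <- c(ends, pos[j + size - 1L])
        j <- j + size + gapSnps
      }
      nG <- length(starts)
      gr <- GenomicRanges::GRanges(
        chr, IRanges::IRanges(starts, ends),
        strand = rep(c("+", "-"), length.out = nG)
      )
      S4Vectors::mcols(gr)$gene_id <- sprintf("GENE%s_%03d", chr,
                                              seq_len(nG))
      S4Vectors::mcols(gr)$symbol <- sprintf("SYM%s%03d", chr, seq_len(nG))
      gr
    }))
  suppressWarnings(unname(do.call(c, out)))
}

# Map gene windows to panel variant indices (per chromosome list).
panelGeneMap <- function(panel, geneWindows) {
  vt <- variants(panel)
  vgr <- GenomicRanges::GRanges(vt$chrom, IRanges::IRanges(vt$pos, vt$pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(geneWindows, vgr, ignore.strand = TRUE))
  m <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  names(m) <- S4Vectors::mcols(geneWindows)$gene_id[
    as.integer(names(m))]
  m
}

#' Simulate a pair of disorder GWAS with planted gene effects
#'
#' Null SNP Z-scores are multivariate normal under the panel LD (per
#' chromosome, Cholesky of the regularised dosage correlation), with a
#' background genetic correlation \code{rgBackground} between the two
#' disorders' noise. Planted effect genes receive a mean shift on the Z
#' scale at each of their SNPs: shared genes in both disorders, specific
#' genes in the first (focal) disorder only. The shift is
#' \eqn{\sqrt{N}}-scaled: disorder \eqn{d} gets
#' \code{effectSize * sqrt(n_d / max(n1, n2))} per SNP, so the smaller GWAS
#' carries proportionally weaker evidence. Per-SNP p-values are two-sided
#' normal; INFO and N columns are filled. Defaults mirror the flagship
#' schizophrenia/bipolar pairing: \code{n1 = 105318}, \code{n2 = 51710},
#' background correlation 0 (set e.g. 0.7 to emulate the observed
#' SZ-BIP genetic correlation).
#'
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param geneWindows extended gene windows (\code{GRanges}).
#' @param sharedGenes,specificGenes gene_ids planted in both / focal only
#'   (disjoint).
#' @param effectSize per-SNP Z-shift at the larger sample size
#'   (\code{>= 0}).
#' @param rgBackground background correlation of the null Z noise in
#'   [0, 1).
#' @param n1,n2 GWAS sample sizes (focal, comparison).
#' @param seed master seed.
#' @param labels disorder labels.
#' @return list with \code{ss1}, \code{ss2}
#'   (\code{\linkS4class{SumStats}}) and \code{truth} (all parameters and
#'   planted gene lists).
#' @export
simulateDisorderPair <- function(panel, geneWindows,
                                 sharedGenes = character(),
                                 specificGenes = character(),
                                 effectSize = 12, rgBackground = 0,
                                 n1 = 105318, n2 = 51710, seed = 1,
                                 labels = c("SZ", "BIP")) {
  if (length(intersect(sharedGenes, specificGenes)))
    stop("shared and specific gene sets must be disjoint")
  stopifnot(effectSize >= 0, rgBackground >= 0, rgBackground < 1)
  vt <- variants(panel)
  gmap <- panelGeneMap(panel, geneWindows)
  planted <- c(sharedGenes, specificGenes)
  missing <- setdiff(planted, names(gmap))
  if (length(missing))
    stop("effect gene(s) with no SNPs: ", paste(missing, collapse = ", "))

  shift1 <- effectSize * sqrt(n1 / max(n1, n2))
  shift2 <- effectSize * sqrt(n2 / max(n1, n2))
  mu1 <- mu2 <- numeric(nrow(vt))
  for (g in sharedGenes) {
    mu1[gmap[[g]]] <- mu1[gmap[[g]]] + shift1
    mu2[gmap[[g]]] <- mu2[gmap[[g]]] + shift2
  }
  for (g in specificGenes)
    mu1[gmap[[g]]] <- mu1[gmap[[g]]] + shift1

  z1 <- z2 <- numeric(nrow(vt))
  withSeed(substreamSeed(seed, "disorder-pair"), {
    for (chr in unique(vt$chrom)) {
      ix <- which(vt$chrom == chr)
      R <- regulariseLd(stats::cor(dosages(panel)[, ix, drop = FALSE]))$R
      L <- t(chol(R))
      e1 <- rnorm(length(ix))
      e2 <- rgBackground * e1 + sqrt(1 - rgBackground^2) * rnorm(length(ix))
      z1[ix] <- as.numeric(L %*% e1)
      z2[ix] <- as.numeric(L %*% e2)
    }
    alleles <- matrix(sample(c("A", "C", "G", "T"), 2L * nrow(vt),
                             replace = TRUE), ncol = 2L)
    same <- alleles[, 1] == alleles[, 2]
    alleles[same, 2] <- vapply(alleles[same, 1], function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1L), "")
    info1 <- runif(nrow(vt), 0.92, 1)
    info2 <- runif(nrow(vt), 0.92, 1)
    z1 <- z1 + mu1
    z2 <- z2 + mu2
    mk <- function(z, info, n, label) {
      SumStats(data.frame(
        snp_id = vt$snp_id, chrom = vt$chrom, pos = vt$pos,
        a1 = alleles[, 1], a2 = alleles[, 2],
        p = pmax(2 * pnorm(abs(z), lower.tail = FALSE), 1e-300),
        z = z, n = n, info = info, stringsAsFactors = FALSE
      ), disorder = label, totalN = n)
    }
    truth <- list(seed = seed, effect_size = effectSize,
                  rg_background = rgBackground, n1 = n1, n2 = n2,
                  shift1 = shift1, shift2 = shift2,
                  shared_genes = as.character(sharedGenes),
                  specific_genes = as.character(specificGenes),
                  labels = labels)
    list(ss1 = mk(z1, info1, n1, labels[1]),
         ss2 = mk(z2, info2, n2, labels[2]),
         truth = truth)
  })
}

#' Plant gene-set enrichment in a gene-Z vector
#'
#' Shifts the Z of member genes by \code{delta} (deterministic given the
#' template; \code{seed} is accepted for interface symmetry with the other
#' generators but unused).
#'
#' @param geneZ named numeric vector of gene Z-scores.
#' @param members member gene IDs.
#' @param delta non-negative shift.
#' @param seed unused.
#' @return The shifted vector.
#' @export
simulateGenesetEnrichment <- function(geneZ, members, delta, seed = NULL) {
  stopifnot(delta >= 0, !is.null(names(geneZ)))
  hit <- names(geneZ) %in% members
  geneZ[hit] <- geneZ[hit] + delta
  geneZ
}

#' Simulate sparse cis-eQTL weight models and TWAS-consistent SNP Z-scores
#'
#' For every gene with panel SNPs inside its window, draws
#' \code{nCausalSnps} cis SNPs and standard-normal weights. Trait SNP
#' Z-scores are then generated so that the expected summary-based TWAS Z of
#' gene \eqn{g} equals its planted effect \eqn{\alpha_g}:
#' \deqn{z = \sum_g \alpha_g R \tilde w_g + L\varepsilon,}
#' with \eqn{\tilde w_g = w_g / \sqrt{w_g^\top R w_g}} and \eqn{LL^\top = R}
#' the panel LD. Non-causal genes have \eqn{\alpha = 0}.
#'
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param geneWindows gene windows (\code{GRanges}).
#' @param nCausalSnps causal cis SNPs per model (>= 1).
#' @param alpha named numeric vector of planted TWAS effects (names =
#'   gene_ids); genes absent from it get 0.
#' @param tissue tissue label for the weight table.
#' @param seed master seed.
#' @return list with \code{weights} (long-format data.frame), \code{snpZ}
#'   (named vector over panel SNPs) and \code{truth}.
#' @export
simulateEqtlModels <- function(panel, geneWindows, nCausalSnps = 3L,
                               alpha = numeric(), tissue = "DLPFC",
                               seed = 1) {
  stopifnot(nCausalSnps >= 1)
  vt <- variants(panel)
  gmap <- panelGeneMap(panel, geneWindows)
  withSeed(substreamSeed(seed, "eqtl"), {
    wrows <- list()
    wvec <- list()
    for (g in names(gmap)) {
      cis <- gmap[[g]]
      pick <- if (length(cis) <= nCausalSnps) cis
              else sort(sample(cis, nCausalSnps))
      w <- rnorm(length(pick))
      if (all(w == 0)) w[1] <- 1
      wrows[[g]] <- data.frame(gene_id = g, tissue = tissue,
                               snp_id = vt$snp_id[pick], weight = w,
                               stringsAsFactors = FALSE)
      full <- numeric(nrow(vt)); full[pick] <- w
      wvec[[g]] <- full
    }
    z <- numeric(nrow(vt))
    for (chr in unique(vt$chrom)) {
      ix <- which(vt$chrom == chr)
      R <- regulariseLd(stats::cor(dosages(panel)[, ix, drop = FALSE]))$R
      L <- t(chol(R))
      mu <- numeric(length(ix))
      for (g in names(wvec)) {
        a <- if (g %in% names(alpha)) alpha[[g]] else 0
        if (a == 0) next
        wg <- wvec[[g]][ix]
        if (!any(wg != 0)) next
        denom <- sqrt(as.numeric(t(wg) %*% R %*% wg))
        mu <- mu + a * as.numeric(R %*% wg) / denom
      }
      z[ix] <- mu + as.numeric(L %*% rnorm(length(ix)))
    }
    names(z) <- vt$snp_id
    list(weights = do.call(rbind, unname(wrows)),
         snpZ = z,
         truth = list(seed = seed, n_causal_snps = nCausalSnps,
                      alpha = as.list(alpha), tissue = tissue))
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Generates and writes, under \code{outdir}: two disorder summary-stats
#' TSVs, a dosage-matrix panel with variant sidecar, a gene-location TSV, a
#' GMT file (random sets plus a pLI-like constrained set and an FMRP-like
#' target set), a gene-expression covariate TSV, an eQTL weight TSV and a
#' truth JSON recording seeds, parameters and planted gene lists. Scenario
#' \code{"null"} plants no effects; \code{"planted"} plants strongly
#' affected shared and focal-specific genes.
#'
#' @param outdir output directory (created).
#' @param scenario \code{"null"} or \code{"planted"}.
#' @param seed master seed; all files regenerate bit-identically from it.
#' @param nSnpsPerChrom,nInd,chroms panel geometry.
#' @param nShared,nSpecific planted gene counts for \code{"planted"}.
#' @param effectSize per-SNP Z shift for planted genes.
#' @param rgBackground background cross-disorder correlation.
#' @return Named list of written file paths, invisibly.
#' @export
writeFixtureBundle <- function(outdir, scenario = c("null", "planted"),
                               seed = 1, nSnpsPerChrom = 150L, nInd = 500L,
                               chroms = c("1", "2"), nShared = 3L,
                               nSpecific = 3L, effectSize = 12,
                               rgBackground = 0) {
  scenario <- match.arg(scenario)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  panels <- lapply(chroms, function(chr)
    simulatePanel(nSnpsPerChrom, nInd,
                  ld = list(structure = "ar1", rho = 0.8),
                  seed = seed, chrom = chr))
  vt <- do.call(rbind, lapply(panels, variants))
  dos <- do.call(cbind, lapply(panels, dosages))
  rownames(vt) <- NULL
  panel <- new("ReferencePanel", variants = vt, dosages = dos,
               nDropped = 0L)
  # gap of 4 SNPs (8 kb at the default spacing) keeps extended windows from
  # reaching neighbouring gene bodies, so planted effects stay attributable
  genes <- simulateGeneLoc(panel, gapSnps = 4L, seed = seed)
  windows <- extendWindow(genes)
  ids <- S4Vectors::mcols(genes)$gene_id

  if (scenario == "planted") {
    pick <- withSeed(substreamSeed(seed, "planted-genes"),
                     sample(ids, nShared + nSpecific))
    shared <- pick[seq_len(nShared)]
    specific <- pick[nShared + seq_len(nSpecific)]
  } else {
    shared <- specific <- character()
  }
  # effects are planted on gene-body SNPs (causal variants live in the
  # gene); the extended window is an annotation device only
  pair <- simulateDisorderPair(panel, genes, shared, specific,
                               effectSize = effectSize,
                               rgBackground = rgBackground, seed = seed)

  sets <- withSeed(substreamSeed(seed, "sets"), {
    s <- list(
      pLI_ge_0.9_like = sample(ids, max(2L, round(length(ids) * 0.25))),
      FMRP_targets_like = sample(ids, max(2L, round(length(ids) * 0.1)))
    )
    for (k in 1:5)
      s[[sprintf("random_set_%02d", k)]] <-
        sample(ids, max(2L, round(length(ids) * runif(1, 0.05, 0.3))))
    s
  })
  expr <- withSeed(substreamSeed(seed, "expression"),
                   data.frame(gene_id = ids,
                              median_tpm = round(exp(rnorm(length(ids),
                                                           2, 1)), 4)))
  eqtl <- simulateEqtlModels(panel, windows, seed = seed)

  paths <- list(
    sumstats1 = file.path(outdir, "sumstats_disorder1.tsv"),
    sumstats2 = file.path(outdir, "sumstats_disorder2.tsv"),
    panel = file.path(outdir, "panel.dosages.tsv"),
    panel_variants = file.path(outdir, "panel.dosages.tsv.variants.tsv"),
    genes = file.path(outdir, "genes.tsv"),
    gmt = file.path(outdir, "sets.gmt"),
    expression = file.path(outdir, "expression.tsv"),
    weights = file.path(outdir, "weights.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  writeSumstats(pair$ss1, paths$sumstats1)
  writeSumstats(pair$ss2, paths$sumstats2)
  write.table(dosages(panel), paths$panel, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(variants(panel), paths$panel_variants, sep = "\t",
              quote = FALSE, row.names = FALSE)
  gdf <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    symbol = S4Vectors::mcols(genes)$symbol,
    stringsAsFactors = FALSE
  )
  write.table(gdf, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), ""),
    paths$gmt)
  write.table(expr, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(eqtl$weights, paths$weights, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- c(pair$truth, list(
    scenario = scenario,
    master_seed = seed,
    schema_version = "1.0",
    n_genes = length(ids),
    expected_counts = list(shared = length(shared),
                           specific = length(specific),
                           novel = 0L)
  ))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
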