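#' Summary-based TWAS Z-score
#'
#' The association of imputed (genetically regulated) expression with the
#' trait, computed from eQTL SNP weights \code{w}, the SNP Z-scores and the
#' LD matrix of those SNPs:
#' \deqn{Z_{TWAS} = \frac{w^\top z}{\sqrt{w^\top R w}}.}
#' Sign-equivariant in \code{w} and invariant to positive rescaling.
#'
#' @param w weight vector.
#' @param snpZ SNP Z-scores, same length.
#' @param R LD matrix of matching dimension.
#' @return The TWAS Z.
#' @export
twasZ <- function(w, snpZ, R) {
  R <- as.matrix(R)
  stopifnot(length(w) == length(snpZ), nrow(R) == length(w))
  v <- as.numeric(t(w) %*% R %*% w)
  if (v <= 1e-12) stop("degenerate predictor: w'Rw is (near) zero")
  as.numeric(sum(w * snpZ) / sqrt(v))
}

#' Bonferroni threshold over tested expression models
#'
#' @param nModels number of models tested.
#' @param alpha family-wise error rate (default 0.05).
#' @return \code{alpha / nModels} at full precision.
#' @export
modelBonferroni <- function(nModels, alpha = 0.05) {
  bonferroniThreshold(alpha, nModels)
}

# Split a long-format weight table into per-model records, matching each
# model's SNPs against the summary statistics and the panel.
buildTwasModels <- function(weights, ss, panel, geneWindows = NULL) {
  v <- variants(ss)
  if (is.null(v$z))
    stop("TWAS needs signed SNP Z-scores (Z column) in the summary stats")
  pv <- variants(panel)
  key <- paste(weights$gene_id, weights$tissue, sep = "\r")
  models <- lapply(split(weights, key), function(m) {
    ok <- m$snp_id %in% v$snp_id & m$snp_id %in% pv$snp_id & m$weight != 0
    m <- m[ok, , drop = FALSE]
    if (!nrow(m)) return(NULL)
    iv <- match(m$snp_id, v$snp_id)
    ip <- match(m$snp_id, pv$snp_id)
    win <- if (!is.null(geneWindows) && m$gene_id[1] %in% geneWindows$gene_id) {
      gw <- geneWindows[match(m$gene_id[1], geneWindows$gene_id), ]
      c(gw$start, gw$end)
    } else range(pv$pos[ip])
    list(gene_id = m$gene_id[1], tissue = m$tissue[1],
         snp_id = m$snp_id, w = m$weight, z = v$z[iv],
         chrom = pv$chrom[ip[1]], start = win[1], end = win[2])
  })
  models[!vapply(models, is.null, TRUE)]
}

#' Run marginal TWAS over a weight table
#'
#' For every expression model (gene x tissue) with at least one nonzero
#' weight on a SNP present in both the summary statistics and the panel,
#' computes the summary-based TWAS Z and its two-sided p-value (effect
#' direction is meaningful: both over- and under-expression associations
#' are reported).
#'
#' @param weights long-format weight table (\code{\link{readWeights}}).
#' @param ss a munged \code{\linkS4class{SumStats}} carrying SNP Z-scores.
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param geneWindows optional data.frame (\code{gene_id}, \code{start},
#'   \code{end}) giving cis-window coordinates; defaults to the span of
#'   each model's SNPs.
#' @return data.frame with \code{gene_id}, \code{tissue}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_snps_used}, \code{z_twas}, \code{p};
#'   the matched models in \code{attr(, "models")} for
#'   \code{\link{conditionalTwas}}.
#' @export
runTwas <- function(weights, ss, panel, geneWindows = NULL) {
  models <- buildTwasModels(weights, ss, panel, geneWindows)
  if (!length(models)) stop("no testable expression model")
  rows <- lapply(models, function(m) {
    ld <- suppressWarnings(ldAndSpectrum(panel, m$snp_id))
    z <- twasZ(m$w, m$z, ld$R)
    data.frame(gene_id = m$gene_id, tissue = m$tissue, chrom = m$chrom,
               start = m$start, end = m$end, n_snps_used = length(m$w),
               z_twas = z, p = 2 * pnorm(abs(z), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

condZGivenSet <- function(i, S, z, C, varFloor = 1e-8) {
  if (!length(S)) return(z[i])
  Css <- C[S, S, drop = FALSE]
  Cis <- C[i, S]
  sol <- solve(Css, cbind(z[S], Cis))
  num <- z[i] - sum(Cis * sol[, 1])
  den2 <- max(1 - sum(Cis * sol[, 2]), varFloor)
  num / sqrt(den2)
}

#' Conditional TWAS analysis within loci
#'
#' Chains models into loci when their cis-windows lie within \code{window}
#' bp of each other on the same chromosome, computes the
#' predicted-expression correlation
#' \eqn{C_{ij} = w_i^\top R w_j / \sqrt{(w_i^\top R w_i)(w_j^\top R w_j)}},
#' and performs greedy forward selection: the model with the smallest
#' current (conditional) p is added to the joint set while it remains below
#' the significance threshold. Every model is then reported with its Z and
#' p conditional on the selected set (selected models are conditioned on
#' the other selected models); a model is flagged conditionally independent
#' when that conditional p stays below the threshold. A model whose
#' addition would make the conditioning matrix numerically singular is
#' skipped from the conditioning set with a warning. The conditional
#' variance is floored at \code{1e-8}, so a model duplicating a selected
#' predictor gets conditional Z = 0 and p near 1.
#'
#' @param twasResults output of \code{\link{runTwas}} (carries the matched
#'   models as an attribute).
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param window locus-chaining window in bp (default 100000).
#' @param threshold significance threshold for selection and the
#'   independence flag; defaults to the Bonferroni threshold over the
#'   number of models tested.
#' @return \code{twasResults} with added columns \code{locus_id},
#'   \code{conditional_z}, \code{conditional_p},
#'   \code{conditionally_independent}.
#' @export
conditionalTwas <- function(twasResults, panel, window = 100000,
                            threshold = NULL) {
  models <- attr(twasResults, "models")
  if (is.null(models)) stop("twasResults must come from runTwas()")
  if (is.null(threshold))
    threshold <- modelBonferroni(nrow(twasResults))
  res <- twasResults
  res$locus_id <- NA_character_
  res$conditional_z <- NA_real_
  res$conditional_p <- NA_real_
  res$conditionally_independent <- FALSE

  for (tis in unique(res$tissue)) {
    ti <- which(res$tissue == tis)
    for (chr in unique(res$chrom[ti])) {
      ci <- ti[res$chrom[ti] == chr]
      ord <- ci[order(res$start[ci])]
      # chain consecutive windows into one locus while the gap <= window
      gap <- if (length(ord) > 1L)
        res$start[ord][-1] - res$end[ord][-length(ord)] else numeric()
      locus <- cumsum(c(1L, as.integer(gap > window)))
      for (l in unique(locus)) {
        li <- ord[locus == l]
        lid <- sprintf("%s_%s_L%d", tis, chr, l)
        res$locus_id[li] <- lid
        if (length(li) == 1L) {
          res$conditional_z[li] <- res$z_twas[li]
          res$conditional_p[li] <- res$p[li]
          res$conditionally_independent[li] <- res$p[li] < threshold
          next
        }
        mlist <- models[match(paste(res$gene_id[li], res$tissue[li]),
                              vapply(models, function(m)
                                paste(m$gene_id, m$tissue), ""))]
        allSnps <- unique(unlist(lapply(mlist, `[[`, "snp_id")))
        ld <- suppressWarnings(ldAndSpectrum(panel, allSnps))
        W <- vapply(mlist, function(m) {
          w <- numeric(length(allSnps))
          w[match(m$snp_id, ld$snp_ids)] <- m$w
          w
        }, numeric(length(allSnps)))
        G <- t(W) %*% ld$R %*% W
        d <- sqrt(pmax(diag(G), 1e-12))
        C <- G / outer(d, d)
        diag(C) <- 1
        z <- res$z_twas[li]
        p <- res$p[li]
        k <- length(li)

        S <- integer(0)
        remaining <- seq_len(k)
        repeat {
          if (!length(remaining)) break
          cz <- vapply(remaining, condZGivenSet, 0.0, S = S, z = z, C = C)
          cp <- 2 * pnorm(abs(cz), lower.tail = FALSE)
          best <- which.min(cp)
          if (cp[best] >= threshold) break
          cand <- remaining[best]
          if (length(S) &&
              rcond(C[c(S, cand), c(S, cand), drop = FALSE]) < 1e-10) {
            warning("model ", res$gene_id[li][cand],
                    " skipped from conditioning set (singular C)")
            remaining <- remaining[-best]
            next
          }
          S <- c(S, cand)
          remaining <- remaining[-best]
        }
        for (j in seq_len(k)) {
          Sj <- setdiff(S, j)
          czj <- condZGivenSet(j, Sj, z, C)
          cpj <- 2 * pnorm(abs(czj), lower.tail = FALSE)
          res$conditional_z[li[j]] <- czj
          res$conditional_p[li[j]] <- cpj
          res$conditionally_independent[li[j]] <-
            (j %in% S) && cpj < threshold
        }
      }
    }
  }
  attr(res, "models") <- models
  attr(res, "threshold") <- threshold
  res
}
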