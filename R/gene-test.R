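#' Per-SNP chi-square from a p-value
#'
#' Inverts the 1-df chi-square survival function: the returned value is the
#' chi-square quantile at \code{1 - p}, monotone decreasing in \code{p}.
#'
#' @param p SNP p-value(s) in (0, 1].
#' @return 1-df chi-square value(s).
#' @export
snpChisq <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  qchisq(p, df = 1, lower.tail = FALSE)
}

#' Gene statistic: mean chi-square
#'
#' @param chisq vector of per-SNP 1-df chi-square values.
#' @return Arithmetic mean.
#' @export
geneStat <- function(chisq) {
  if (!length(chisq)) stop("no chi-square values supplied")
  mean(chisq)
}

#' LD matrix and eigen-spectrum for a set of panel SNPs
#'
#' Pairwise Pearson correlation of panel dosages, regularised for numerical
#' stability: when the smallest eigenvalue falls below \code{1e-8} the
#' matrix is shrunk as \eqn{R \leftarrow (1-\epsilon)R + \epsilon I} with
#' \eqn{\epsilon = 0.001}. Eigenvalues are returned in descending order,
#' negatives floored at \code{1e-8}, and the spectrum rescaled so that its
#' sum equals the SNP count (the trace of a correlation matrix).
#'
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param snpIds SNP identifiers; those absent from the panel are dropped
#'   with a warning.
#' @return list with \code{R} (correlation matrix), \code{lambda}
#'   (eigenvalues), \code{snp_ids} (retained, panel order preserved as
#'   requested).
#' @export
ldAndSpectrum <- function(panel, snpIds) {
  stopifnot(is(panel, "ReferencePanel"))
  found <- snpIds %in% variants(panel)$snp_id
  if (!all(found)) {
    warning(sum(!found), " SNP(s) absent from the panel dropped")
    snpIds <- snpIds[found]
  }
  if (!length(snpIds)) stop("no gene SNP present in the panel")
  dos <- dosages(panel)[, snpIds, drop = FALSE]
  if (nrow(dos) < 2) stop("panel needs at least 2 individuals")
  R <- stats::cor(dos)
  R <- regulariseLd(R)
  list(R = R$R, lambda = spectrumOf(R$R), snp_ids = snpIds)
}

regulariseLd <- function(R, eps = 0.001, floor = 1e-8) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * nrow(R))
    stop("LD matrix is not positive semi-definite within tolerance")
  if (min(ev) < floor) {
    m <- nrow(R)
    R <- (1 - eps) * R + eps * diag(m)
  }
  list(R = R)
}

spectrumOf <- function(R, floor = 1e-8) {
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, floor)
  lambda * (nrow(R) / sum(lambda))  # preserve the trace identity
}

#' Survival function of a weighted sum of 1-df chi-squares
#'
#' Computes \eqn{P(\sum_j \lambda_j u_j > x)} for independent
#' \eqn{u_j \sim \chi^2_1} — the null of the LD-aware mean chi-square gene
#' test, with \eqn{\lambda} the eigenvalues of the LD matrix. The primary
#' algorithm is Imhof's exact numerical inversion of the characteristic
#' function, integrated to absolute tolerance \code{1e-10}. For three or
#' fewer (or all-equal) weights an exact conditioning quadrature is used
#' instead, because the oscillatory Imhof integrand then decays too slowly
#' for tight absolute accuracy. If the integrator fails, or its result
#' falls below the integration resolution, a gamma moment-match (mean
#' \eqn{\sum\lambda}, variance \eqn{2\sum\lambda^2}) is used and flagged.
#' A Monte-Carlo mode is available for cross-checks.
#'
#' @param x quantile, \code{x >= 0}.
#' @param lambda positive eigenvalue weights.
#' @param method \code{"imhof"} (default, with gamma fallback),
#'   \code{"gamma"}, or \code{"montecarlo"}.
#' @param absTol absolute integration tolerance.
#' @param nDraws Monte-Carlo sample size.
#' @return The tail probability in (0, 1], with the algorithm actually used
#'   in \code{attr(, "method")}.
#' @export
weightedChisqSf <- function(x, lambda, method = c("imhof", "gamma",
                                                  "montecarlo"),
                            absTol = 1e-10, nDraws = 1e6) {
  method <- match.arg(method)
  stopifnot(length(x) == 1L, x >= 0, all(lambda > 0))
  if (x == 0) return(structure(1, method = "exact"))
  p <- switch(method,
    imhof = imhofTail(x, lambda, absTol),
    gamma = gammaTail(x, lambda),
    montecarlo = mcTail(x, lambda, nDraws)
  )
  used <- attr(p, "method") %||% method
  p <- min(max(as.numeric(p), 1e-300), 1)
  structure(p, method = used)
}

# Exact tail for few or equal weights, by conditioning: integrating the
# smallest-weight chi-square out leaves a smooth 1-D integral, applied
# recursively. Accurate to ~1e-12 including deep tails; used for m <= 3
# where the oscillatory Imhof integral converges too slowly.
exactSmallTail <- function(x, lambda) {
  if (x <= 0) return(1)
  lambda <- sort(lambda, decreasing = TRUE)
  m <- length(lambda)
  if (m == 1L) return(pchisq(x / lambda, df = 1, lower.tail = FALSE))
  if (diff(range(lambda)) < 1e-12)
    return(pchisq(x / lambda[1], df = m, lower.tail = FALSE))
  lm <- lambda[m]
  cut <- x / lm
  inner <- function(v) vapply(v, function(vi)
    exactSmallTail(x - lm * vi, lambda[-m]), 1.0) * dchisq(v, df = 1)
  val <- integrate(inner, 0, cut, rel.tol = 1e-10, abs.tol = 1e-13,
                   subdivisions = 1000L, stop.on.error = FALSE)$value
  val + pchisq(cut, df = 1, lower.tail = FALSE)
}

imhofTail <- function(x, lambda, absTol = 1e-10) {
  # equal weights: the weighted sum is an exactly scaled chi-square;
  # for m <= 3 the conditioning quadrature is exact and cheap
  if (length(lambda) <= 3L || diff(range(lambda)) < 1e-12)
    return(structure(exactSmallTail(x, lambda), method = "exact"))
  integrand <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * x * u
    lrho <- 0.25 * colSums(log1p(lu^2))
    val <- sin(theta) * exp(-lrho) / u
    val[u == 0] <- 0.5 * (sum(lambda) - x)
    val
  }
  # The integrand decays as u^-(1+m/2): for small m reaching 1e-10 needs a
  # very long oscillatory tail, so accept the integrator's own error
  # estimate when it undershoots the target but is still far below any
  # practically relevant scale, escalating the subdivision budget first.
  res <- NULL
  for (sub in c(2000L, 20000L)) {
    res <- tryCatch(
      integrate(integrand, 0, Inf, abs.tol = absTol, rel.tol = absTol,
                subdivisions = sub, stop.on.error = FALSE),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (res$message == "OK" || res$abs.error < 1e-7)) break
    res <- NULL
  }
  if (is.null(res)) return(gammaTail(x, lambda))
  p <- 0.5 + res$value / pi
  # below the integration resolution (or a hair outside [0,1]) the
  # moment-matched gamma gives a smoother, monotone deep tail
  if (p < 1e-9 || p > 1 + 1e-6) return(gammaTail(x, lambda))
  structure(min(p, 1), method = "imhof")
}

gammaTail <- function(x, lambda) {
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  shape <- s1^2 / (2 * s2)
  scale <- 2 * s2 / s1
  structure(pgamma(x, shape = shape, scale = scale, lower.tail = FALSE),
            method = "gamma")
}

mcTail <- function(x, lambda, nDraws) {
  m <- length(lambda)
  draws <- matrix(stats::rchisq(nDraws * m, df = 1), ncol = m)
  q <- as.numeric(draws %*% lambda)
  structure(mean(q > x), method = "montecarlo")
}

#' Gene p-value from SNP p-values and an LD matrix
#'
#' The gene statistic is the mean of the per-SNP 1-df chi-squares. Under
#' the null the SNP Z-scores are multivariate normal with correlation R
#' (the LD matrix), so \eqn{mT = \sum z_j^2 = \sum_j \lambda_j u_j} with
#' \eqn{\lambda} the eigenvalues of R and \eqn{u_j} iid 1-df chi-squares;
#' the p-value is the Imhof tail of that weighted sum at \eqn{mT}. A
#' single-SNP gene reduces exactly to the SNP test. SNP p-values are
#' clamped to \code{[1e-300, 1 - 1e-16]} before quantile inversion.
#'
#' @param snpP vector of SNP p-values.
#' @param R LD (correlation) matrix of matching dimension.
#' @param geneId optional identifier carried through to the result.
#' @return list with \code{gene_id}, \code{n_snps}, \code{stat},
#'   \code{lambda}, \code{p}, \code{z} (probit of \code{1 - p}) and
#'   \code{tail_method}.
#' @export
genePvalue <- function(snpP, R, geneId = NA_character_) {
  snpP <- pmin(pmax(snpP, 1e-300), 1 - 1e-16)
  R <- as.matrix(R)
  m <- length(snpP)
  if (nrow(R) != m || ncol(R) != m)
    stop("dimension mismatch between p-values and LD matrix")
  chi <- snpChisq(snpP)
  T <- geneStat(chi)
  if (m == 1L) {
    p <- snpP
    lambda <- 1
    method <- "exact"
  } else {
    lambda <- spectrumOf(regulariseLd(R)$R)
    p <- weightedChisqSf(m * T, lambda)
    method <- attr(p, "method")
    p <- as.numeric(p)
  }
  list(gene_id = geneId, n_snps = m, stat = T, lambda = lambda,
       p = p, z = zFromP(p), tail_method = method)
}

#' Run the gene-based test over an annotation
#'
#' For each annotated gene, takes its SNP p-values from the summary
#' statistics, derives the LD matrix of those SNPs from the reference panel
#' and computes the mean chi-square p-value. Genes whose SNPs are all
#' missing from the panel are skipped and reported, not assigned p = 1.
#'
#' @param ss a munged \code{\linkS4class{SumStats}}.
#' @param ann a \code{\linkS4class{GeneAnnotation}}.
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_snps}, \code{mac}, \code{stat},
#'   \code{p}, \code{z}, \code{tail_method}; skipped gene IDs in
#'   \code{attr(, "skipped")}.
#' @export
geneTest <- function(ss, ann, panel) {
  stopifnot(is(ss, "SumStats"), is(ann, "GeneAnnotation"),
            is(panel, "ReferencePanel"))
  v <- variants(ss)
  g <- annotatedGenes(ann)
  idx <- snpIndex(ann)
  panelIds <- variants(panel)$snp_id
  rows <- vector("list", nrow(g))
  skipped <- character()
  for (i in seq_len(nrow(g))) {
    ix <- idx[[i]]
    ids <- v$snp_id[ix]
    keep <- ids %in% panelIds
    if (!any(keep)) {
      skipped <- c(skipped, g$gene_id[i])
      next
    }
    ld <- suppressWarnings(ldAndSpectrum(panel, ids[keep]))
    res <- genePvalue(v$p[ix][keep], ld$R, geneId = g$gene_id[i])
    rows[[i]] <- data.frame(
      gene_id = g$gene_id[i], chrom = g$chrom[i], start = g$start[i],
      end = g$end[i], n_snps = res$n_snps, mac = g$mac[i],
      stat = res$stat, p = res$p, z = res$z,
      tail_method = res$tail_method, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    stop("no gene could be tested (all SNPs missing from the panel)")
  rownames(out) <- NULL
  if (length(skipped))
    message(length(skipped), " gene(s) skipped: no SNP in the panel")
  attr(out, "skipped") <- skipped
  out
}

#' Bonferroni threshold
#'
#' \code{alpha / nTests} at full precision. Use \code{\link{displayThreshold}}
#' for the truncated display convention.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param nTests number of tests, at least 1.
#' @return The threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  if (nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}

#' Display form of a significance threshold
#'
#' Truncates (floors) to the given number of significant figures, the
#' convention used when quoting Bonferroni thresholds such as
#' \code{0.05/18297} as \code{2.7e-6}.
#'
#' @param x threshold value(s).
#' @param digits significant figures to keep (default 2).
#' @return Truncated value(s).
#' @export
displayThreshold <- function(x, digits = 2L) truncSignif(x, digits)
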