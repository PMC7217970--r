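#' Probit transform of a gene p-value
#'
#' \eqn{z = \Phi^{-1}(1 - p)}: larger z means stronger association.
#'
#' @param p p-value(s) strictly inside (0, 1).
#' @return Standard-normal deviate(s).
#' @export
probitZ <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p-values must lie strictly in (0, 1)")
  qnorm(p, lower.tail = FALSE)
}

#' Competitive gene-set association test
#'
#' Ordinary least squares of the probit-transformed gene significance on an
#' intercept, the set-membership indicator and gene-level confounder
#' covariates. The null hypothesis is that genes inside the set are no more
#' strongly associated than genes outside it; the membership coefficient
#' \eqn{\beta_{GS}} is tested one-sided (upper tail of its t-statistic).
#'
#' @param geneZ numeric vector of gene Z-scores (probit of 1 - p).
#' @param inSet logical membership indicator, same length.
#' @param covariates optional numeric matrix/data.frame of gene-level
#'   confounders (e.g. log gene length, log SNP count, log MAC + 1).
#' @param setName label carried into the result.
#' @return One-row data.frame: \code{set}, \code{beta}, \code{se},
#'   \code{p_one_sided}, \code{n_in_set}, \code{n_total},
#'   \code{covariates} (comma-joined names).
#' @export
competitiveTest <- function(geneZ, inSet, covariates = NULL,
                            setName = "set") {
  inSet <- as.logical(inSet)
  stopifnot(length(geneZ) == length(inSet))
  nIn <- sum(inSet)
  if (nIn < 2 || (length(inSet) - nIn) < 2)
    stop("need at least 2 genes inside and 2 outside the set")
  df <- data.frame(z = geneZ, membership = as.numeric(inSet))
  covNames <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covNames <- names(covariates)
    df <- cbind(df, covariates)
  }
  fit <- lm(z ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  beta <- sm["membership", "Estimate"]
  se <- sm["membership", "Std. Error"]
  pOne <- pt(beta / se, df = df.residual(fit), lower.tail = FALSE)
  data.frame(set = setName, beta = beta, se = se, p_one_sided = pOne,
             n_in_set = nIn, n_total = length(inSet),
             covariates = paste(covNames, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Competitive test with a brain-expression covariate
#'
#' Same model as \code{\link{competitiveTest}} with a gene-wise expression
#' covariate (median TPM) appended, testing whether set enrichment survives
#' adjustment for brain expression. Genes lacking an expression value are
#' dropped (count reported via attribute).
#'
#' @inheritParams competitiveTest
#' @param expression numeric vector of expression values (\code{NA} allowed;
#'   those genes are dropped), values \code{>= 0}.
#' @return As \code{\link{competitiveTest}}; dropped-gene count in
#'   \code{attr(, "n_dropped")}.
#' @export
expressionAdjustedTest <- function(geneZ, inSet, covariates = NULL,
                                   expression, setName = "set") {
  stopifnot(length(expression) == length(geneZ))
  keep <- !is.na(expression)
  if (any(expression[keep] < 0)) stop("expression values must be >= 0")
  covariates <- if (is.null(covariates)) {
    data.frame(median_tpm = expression)
  } else {
    cbind(as.data.frame(covariates), median_tpm = expression)
  }
  res <- competitiveTest(geneZ[keep], inSet[keep],
                         covariates[keep, , drop = FALSE], setName)
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Default gene-level confounder covariates
#'
#' Builds the standard confounder set for the competitive model from a
#' gene-result table: log gene length (bp), log SNP count and
#' log(genic minor allele count + 1). Raw-scale versions are available via
#' \code{logScale = FALSE}.
#'
#' @param geneResults data.frame from \code{\link{geneTest}} (needs
#'   \code{start}, \code{end}, \code{n_snps}, \code{mac}).
#' @param logScale use log transforms (default \code{TRUE}).
#' @return data.frame of covariates aligned with \code{geneResults} rows.
#' @export
geneCovariates <- function(geneResults, logScale = TRUE) {
  len <- geneResults$end - geneResults$start + 1
  mac <- geneResults$mac
  if (all(is.na(mac))) mac <- NULL
  if (logScale) {
    out <- data.frame(log_length = log(len),
                      log_nsnps = log(geneResults$n_snps))
    if (!is.null(mac)) out$log_mac <- log(mac + 1)
  } else {
    out <- data.frame(length = len, nsnps = geneResults$n_snps)
    if (!is.null(mac)) out$mac <- mac
  }
  out
}

#' Run competitive association for a collection of gene sets
#'
#' Intersects each set with the analysed genes (intersection sizes
#' recorded), builds the membership indicator and runs
#' \code{\link{competitiveTest}} per set, optionally with the expression
#' covariate. Sets that cover none or all analysed genes after
#' intersection, or fewer than \code{minSetSize} genes, are skipped with a
#' reason.
#'
#' @param geneResults data.frame from \code{\link{geneTest}} (or a meta
#'   result with a \code{z} column).
#' @param sets named list of member gene-ID vectors (see
#'   \code{\link{readGmt}}).
#' @param covariates optional covariate data.frame aligned with
#'   \code{geneResults}; defaults to \code{\link{geneCovariates}}.
#' @param expression optional named vector (by gene_id) of median TPM.
#' @param minSetSize minimum post-intersection set size (default 2).
#' @return data.frame of per-set results; skipped sets with reasons in
#'   \code{attr(, "skipped")}.
#' @export
runGenesetAssociation <- function(geneResults, sets, covariates = NULL,
                                  expression = NULL, minSetSize = 2L) {
  if (is.null(covariates) &&
      all(c("start", "end", "n_snps") %in% names(geneResults)))
    covariates <- geneCovariates(geneResults)
  z <- geneResults$z
  ids <- geneResults$gene_id
  expr <- if (!is.null(expression)) unname(expression[ids]) else NULL
  out <- list(); skipped <- list()
  for (nm in names(sets)) {
    inSet <- ids %in% sets[[nm]]
    n <- sum(inSet)
    if (n < minSetSize || (length(ids) - n) < 2) {
      skipped[[nm]] <- sprintf("intersection size %d unusable", n)
      next
    }
    res <- tryCatch(
      if (is.null(expr))
        competitiveTest(z, inSet, covariates, setName = nm)
      else
        expressionAdjustedTest(z, inSet, covariates, expr, setName = nm),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) skipped[[nm]] <- res else out[[nm]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no gene set could be tested")
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
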