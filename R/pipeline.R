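#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file path) with:
#' \describe{
#'   \item{sumstats}{named list of summary-statistics paths, one per
#'     disorder; the first (or \code{focal}) is the focal disorder.}
#'   \item{genes, sets, panel}{paths to the gene-location TSV, GMT file and
#'     reference panel.}
#'   \item{weights, expression}{optional paths (TWAS weights, gene
#'     expression covariate).}
#'   \item{thresholds}{\code{alpha} (default 0.05, used where a Bonferroni
#'     threshold is recomputed), \code{bonferroni} (classification
#'     threshold: a number, default \code{2.7e-6} i.e. 0.05 over 18297
#'     genes, or \code{"auto"} to recompute \code{alpha} over the genes
#'     actually tested), \code{nominal} (0.05),
#'     \code{up} (5000), \code{down} (1500), \code{locus_window} (100000),
#'     \code{mhc} (list \code{chrom}, \code{start}, \code{end}).}
#'   \item{flags}{\code{munge} (TRUE), \code{info_min} (0.9),
#'     \code{drop_ambiguous} (FALSE), \code{run_twas} (FALSE),
#'     \code{expression_covariate} (FALSE), \code{run_genesets} (TRUE).}
#'   \item{seed}{integer, used for any stochastic step.}
#' }
#'
#' @param config list or YAML path.
#' @return Character vector of validation errors (empty when valid), with
#'   the normalised config in \code{attr(, "config")}.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  errs <- character()
  defaults <- list(
    thresholds = list(alpha = 0.05, bonferroni = 2.7e-6, nominal = 0.05,
                      up = 5000,
                      down = 1500, locus_window = 100000,
                      mhc = list(chrom = "6", start = 28477797,
                                 end = 33448354)),
    flags = list(munge = TRUE, info_min = 0.9, drop_ambiguous = FALSE,
                 run_twas = FALSE, expression_covariate = FALSE,
                 run_genesets = TRUE),
    seed = 1L
  )
  for (top in names(defaults)) {
    if (is.list(defaults[[top]])) {
      cur <- config[[top]] %||% list()
      for (k in names(defaults[[top]]))
        cur[[k]] <- cur[[k]] %||% defaults[[top]][[k]]
      config[[top]] <- cur
    } else {
      config[[top]] <- config[[top]] %||% defaults[[top]]
    }
  }
  ss <- config$sumstats
  if (is.null(ss) || length(ss) < 2L || is.null(names(ss)))
    errs <- c(errs, "sumstats: need a named list of >= 2 disorders")
  for (nm in names(ss))
    if (!file.exists(ss[[nm]]))
      errs <- c(errs, sprintf("sumstats[%s]: file not found: %s", nm,
                              ss[[nm]]))
  for (key in c("genes", "sets", "panel")) {
    if (is.null(config[[key]]))
      errs <- c(errs, paste0(key, ": path missing"))
    else if (!file.exists(config[[key]]))
      errs <- c(errs, sprintf("%s: file not found: %s", key, config[[key]]))
  }
  for (key in c("weights", "expression"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      errs <- c(errs, sprintf("%s: file not found: %s", key, config[[key]]))
  th <- config$thresholds
  for (k in c("alpha", "nominal", "up", "down", "locus_window"))
    if (!is.numeric(th[[k]]) || th[[k]] < 0)
      errs <- c(errs, sprintf("thresholds$%s: must be non-negative", k))
  if (is.null(config$focal)) config$focal <- names(ss)[1]
  if (!config$focal %in% names(ss))
    errs <- c(errs, "focal: not among sumstats names")
  attr(errs, "config") <- config
  errs
}

#' Run the whole cross-disorder pipeline
#'
#' Executes munge, annotation, the gene-based test per disorder,
#' competitive gene-set association for the focal disorder, pairwise
#' sample-size-weighted meta-analysis of the focal disorder with every
#' comparison disorder (plus gene-set association on the meta Z),
#' pleiotropy classification (shared / specific / novel-on-meta), and
#' optionally TWAS with conditional analysis. All stage tables are written
#' as TSV under \code{outdir} together with a machine-readable
#' \code{summary.json} (class counts, thresholds, versions, seed, per-stage
#' timings). Any stage error aborts with the stage name; partial outputs
#' are retained next to a \code{FAILED} marker naming the stage.
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{validatePipelineConfig}}).
#' @param outdir output directory (created).
#' @return Invisibly, a list with all stage results and the summary.
#' @export
runPipeline <- function(config, outdir) {
  errs <- validatePipelineConfig(config)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  config <- attr(errs, "config")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  fl <- config$flags
  timings <- list()
  stageName <- "setup"
  onFail <- function(e) {
    writeLines(c(stageName, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("stage ", stageName, ": ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    stageName <<- name
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = onFail)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  wtsv <- function(x, name) {
    write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  panel <- stage("read_panel", readPanel(config$panel))
  genes <- stage("read_genes", readGeneLoc(config$genes))
  sets <- stage("read_sets", readGmt(config$sets))
  windows <- stage("windows", {
    w <- extendWindow(genes, up = th$up, down = th$down)
    excludeMhc(w, chrom = th$mhc$chrom, start = th$mhc$start,
               end = th$mhc$end)
  })

  disorders <- names(config$sumstats)
  ssList <- stage("read_sumstats", lapply(disorders, function(nm)
    readSumstats(config$sumstats[[nm]], disorder = nm)))
  names(ssList) <- disorders
  if (isTRUE(fl$munge))
    ssList <- stage("munge", lapply(ssList, mungeSumstats,
                                    infoMin = fl$info_min,
                                    dropAmbiguous = fl$drop_ambiguous))

  annList <- stage("annotate", lapply(ssList, annotateGenes,
                                      genes = windows, panel = panel))
  geneRes <- stage("gene_test", {
    out <- lapply(disorders, function(nm) {
      r <- geneTest(ssList[[nm]], annList[[nm]], panel)
      wtsv(r, sprintf("gene_results_%s.tsv", nm))
      r
    })
    names(out) <- disorders
    out
  })

  focal <- config$focal
  comparisons <- setdiff(disorders, focal)
  nGenes <- nrow(geneRes[[focal]])
  # classification threshold: the fixed genome-wide default (0.05/18297),
  # "auto" to recompute over the genes actually tested, or any number
  bonf <- if (identical(th$bonferroni, "auto"))
    bonferroniThreshold(th$alpha, nGenes) else as.numeric(th$bonferroni)

  setRes <- NULL
  if (isTRUE(fl$run_genesets)) {
    expression <- if (!is.null(config$expression) &&
                      isTRUE(fl$expression_covariate)) {
      e <- readExpression(config$expression)
      setNames(e$median_tpm, e$gene_id)
    } else NULL
    setRes <- stage("geneset_test", {
      r <- runGenesetAssociation(geneRes[[focal]], sets,
                                 expression = expression)
      wtsv(r, sprintf("geneset_results_%s.tsv", focal))
      r
    })
  }

  metas <- stage("meta", {
    out <- lapply(comparisons, function(nm) {
      m <- suppressWarnings(pairwiseMeta(
        geneRes[[focal]], geneRes[[nm]],
        totalN(ssList[[focal]]), totalN(ssList[[nm]]),
        alpha = th$alpha))
      wtsv(m, sprintf("meta_%s_%s.tsv", focal, nm))
      m
    })
    names(out) <- comparisons
    out
  })

  report <- stage("classify", {
    cls <- classifyGenes(
      focal = geneRes[[focal]][, c("gene_id", "p")],
      comparisons = lapply(geneRes[comparisons], `[`,
                           c("gene_id", "p")),
      metas = metas, bonf = bonf, nominal = th$nominal
    )
    wtsv(cls$genes, "classification.tsv")
    cls
  })

  twas <- NULL
  if (isTRUE(fl$run_twas) && !is.null(config$weights)) {
    twas <- stage("twas", {
      w <- readWeights(config$weights)
      tw <- runTwas(w, ssList[[focal]], panel)
      tw <- conditionalTwas(tw, panel, window = th$locus_window)
      wtsv(tw, sprintf("twas_%s.tsv", focal))
      tw
    })
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("pleioGene")),
    seed = config$seed,
    focal = focal,
    comparisons = comparisons,
    n_genes_tested = nGenes,
    bonferroni = bonf,
    nominal = th$nominal,
    counts = report$counts,
    timings = timings
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(gene_results = geneRes, geneset_results = setRes,
                 metas = metas, classification = report, twas = twas,
                 summary = summary))
}
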