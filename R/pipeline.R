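#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom utils packageVersion
NULL

.pipelineCallConfig <- function(cfg) {
  cc <- cfg$call
  if (is.null(cc)) return(CallConfig())
  CallConfig(
    megFractionThreshold = cc$meg_fraction_threshold %||% 0.8,
    pegFractionThreshold = cc$peg_fraction_threshold %||% 0.6,
    minReads = cc$min_reads %||% 5L,
    alpha = cc$alpha %||% 0.05,
    expectedMaternalRatio = cc$expected_maternal_ratio %||% (2 / 3),
    correction = cc$correction %||% "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkInputsExist <- function(cfg, base) {
  missing <- character()
  chk <- function(p) {
    if (is.null(p)) return(invisible())
    fp <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(fp)) missing <<- c(missing, p)
  }
  for (cond in cfg$conditions) {
    if (!is.null(cond$simulation)) next
    chk(cond$cross1); chk(cond$cross2)
    chk(cond$snp_counts_cross1); chk(cond$snp_counts_cross2)
    chk(cond$snp_table)
  }
  chk(cfg$expression$matrix); chk(cfg$expression$metadata)
  chk(cfg$contamination$table)
  if (length(missing))
    stop("pipeline input file(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.resolvePath <- function(p, base)
  if (file.exists(p)) p else file.path(base, p)

# load or simulate one condition's two gene-count tables
.loadCondition <- function(cond, name, base, seed) {
  if (!is.null(cond$simulation)) {
    s <- cond$simulation
    cfg <- SimConfig(nGenes = s$n_genes %||% 1000L,
                     fracMeg = s$frac_meg %||% 0,
                     fracPeg = s$frac_peg %||% 0,
                     megMaternalFraction = s$meg_maternal_fraction %||% 0.95,
                     pegMaternalFraction = s$peg_maternal_fraction %||% 0.15,
                     depthRange = as.integer(s$depth_range %||% c(20L, 200L)),
                     overdispersion = s$overdispersion %||% 0,
                     seed = s$seed %||% seed)
    sim <- simulateAllelicCounts(cfg)
    return(list(cross1 = sim$cross1, cross2 = sim$cross2,
                truth = sim$truth))
  }
  if (!is.null(cond$cross1)) {
    return(list(cross1 = readGeneCounts(.resolvePath(cond$cross1, base)),
                cross2 = readGeneCounts(.resolvePath(cond$cross2, base)),
                truth = NULL))
  }
  if (is.null(cond$snp_counts_cross1) || is.null(cond$snp_table))
    stop("condition '", name, "' needs either a simulation block, ",
         "gene-count tables (cross1/cross2), or per-SNP counts plus a ",
         "snp_table", call. = FALSE)
  snpTable <- readSnpTable(.resolvePath(cond$snp_table, base))
  refParent <- cond$ref_parent %||% "Col"
  mk <- function(path, mother, father) {
    cnt <- readSnpCounts(.resolvePath(path, base))
    aggregateGeneCounts(orientCounts(cnt, CrossDirection(mother, father),
                                     refParent = refParent), snpTable)
  }
  alt <- cond$alt_parent %||% "Cvi"
  list(cross1 = mk(cond$snp_counts_cross1, refParent, alt),
       cross2 = mk(cond$snp_counts_cross2, alt, refParent),
       truth = NULL)
}

#' Run the full imprinting analysis pipeline
#'
#' Orchestrates counting, imprinting calling, condition-specific set logic,
#' expression clustering / dormancy classification, and contamination QC from
#' one structured configuration, writing per-stage TSVs and a machine-readable
#' \code{report.json} that echoes the configuration and every filter tally.
#'
#' The configuration (YAML file or an equivalent nested list) names, per
#' condition under \code{conditions}, either per-gene count tables
#' (\code{cross1}/\code{cross2}), per-SNP counts plus a \code{snp_table}, or
#' a \code{simulation} block mirroring [SimConfig]; optional top-level blocks
#' \code{call} (thresholds, see [CallConfig]), \code{expression}
#' (\code{matrix}, \code{metadata}, \code{reference}, \code{k},
#' \code{kmeans_seed}) and \code{contamination} (a TSV with columns
#' \code{gene_id}, \code{reads_testa}, \code{reads_endosperm}). Relative
#' paths are resolved against the config file's directory. Input files are
#' checked before any computation starts.
#'
#' @param config path to a YAML config file, or a nested list.
#' @param outDir output directory (created if needed).
#' @param seed default seed for stochastic stages lacking their own.
#' @return the report, invisibly (also written to
#'   \code{file.path(outDir, "report.json")}).
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    cfg <- read_yaml(config)
  } else {
    base <- "."
    cfg <- config
  }
  if (is.null(cfg$conditions) || !length(cfg$conditions))
    stop("config must define at least one condition under 'conditions'",
         call. = FALSE)
  seed <- as.integer(cfg$seed %||% seed)
  .checkInputsExist(cfg, base)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir, call. = FALSE)

  callCfg <- .pipelineCallConfig(cfg)
  report <- list(
    package = "endoimprint",
    version = as.character(packageVersion("endoimprint")),
    seed = seed,
    config = cfg,
    stages = list())

  results <- list()
  for (name in names(cfg$conditions)) {
    dat <- .loadCondition(cfg$conditions[[name]], name, base, seed)
    res <- callImprinting(dat$cross1, dat$cross2, config = callCfg,
                          condition = name)
    results[[name]] <- res
    tab <- as.data.frame(calls(res))
    write.table(tab, file.path(outDir, paste0("calls_", name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(megs(res), file.path(outDir, paste0("megs_", name, ".txt")))
    writeLines(pegs(res), file.path(outDir, paste0("pegs_", name, ".txt")))
    clsTab <- table(factor(tab$class,
                           levels = c("MEG", "PEG", "biallelic", "low_reads")))
    message("condition ", name, ": ", nrow(tab), " genes callable; ",
            clsTab[["low_reads"]], " filtered for low reads")
    report$stages[[name]] <- list(
      genes_called = nrow(tab),
      megs = clsTab[["MEG"]], pegs = clsTab[["PEG"]],
      biallelic = clsTab[["biallelic"]],
      low_reads = clsTab[["low_reads"]])
  }

  if (length(results) >= 2L) {
    nm <- names(results)[1:2]
    part <- classifyConditionSpecific(results[[nm[1L]]], results[[nm[2L]]])
    write.table(part$sizes, file.path(outDir, "condition_partition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$condition_partition <- stats::setNames(
      as.list(part$sizes$n), paste(part$sizes$set, part$sizes$partition,
                                   sep = "_"))
    message("condition partition (", nm[1L], " vs ", nm[2L], "): ",
            paste(paste(part$sizes$set, part$sizes$partition,
                        part$sizes$n), collapse = "; "))
  }

  if (!is.null(cfg$expression)) {
    ex <- cfg$expression
    se <- readExpressionMatrix(.resolvePath(ex$matrix, base),
                               .resolvePath(ex$metadata, base))
    ref <- ex$reference %||% "ColxCvi"
    nGenesIn <- nrow(se)
    rel <- relativeToReference(se, ref)
    cl <- kmeansCluster(rel, k = ex$k %||% 3L,
                        seed = ex$kmeans_seed %||% 17L)
    relMat <- assay(rel, "fpkm")
    ord <- match(.DORMANCY_ORDER, colData(rel)$genotype)
    dorm <- if (!anyNA(ord))
      dormancyCorrelationClass(relMat[, ord, drop = FALSE])
    else rep(NA_character_, nrow(relMat))
    out <- data.frame(gene_id = rownames(relMat),
                      cluster = assignments(cl),
                      dormancy_class = dorm)
    write.table(out, file.path(outDir, "expression_clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$expression <- list(
      genes_in = nGenesIn,
      genes_clustered = nrow(relMat),
      dropped_zero_reference = nGenesIn - nrow(relMat),
      k = cl@k,
      cluster_sizes = as.list(stats::setNames(
        tabulate(assignments(cl), nbins = cl@k),
        rownames(centroids(cl)))),
      negative_dormancy_correlation = sum(dorm == "negative", na.rm = TRUE))
    message("expression: ", nrow(relMat), " genes clustered into ", cl@k,
            " clusters; ", nGenesIn - nrow(relMat),
            " dropped for zero reference")
  }

  if (!is.null(cfg$contamination)) {
    qc <- read.table(.resolvePath(cfg$contamination$table, base),
                     header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    qc$contamination_pct <- contaminationFraction(qc$reads_testa,
                                                  qc$reads_endosperm)
    write.table(qc, file.path(outDir, "contamination_qc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$contamination <- list(
      genes = nrow(qc),
      max_contamination_pct = max(qc$contamination_pct))
    message("contamination QC: max ",
            format(max(qc$contamination_pct), digits = 3), "% over ",
            nrow(qc), " gene(s)")
  }

  write_json(report, file.path(outDir, "report.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
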