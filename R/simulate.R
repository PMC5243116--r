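#' @importFrom stats rbinom rbeta rnorm runif rmultinom rpois
NULL

.simGeneIds <- function(n) sprintf("gene%05d", seq_len(n))

#' Simulate reciprocal-cross per-gene allelic counts with known truth
#'
#' Emulates the count structure of endosperm allele-specific RNA-seq in a
#' reciprocal cross: every biallelic gene samples maternal reads at the
#' triploid dosage proportion 2/3 of its per-cross depth, planted MEGs and
#' PEGs at their configured maternal proportions (same truth label and
#' proportion in both cross directions). Depth is drawn uniformly per gene
#' and cross from \code{depthRange}; with \code{overdispersion > 0} the
#' per-gene, per-cross maternal proportion is Beta-distributed around the
#' class mean (beta-binomial counts). One global RNG stream is seeded once,
#' so results are byte-identical across runs for a fixed seed.
#'
#' @param config a [SimConfig].
#' @return a list with per-gene count data.frames \code{cross1} (ColxCvi) and
#'   \code{cross2} (CvixCol) in the [readGeneCounts()] layout, and
#'   \code{truth}: gene id, planted class, true maternal fraction and the
#'   drawn depths.
#' @examples
#' sim <- simulateAllelicCounts(SimConfig(nGenes = 100, fracMeg = 0.1,
#'                                        seed = 42))
#' table(sim$truth$class)
#' @export
simulateAllelicCounts <- function(config = SimConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nGenes
  u <- runif(n)
  class <- ifelse(u < config@fracMeg, "MEG",
                  ifelse(u < config@fracMeg + config@fracPeg, "PEG",
                         "biallelic"))
  theta <- c(MEG = config@megMaternalFraction,
             PEG = config@pegMaternalFraction,
             biallelic = config@nullMaternalFraction)[class]
  depths <- seq.int(config@depthRange[1L], config@depthRange[2L])
  drawCross <- function(label) {
    depth <- depths[sample.int(length(depths), n, replace = TRUE)]
    p <- theta
    if (config@overdispersion > 0) {
      conc <- 1 / config@overdispersion
      p <- rbeta(n, theta * conc, (1 - theta) * conc)
    }
    maternal <- rbinom(n, depth, p)
    data.frame(gene_id = .simGeneIds(n),
               cross = label,
               maternal_reads = maternal,
               paternal_reads = depth - maternal,
               n_snps = 1L)
  }
  cross1 <- drawCross("ColxCvi")
  cross2 <- drawCross("CvixCol")
  truth <- data.frame(gene_id = .simGeneIds(n),
                      class = unname(class),
                      true_maternal_fraction = unname(theta),
                      depth_cross1 = cross1$maternal_reads +
                        cross1$paternal_reads,
                      depth_cross2 = cross2$maternal_reads +
                        cross2$paternal_reads)
  list(cross1 = cross1, cross2 = cross2, truth = truth)
}

#' Default cluster profiles for the genotype-ordered expression panel
#'
#' Three well-separated relative-expression centroids over the genotypes
#' (Cvi, CvixCol, ColxCvi, Col), normalized to the ColxCvi reference: one
#' strictly increasing along decreasing dormancy (the negatively
#' dormancy-correlated shape), one decreasing, one flat.
#'
#' @return a named list of clusters, each with a 4-value \code{centroid} and
#'   a gene \code{share}.
#' @export
defaultClusterSpec <- function() {
  list(
    cluster1 = list(centroid = c(0.25, 0.5, 1, 2), share = 0.45),
    cluster2 = list(centroid = c(4, 2, 1, 0.5), share = 0.30),
    cluster3 = list(centroid = c(1, 1, 1, 1), share = 0.25))
}

#' Simulate a genotype-ordered expression panel with planted clusters
#'
#' Generates relative expression for the four dormancy-ranked genotypes
#' (columns Cvi, CvixCol, ColxCvi, Col, most to least dormant). Each gene is
#' assigned to a cluster according to the spec's shares and takes its
#' centroid profile times multiplicative log-normal noise
#' (\code{exp(rnorm(0, noiseSd))} per value); \code{noiseSd = 0} reproduces
#' the centroids exactly.
#'
#' @param nGenes number of genes.
#' @param clusterSpec list of clusters with \code{centroid} (4 positive
#'   values) and \code{share}; shares must sum to 1. See
#'   [defaultClusterSpec()].
#' @param noiseSd standard deviation of the log-normal noise on the log
#'   scale (default 0.05).
#' @param seed RNG seed.
#' @return a list with \code{se}, a \code{SummarizedExperiment} (assay
#'   \code{fpkm}, colData genotype / dormancy_rank), and \code{truth}, a
#'   data.frame of planted cluster labels.
#' @examples
#' panel <- simulateExpressionPanel(nGenes = 30, noiseSd = 0, seed = 1)
#' assay(panel$se)[1:3, ]
#' @export
simulateExpressionPanel <- function(nGenes = 300L,
                                    clusterSpec = defaultClusterSpec(),
                                    noiseSd = 0.05, seed = 1L) {
  shares <- vapply(clusterSpec, function(cl) cl$share, numeric(1L))
  if (abs(sum(shares) - 1) > 1e-8)
    stop("cluster shares must sum to 1", call. = FALSE)
  cents <- lapply(clusterSpec, function(cl) {
    if (length(cl$centroid) != 4L || any(cl$centroid <= 0))
      stop("each centroid needs 4 positive values (Cvi, CvixCol, ColxCvi, ",
           "Col)", call. = FALSE)
    cl$centroid
  })
  if (noiseSd < 0)
    stop("noiseSd must be non-negative", call. = FALSE)
  set.seed(seed)
  sizes <- diff(round(cumsum(c(0, shares)) * nGenes))
  labels <- rep(names(clusterSpec), sizes)
  mat <- do.call(rbind, lapply(cents, function(x)
    matrix(x, nrow = 1L)))[match(labels, names(clusterSpec)), , drop = FALSE]
  noise <- matrix(exp(rnorm(length(mat), sd = noiseSd)),
                  nrow = nrow(mat))
  mat <- mat * noise
  dimnames(mat) <- list(.simGeneIds(nGenes), .DORMANCY_ORDER)
  se <- SummarizedExperiment(
    assays = list(fpkm = mat),
    colData = DataFrame(sample = .DORMANCY_ORDER,
                        genotype = .DORMANCY_ORDER,
                        condition = "dormant",
                        dormancy_rank = 4:1,
                        library_size = 1e6,
                        row.names = .DORMANCY_ORDER))
  list(se = se,
       truth = data.frame(gene_id = rownames(mat), cluster = labels,
                          row.names = NULL))
}

#' Write the full synthetic fixture set as plain-text TSV files
#'
#' Generates, from one seeded configuration, every table the pipeline readers
#' consume: a SNP table (1-3 diagnostic SNPs per gene), per-SNP Col/Cvi
#' allele counts for both cross directions consistent with the simulated
#' per-gene totals (gene reads split multinomially over the gene's SNPs, a
#' sprinkle of \code{other_reads} that match neither allele), the per-gene
#' count tables, a genotype-ordered expression panel with sample metadata,
#' and the truth labels.
#'
#' @param dir output directory (created if needed).
#' @param config a [SimConfig] driving the allelic simulation.
#' @param panelGenes,noiseSd expression-panel size and noise
#'   ([simulateExpressionPanel()]); the panel seed is derived from
#'   \code{config@seed}.
#' @return named character vector of the written file paths, invisibly.
#' @export
writeFixtures <- function(dir, config = SimConfig(nGenes = 200L, seed = 1L),
                          panelGenes = 120L, noiseSd = 0.05) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir, call. = FALSE)
  sim <- simulateAllelicCounts(config)
  n <- config@nGenes
  set.seed(config@seed + 1L)
  nsnp <- sample(1:3, n, replace = TRUE)
  snp <- data.frame(
    chrom = paste0("Chr", (seq_len(sum(nsnp)) %% 5L) + 1L),
    pos = seq_len(sum(nsnp)) * 100L,
    col_allele = sample(c("A", "C", "G", "T"), sum(nsnp), replace = TRUE),
    gene_id = rep(.simGeneIds(n), nsnp))
  snp$cvi_allele <- vapply(snp$col_allele, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  snp <- snp[, c("chrom", "pos", "col_allele", "cvi_allele", "gene_id")]

  splitOverSnps <- function(total, s) {
    if (s == 1L) return(total)
    as.integer(rmultinom(1L, total, rep(1 / s, s)))
  }
  perSnpCounts <- function(gc, motherIsRef) {
    rows <- lapply(seq_len(n), function(i) {
      s <- nsnp[i]
      m <- splitOverSnps(gc$maternal_reads[i], s)
      p <- splitOverSnps(gc$paternal_reads[i], s)
      if (motherIsRef) cbind(col = m, cvi = p) else cbind(col = p, cvi = m)
    })
    ab <- do.call(rbind, rows)
    data.frame(library_id = gc$cross[1L],
               chrom = snp$chrom, pos = snp$pos,
               col_reads = ab[, "col"], cvi_reads = ab[, "cvi"],
               other_reads = rpois(nrow(ab), 0.1))
  }
  snpCounts1 <- perSnpCounts(sim$cross1, motherIsRef = TRUE)
  snpCounts2 <- perSnpCounts(sim$cross2, motherIsRef = FALSE)
  # per-gene n_snps now reflects the SNPs the counts are spread over
  sim$cross1$n_snps <- nsnp
  sim$cross2$n_snps <- nsnp

  panel <- simulateExpressionPanel(nGenes = panelGenes, noiseSd = noiseSd,
                                   seed = config@seed + 2L)
  paths <- c(
    snp_table = "snp_table.tsv",
    snp_counts_cross1 = "snp_counts_ColxCvi.tsv",
    snp_counts_cross2 = "snp_counts_CvixCol.tsv",
    gene_counts_cross1 = "gene_counts_ColxCvi.tsv",
    gene_counts_cross2 = "gene_counts_CvixCol.tsv",
    expression_matrix = "expression_matrix.tsv",
    sample_metadata = "sample_metadata.tsv",
    truth_allelic = "truth_allelic.tsv",
    truth_expression = "truth_expression.tsv")
  paths <- vapply(paths, function(f) file.path(dir, f), character(1L))
  wt <- function(df, path)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(snp, paths["snp_table"])
  wt(snpCounts1, paths["snp_counts_cross1"])
  wt(snpCounts2, paths["snp_counts_cross2"])
  wt(sim$cross1, paths["gene_counts_cross1"])
  wt(sim$cross2, paths["gene_counts_cross2"])
  writeExpressionMatrix(panel$se, paths["expression_matrix"],
                        paths["sample_metadata"])
  wt(sim$truth, paths["truth_allelic"])
  wt(panel$truth, paths["truth_expression"])
  invisible(paths)
}
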