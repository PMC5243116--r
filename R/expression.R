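#' @importFrom stats kmeans cor setNames
NULL

# canonical genotype order, most dormant first
.DORMANCY_ORDER <- c("Cvi", "CvixCol", "ColxCvi", "Col")

#' Fragments per kilobase of exon per million mapped fragments
#'
#' @param fragmentCount fragments assigned to the gene (vectorized).
#' @param exonicLengthBp exonic length in bp (> 0).
#' @param totalMappedFragments library size in mapped fragments (> 0).
#' @return FPKM = fragmentCount * 1e9 / (exonicLengthBp * totalMappedFragments).
#' @examples
#' fpkm(1000, 1000, 1e6)   # 1000
#' @export
fpkm <- function(fragmentCount, exonicLengthBp, totalMappedFragments) {
  if (any(exonicLengthBp <= 0))
    stop("exonic length must be positive", call. = FALSE)
  if (any(totalMappedFragments <= 0))
    stop("total mapped fragments must be positive", call. = FALSE)
  fragmentCount * 1e9 / (exonicLengthBp * totalMappedFragments)
}

#' Read / write an expression matrix with sample metadata
#'
#' The matrix is a TSV with gene ids in the first column (\code{gene_id}) and
#' one column per sample; the sidecar metadata TSV has columns
#' \code{sample, genotype, condition, dormancy_rank, library_size}.
#'
#' @param file expression matrix path.
#' @param metadataFile sample metadata path.
#' @return \code{readExpressionMatrix}: a \code{SummarizedExperiment} with
#'   assay \code{fpkm} and the metadata as \code{colData}.
#' @export
readExpressionMatrix <- function(file, metadataFile) {
  df <- read.table(file, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "gene_id")
    stop("expression matrix must have gene_id as its first column",
         call. = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$gene_id
  md <- read.table(metadataFile, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "condition", "dormancy_rank", "library_size")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("sample metadata is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!setequal(md$sample, colnames(mat)))
    stop("metadata samples do not match expression matrix columns",
         call. = FALSE)
  md <- md[match(colnames(mat), md$sample), ]
  if (any(mat < 0))
    stop("expression values must be non-negative", call. = FALSE)
  SummarizedExperiment(assays = list(fpkm = mat),
                       colData = DataFrame(md, row.names = md$sample))
}

#' @param se a \code{SummarizedExperiment} with assay \code{fpkm}.
#' @param metadataFile path for the sidecar sample metadata TSV.
#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(se, file, metadataFile) {
  mat <- assay(se, "fpkm")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- as.data.frame(colData(se))
  write.table(md, metadataFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Express a matrix relative to a reference sample
#'
#' Divides every gene's values by its value in the reference sample, so the
#' reference column becomes all ones. Genes with a zero reference value are
#' dropped with a warning.
#'
#' @param x a genes x samples numeric matrix, or a
#'   \code{SummarizedExperiment} with assay \code{fpkm}.
#' @param reference name of the reference sample/column.
#' @return an object of the same kind as \code{x}, values relative to the
#'   reference.
#' @examples
#' m <- matrix(c(2, 4, 8), 1, dimnames = list("g1", c("a", "b", "c")))
#' relativeToReference(m, "a")
#' @export
relativeToReference <- function(x, reference) {
  isSE <- is(x, "SummarizedExperiment")
  mat <- if (isSE) assay(x, "fpkm") else x
  if (!reference %in% colnames(mat))
    stop("reference sample '", reference, "' not found", call. = FALSE)
  zero <- mat[, reference] == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with a zero reference value were dropped",
            call. = FALSE)
    mat <- mat[!zero, , drop = FALSE]
    if (isSE) x <- x[!zero, ]
  }
  rel <- mat / mat[, reference]
  if (isSE) {
    SummarizedExperiment::assay(x, "fpkm") <- rel
    x
  } else rel
}

#' K-means clustering of (relative) expression profiles
#'
#' Deterministic for a fixed seed: the best of \code{restarts} random
#' initializations by within-cluster sum of squares is kept. When the matrix
#' has fewer distinct rows than \code{k}, the distinct rows are clustered
#' (one cluster each) and duplicates inherit the lowest matching cluster
#' index, so identical profiles always share a label.
#'
#' @param x genes x samples numeric matrix (rownames = gene ids), or a
#'   \code{SummarizedExperiment} with assay \code{fpkm}.
#' @param k number of clusters (default 3).
#' @param seed RNG seed (default 17).
#' @param restarts random initializations (default 25).
#' @return a [ClusterResult-class].
#' @examples
#' m <- rbind(a = c(1, 1), b = c(1.1, 0.9), c = c(10, 10), d = c(9.9, 10.2))
#' assignments(kmeansCluster(m, k = 2, seed = 1))
#' @export
kmeansCluster <- function(x, k = 3L, seed = 17L, restarts = 25L) {
  mat <- if (is(x, "SummarizedExperiment")) assay(x, "fpkm") else x
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("gene", seq_len(nrow(mat)))
  k <- as.integer(k)
  if (k < 1L)
    stop("k must be at least 1", call. = FALSE)
  if (k > nrow(mat))
    stop("k (", k, ") exceeds the number of genes (", nrow(mat), ")",
         call. = FALSE)
  keyRow <- apply(mat, 1L, paste, collapse = "\r")
  uniq <- !duplicated(keyRow)
  umat <- mat[uniq, , drop = FALSE]
  set.seed(seed)
  if (nrow(umat) <= k) {
    # fewer distinct profiles than clusters: one cluster per distinct row
    uassign <- seq_len(nrow(umat))
    cent <- umat
    twss <- 0
  } else {
    km <- kmeans(umat, centers = k, nstart = restarts, iter.max = 100L)
    uassign <- km$cluster
    cent <- km$centers
    twss <- km$tot.withinss
  }
  assign <- uassign[match(keyRow, keyRow[uniq])]
  names(assign) <- rownames(mat)
  if (nrow(cent) < k) {
    pad <- matrix(NA_real_, k - nrow(cent), ncol(cent))
    cent <- rbind(cent, pad)
  }
  rownames(cent) <- paste0("cluster", seq_len(k))
  new("ClusterResult", assignments = as.integer(assign) |>
        setNames(rownames(mat)),
      k = k, centroids = as.matrix(cent), seed = as.integer(seed),
      totWithinSS = twss)
}

#' Classify expression against the seed-dormancy genotype ranking
#'
#' Seed dormancy decreases along the genotype order Cvi > CvixCol F1 >
#' ColxCvi F1 > Col. A gene is classified \code{"negative"} (negatively
#' correlated with dormancy) when its expression strictly increases along
#' that order; any other shape is \code{"other"}. The \code{"spearman"}
#' method instead requires Spearman correlation with the dormancy rank at or
#' below \code{rhoThreshold}.
#'
#' @param x numeric vector of 4 values ordered most to least dormant
#'   (Cvi, CvixCol, ColxCvi, Col), or a genes x 4 matrix in that column
#'   order.
#' @param method \code{"monotone"} (default) or \code{"spearman"}.
#' @param rhoThreshold Spearman cutoff for the alternative method
#'   (default -0.8).
#' @return \code{"negative"} or \code{"other"}, one per gene.
#' @examples
#' dormancyCorrelationClass(c(1, 2, 3, 4))   # "negative"
#' dormancyCorrelationClass(c(4, 3, 3, 2))   # "other"
#' @export
dormancyCorrelationClass <- function(x, method = c("monotone", "spearman"),
                                     rhoThreshold = -0.8) {
  method <- match.arg(method)
  mat <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(mat) != 4L)
    stop("expected expression for exactly the 4 dormancy-ranked genotypes (",
         paste(.DORMANCY_ORDER, collapse = ", "), ")", call. = FALSE)
  if (anyNA(mat))
    stop("missing genotype value(s)", call. = FALSE)
  out <- apply(mat, 1L, function(v) {
    neg <- switch(method,
      monotone = all(diff(v) > 0),
      spearman = cor(v, 4:1, method = "spearman") <= rhoThreshold)
    if (isTRUE(neg)) "negative" else "other"
  })
  unname(out)
}

#' Cold-response expression classes
#'
#' Classifies each gene's response to maternal cold treatment during seed
#' development: \code{Down} when cold expression falls below half of control
#' (fold change < 0.5) with p < alpha, \code{Up} when it more than doubles
#' with p < alpha, \code{Unchanged} otherwise. A zero control value with
#' non-zero cold expression yields an infinite fold change, flagged and
#' classified Up when significant.
#'
#' @param exprControl,exprCold expression under control and cold conditions
#'   (vectorized).
#' @param pvalue per-gene differential-expression p-value.
#' @param alpha significance level (default 0.05).
#' @param foldThreshold fold-change cutoff (default 2; Down uses its
#'   reciprocal).
#' @return a \code{DataFrame} with \code{class}, \code{fold_change},
#'   \code{pvalue}.
#' @examples
#' coldResponseClass(10, 3, 0.01)$class    # "Down"
#' coldResponseClass(10, 3, 0.2)$class     # "Unchanged"
#' coldResponseClass(10, 25, 0.01)$class   # "Up"
#' @export
coldResponseClass <- function(exprControl, exprCold, pvalue, alpha = 0.05,
                              foldThreshold = 2) {
  if (any(exprControl < 0 | exprCold < 0))
    stop("expression values must be non-negative", call. = FALSE)
  fc <- ifelse(exprControl > 0, exprCold / exprControl,
               ifelse(exprCold > 0, Inf, NA_real_))
  if (any(is.infinite(fc)))
    warning(sum(is.infinite(fc)),
            " gene(s) with zero control expression: infinite fold change",
            call. = FALSE)
  cls <- rep("Unchanged", length(fc))
  sig <- !is.na(pvalue) & pvalue < alpha
  cls[sig & !is.na(fc) & fc < 1 / foldThreshold] <- "Down"
  cls[sig & !is.na(fc) & fc > foldThreshold] <- "Up"
  DataFrame(class = cls, fold_change = fc, pvalue = pvalue)
}

#' Simplified exact-test differential expression between two libraries
#'
#' A deliberately simple surrogate for a full differential-expression engine,
#' intended for synthetic-data exercises and the cold-response classes: the
#' log2 fold change of library-size-normalized counts (pseudocount 0.5) and a
#' two-tailed exact test on the 2x2 table
#' \code{[countsA, libsizeA - countsA; countsB, libsizeB - countsB]}.
#'
#' @param countsA,countsB gene counts in the two libraries.
#' @param libsizeA,libsizeB total mapped fragments per library.
#' @return a list with \code{log2_fold_change} (A over B) and \code{pvalue}.
#' @examples
#' deTest(100, 100, 1e6, 1e6)$log2_fold_change   # 0
#' deTest(100, 0, 1e6, 1e6)$pvalue < 1e-10
#' @export
deTest <- function(countsA, countsB, libsizeA, libsizeB) {
  stopifnot(length(countsA) == length(countsB))
  if (any(libsizeA <= 0 | libsizeB <= 0))
    stop("library sizes must be positive", call. = FALSE)
  if (any(countsA < 0 | countsB < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(countsA > libsizeA | countsB > libsizeB))
    stop("counts cannot exceed library size", call. = FALSE)
  lfc <- log2(((countsA + 0.5) / libsizeA) / ((countsB + 0.5) / libsizeB))
  n <- length(countsA)
  la <- rep_len(libsizeA, n)
  lb <- rep_len(libsizeB, n)
  pv <- vapply(seq_len(n), function(i) {
    k <- countsA[i] + countsB[i]
    if (k == 0) return(1)
    d <- dhyper(0:k, la[i], lb[i], k)
    .sumSmallMasses(d, d[countsA[i] + 1L])
  }, numeric(1L))
  list(log2_fold_change = lfc, pvalue = pv)
}

#' Testa contamination as a percentage of endosperm signal
#'
#' Read support for a candidate MEG in the dead maternal seed coat (testa),
#' expressed as a percentage of its read count in dissected endosperm. Values
#' comfortably below a few percent indicate the maternal bias is not seed-coat
#' RNA carry-over.
#'
#' @param readsTesta read count in the testa library.
#' @param readsEndosperm read count in the endosperm library (> 0).
#' @return 100 * readsTesta / readsEndosperm.
#' @examples
#' contaminationFraction(9, 603)    # ~1.49
#' contaminationFraction(3, 2154)   # ~0.14
#' @export
contaminationFraction <- function(readsTesta, readsEndosperm) {
  if (any(readsEndosperm <= 0))
    stop("endosperm read count must be positive", call. = FALSE)
  if (any(readsTesta < 0))
    stop("testa read count must be non-negative", call. = FALSE)
  100 * readsTesta / readsEndosperm
}
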