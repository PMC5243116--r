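#' @importFrom stats dhyper dbinom p.adjust
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' Gene-level reciprocal-cross allelic counts
#'
#' A \code{SummarizedExperiment} subclass holding per-gene maternal and
#' paternal read totals for the two directions of a reciprocal cross: assays
#' \code{maternal}, \code{paternal} and \code{nSnps} over genes (rows) and
#' cross directions (columns).
#'
#' @param cross1,cross2 per-gene count data.frames for the two cross
#'   directions, as returned by [aggregateGeneCounts()] or
#'   [readGeneCounts()]. Only genes present in both crosses are retained
#'   (a message reports how many were dropped).
#' @return an \code{AllelicCountSet}.
#' @examples
#' gc1 <- data.frame(gene_id = "g1", cross = "ColxCvi",
#'                   maternal_reads = 95L, paternal_reads = 5L, n_snps = 3L)
#' gc2 <- data.frame(gene_id = "g1", cross = "CvixCol",
#'                   maternal_reads = 90L, paternal_reads = 10L, n_snps = 3L)
#' AllelicCountSet(gc1, gc2)
#' @export AllelicCountSet
#' @exportClass AllelicCountSet
setClass("AllelicCountSet", contains = "SummarizedExperiment")

setValidity("AllelicCountSet", function(object) {
  msg <- character()
  need <- c("maternal", "paternal", "nSnps")
  miss <- setdiff(need, SummarizedExperiment::assayNames(object))
  if (length(miss))
    return(paste("missing assay(s):", paste(miss, collapse = ", ")))
  for (a in need)
    if (any(assay(object, a) < 0))
      msg <- c(msg, paste("assay", a, "has negative values"))
  if (!"cross" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'cross' column")
  else if (anyDuplicated(colData(object)$cross))
    msg <- c(msg, "cross labels must be distinct")
  if (length(msg)) msg else TRUE
})

AllelicCountSet <- function(cross1, cross2) {
  for (df in list(cross1, cross2))
    stopifnot(all(c("gene_id", "cross", "maternal_reads",
                    "paternal_reads", "n_snps") %in% colnames(df)))
  lab1 <- if (nrow(cross1)) cross1$cross[1L] else "cross1"
  lab2 <- if (nrow(cross2)) cross2$cross[1L] else "cross2"
  if (identical(lab1, lab2))
    stop("the two tables must come from opposite cross directions",
         call. = FALSE)
  common <- intersect(cross1$gene_id, cross2$gene_id)
  dropped <- length(union(cross1$gene_id, cross2$gene_id)) - length(common)
  if (dropped)
    message(dropped, " gene(s) detected in only one cross direction were ",
            "dropped (uncallable)")
  common <- sort(common)
  i1 <- match(common, cross1$gene_id)
  i2 <- match(common, cross2$gene_id)
  mk <- function(v1, v2) {
    m <- cbind(v1, v2)
    dimnames(m) <- list(common, c(lab1, lab2))
    m
  }
  se <- SummarizedExperiment(
    assays = list(
      maternal = mk(cross1$maternal_reads[i1], cross2$maternal_reads[i2]),
      paternal = mk(cross1$paternal_reads[i1], cross2$paternal_reads[i2]),
      nSnps = mk(cross1$n_snps[i1], cross2$n_snps[i2])),
    colData = DataFrame(cross = c(lab1, lab2)))
  new("AllelicCountSet", se)
}

#' Maternal read fraction
#'
#' \code{maternal / (maternal + paternal)}. In triploid endosperm the
#' biallelic expectation is 2/3.
#'
#' @param maternal,paternal non-negative read counts (vectorized).
#' @return the maternal fraction in [0, 1].
#' @examples
#' maternalFraction(10, 5)   # 2/3
#' @export
maternalFraction <- function(maternal, paternal) {
  total <- maternal + paternal
  if (any(total == 0))
    stop("maternal fraction undefined for zero total reads; filter first",
         call. = FALSE)
  maternal / total
}

# two-sided exact p as the sum of point masses no larger than the observed
# one; the 1e-7 relative slack guards against ties lost to floating point
.sumSmallMasses <- function(d, dobs) {
  sel <- d <= dobs * (1 + 1e-7)
  if (all(sel)) return(1)
  min(1, sum(d[sel]))
}

#' Fisher exact test against an expected maternal:paternal ratio
#'
#' Tests the observed (maternal, paternal) counts of one gene in one cross
#' against the counts expected under biallelic expression at
#' \code{expectedMaternalRatio} (2:1 maternal:paternal by default, the
#' triploid endosperm dosage). The 2x2 table contrasts the observed row with
#' an expected row of the same total, \code{round(N * ratio)} maternal
#' (half rounded up); the two-tailed p-value sums all hypergeometric tables
#' with fixed margins whose probability does not exceed the observed table's.
#'
#' @param maternal,paternal non-negative integer counts (vectorized).
#' @param expectedMaternalRatio null maternal proportion (default 2/3).
#' @return p-values in (0, 1]; NA where maternal + paternal == 0.
#' @examples
#' fisherVsExpected(200, 100)   # exactly the 2:1 expectation -> 1
#' fisherVsExpected(95, 5) < 0.05
#' @export
fisherVsExpected <- function(maternal, paternal, expectedMaternalRatio = 2 / 3) {
  stopifnot(length(maternal) == length(paternal))
  if (any(maternal < 0 | paternal < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  n <- maternal + paternal
  vapply(seq_along(n), function(i) {
    if (is.na(n[i]) || n[i] < 1) return(NA_real_)
    e1 <- floor(n[i] * expectedMaternalRatio + 0.5)
    white <- maternal[i] + e1          # column total, maternal side
    black <- 2 * n[i] - white          # column total, paternal side
    lo <- max(0, n[i] - black)
    hi <- min(n[i], white)
    d <- dhyper(lo:hi, white, black, n[i])
    .sumSmallMasses(d, dhyper(maternal[i], white, black, n[i]))
  }, numeric(1L))
}

#' Exact binomial test against an expected maternal proportion
#'
#' Alternative backend to [fisherVsExpected()]: treats the maternal count as
#' binomial(N, ratio) and returns the two-sided small-mass-sum p-value.
#'
#' @inheritParams fisherVsExpected
#' @return p-values in (0, 1]; NA where maternal + paternal == 0.
#' @export
binomVsExpected <- function(maternal, paternal, expectedMaternalRatio = 2 / 3) {
  stopifnot(length(maternal) == length(paternal))
  if (any(maternal < 0 | paternal < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  n <- maternal + paternal
  vapply(seq_along(n), function(i) {
    if (is.na(n[i]) || n[i] < 1) return(NA_real_)
    d <- dbinom(0:n[i], n[i], expectedMaternalRatio)
    .sumSmallMasses(d, d[maternal[i] + 1L])
  }, numeric(1L))
}

# vectorized three-criterion classification; returns a DataFrame
.classify <- function(gene_id, m1, p1, m2, p2, config) {
  t1 <- m1 + p1
  t2 <- m2 + p2
  low <- t1 < config@minReads | t2 < config@minReads | t1 == 0L | t2 == 0L
  f1 <- ifelse(t1 > 0, m1 / t1, NA_real_)
  f2 <- ifelse(t2 > 0, m2 / t2, NA_real_)
  pv1 <- fisherVsExpected(m1, p1, config@expectedMaternalRatio)
  pv2 <- fisherVsExpected(m2, p2, config@expectedMaternalRatio)
  pb1 <- binomVsExpected(m1, p1, config@expectedMaternalRatio)
  pb2 <- binomVsExpected(m2, p2, config@expectedMaternalRatio)
  q1 <- pv1
  q2 <- pv2
  if (config@correction == "BH") {
    q1[!low] <- p.adjust(pv1[!low], method = "BH")
    q2[!low] <- p.adjust(pv2[!low], method = "BH")
  }
  sig <- !is.na(q1) & !is.na(q2) & q1 < config@alpha & q2 < config@alpha
  isMeg <- !low & sig &
    f1 > config@megFractionThreshold & f2 > config@megFractionThreshold
  isPeg <- !low & sig &
    (1 - f1) > config@pegFractionThreshold &
    (1 - f2) > config@pegFractionThreshold
  class <- rep("biallelic", length(gene_id))
  class[isMeg] <- "MEG"
  class[isPeg] <- "PEG"
  class[low] <- "low_reads"
  DataFrame(gene_id = gene_id, class = class,
            maternal_fraction_cross1 = f1, maternal_fraction_cross2 = f2,
            pvalue_cross1 = pv1, pvalue_cross2 = pv2,
            pvalue_binom_cross1 = pb1, pvalue_binom_cross2 = pb2,
            total_reads_cross1 = t1, total_reads_cross2 = t2)
}

#' Classify one gene as MEG, PEG, biallelic or low_reads
#'
#' Applies the three criteria to a single gene's counts in the two reciprocal
#' crosses: (1) the maternal fraction exceeds the MEG threshold in both
#' crosses (or the paternal fraction exceeds the PEG threshold in both);
#' (2) each cross carries at least \code{minReads} informative reads;
#' (3) both exact tests against the 2:1 expectation are significant.
#'
#' @param count1,count2 one-row data.frames (or lists) with \code{gene_id},
#'   \code{maternal_reads}, \code{paternal_reads}, from opposite crosses.
#' @param config a [CallConfig].
#' @return a one-row \code{DataFrame} with the call and its evidence.
#' @examples
#' callGene(list(gene_id = "g", maternal_reads = 95, paternal_reads = 5),
#'          list(gene_id = "g", maternal_reads = 90, paternal_reads = 10))
#' @export
callGene <- function(count1, count2, config = CallConfig()) {
  if (!identical(as.character(count1$gene_id), as.character(count2$gene_id)))
    stop("counts refer to different genes: ", count1$gene_id, " vs ",
         count2$gene_id, call. = FALSE)
  .classify(as.character(count1$gene_id),
            count1$maternal_reads, count1$paternal_reads,
            count2$maternal_reads, count2$paternal_reads, config)
}

#' Call imprinted genes from reciprocal-cross counts
#'
#' Runs the three-criterion MEG/PEG classification over all genes covered in
#' both cross directions.
#'
#' @param x an [AllelicCountSet], or a per-gene count data.frame for the
#'   first cross direction (then \code{cross2} is required).
#' @param cross2 per-gene counts for the opposite cross direction when
#'   \code{x} is a data.frame.
#' @param config a [CallConfig].
#' @param condition label recorded on the result (e.g. \code{"dormant"}).
#' @return an [ImprintingResult-class].
#' @examples
#' sim <- simulateAllelicCounts(SimConfig(nGenes = 200, fracMeg = 0.05,
#'                                        seed = 7))
#' res <- callImprinting(sim$cross1, sim$cross2, condition = "dormant")
#' res
#' megs(res)
#' @export
callImprinting <- function(x, cross2 = NULL, config = CallConfig(),
                           condition = "unspecified") {
  if (is(x, "AllelicCountSet")) {
    acs <- x
  } else {
    if (is.null(cross2))
      stop("cross2 is required when x is a per-gene count table",
           call. = FALSE)
    acs <- AllelicCountSet(x, cross2)
  }
  if (ncol(acs) != 2L)
    stop("imprinting calls need exactly the two reciprocal cross directions",
         call. = FALSE)
  m <- assay(acs, "maternal")
  p <- assay(acs, "paternal")
  gid <- rownames(acs)
  if (is.null(gid)) gid <- character(0)
  tab <- .classify(gid, m[, 1L], p[, 1L], m[, 2L], p[, 2L], config)
  new("ImprintingResult", calls = tab, config = config,
      condition = condition)
}

#' Partition MEG/PEG sets by condition
#'
#' Given the imprinted gene sets called under two conditions (e.g. dormant
#' and non-dormant seeds), splits each of the MEG and PEG catalogs into the
#' condition-specific and shared parts.
#'
#' @param dormant,nondormant [ImprintingResult-class] objects, or lists with
#'   elements \code{megs} and \code{pegs} (character vectors of gene ids).
#' @return a list with elements \code{megs} and \code{pegs}, each a list of
#'   character vectors \code{dormant_specific}, \code{shared},
#'   \code{nondormant_specific}, plus a \code{sizes} data.frame.
#' @examples
#' d <- list(megs = paste0("g", 1:71), pegs = paste0("p", 1:5))
#' n <- list(megs = paste0("g", c(1:14, 72:107)), pegs = paste0("p", 1:2))
#' classifyConditionSpecific(d, n)$sizes
#' @export
classifyConditionSpecific <- function(dormant, nondormant) {
  pick <- function(x) {
    if (is(x, "ImprintingResult")) list(megs = megs(x), pegs = pegs(x))
    else list(megs = as.character(x$megs), pegs = as.character(x$pegs))
  }
  d <- pick(dormant)
  n <- pick(nondormant)
  part <- function(a, b) list(dormant_specific = setdiff(a, b),
                              shared = intersect(a, b),
                              nondormant_specific = setdiff(b, a))
  m <- part(d$megs, n$megs)
  p <- part(d$pegs, n$pegs)
  sizes <- data.frame(
    set = rep(c("MEG", "PEG"), each = 3L),
    partition = rep(c("dormant_specific", "shared", "nondormant_specific"), 2L),
    n = c(lengths(m), lengths(p)))
  list(megs = m, pegs = p, sizes = sizes)
}

#' Log ratio of maternal to duplicated paternal reads
#'
#' \code{log2((maternal + pseudocount) / (2 * paternal + pseudocount))}.
#' Doubling the paternal count puts biallelic genes (2:1 maternal:paternal)
#' at 0, so departures from triploid dosage read directly as the log ratio.
#'
#' @param maternal,paternal non-negative counts (vectorized).
#' @param pseudocount added to numerator and denominator (default 0).
#' @return log2 ratios; exact 2:1 counts give 0 at pseudocount 0.
#' @examples
#' logRatioDuplicatedPaternal(200, 100)       # 0
#' logRatioDuplicatedPaternal(400, 100)       # 1
#' @export
logRatioDuplicatedPaternal <- function(maternal, paternal, pseudocount = 0) {
  if (any(maternal < 0 | paternal < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (pseudocount == 0 && any(maternal == 0 & paternal == 0))
    stop("log ratio undefined for zero counts with pseudocount 0",
         call. = FALSE)
  log2((maternal + pseudocount) / (2 * paternal + pseudocount))
}
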