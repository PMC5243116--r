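#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Cross direction of a reciprocal cross
#'
#' Records which parental genotype was the seed parent (mother) and which the
#' pollen donor (father). In the triploid endosperm the maternal genome is
#' present in two copies and the paternal in one, so orientation of allelic
#' counts to maternal/paternal depends on this object.
#'
#' @slot mother parental genotype label of the seed parent.
#' @slot father parental genotype label of the pollen donor.
#'
#' @examples
#' CrossDirection("Col", "Cvi")
#' @export
setClass("CrossDirection",
         representation(mother = "character", father = "character"))

setValidity("CrossDirection", function(object) {
  msg <- character()
  if (length(object@mother) != 1L || length(object@father) != 1L)
    msg <- c(msg, "mother and father must be single genotype labels")
  else if (identical(object@mother, object@father))
    msg <- c(msg, "mother and father must differ")
  if (length(msg)) msg else TRUE
})

#' @param mother,father single genotype labels, e.g. \code{"Col"}, \code{"Cvi"}.
#' @rdname CrossDirection-class
#' @export
CrossDirection <- function(mother, father) {
  new("CrossDirection", mother = as.character(mother),
      father = as.character(father))
}

#' @describeIn CrossDirection-class compact "MotherxFather" label.
#' @param x a \code{CrossDirection}.
#' @export
crossLabel <- function(x) {
  stopifnot(is(x, "CrossDirection"))
  paste0(x@mother, "x", x@father)
}

setMethod("show", "CrossDirection", function(object) {
  cat("CrossDirection:", crossLabel(object),
      "(mother:", object@mother, "/ father:", object@father, ")\n")
})

#' Configuration of the imprinting caller
#'
#' Thresholds of the three-criterion MEG/PEG classification. A gene is a MEG
#' when its maternal fraction m/(m+p) exceeds \code{megFractionThreshold} in
#' both reciprocal crosses, a PEG when its paternal fraction exceeds
#' \code{pegFractionThreshold} in both crosses, in each case with both exact
#' tests against the expected maternal proportion significant at \code{alpha};
#' genes with fewer than \code{minReads} informative reads in either cross are
#' not called. Ties at the thresholds fail (strictly greater is required).
#'
#' @slot megFractionThreshold maternal-fraction threshold for MEGs (default 0.8).
#' @slot pegFractionThreshold paternal-fraction threshold for PEGs (default 0.6).
#' @slot minReads minimum informative reads (maternal + paternal) per cross
#'   (default 5).
#' @slot alpha per-cross significance level of the exact test (default 0.05).
#' @slot expectedMaternalRatio null maternal proportion; 2/3 is the dosage
#'   expectation for biallelic expression in triploid endosperm.
#' @slot correction p-value adjustment applied across genes within each cross:
#'   \code{"none"} (default) or \code{"BH"}.
#'
#' @examples
#' CallConfig()
#' CallConfig(alpha = 0.01, correction = "BH")
#' @export
setClass("CallConfig",
         representation(megFractionThreshold = "numeric",
                        pegFractionThreshold = "numeric",
                        minReads = "integer",
                        alpha = "numeric",
                        expectedMaternalRatio = "numeric",
                        correction = "character"))

setValidity("CallConfig", function(object) {
  msg <- character()
  inOpen01 <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x < 1
  if (!inOpen01(object@megFractionThreshold))
    msg <- c(msg, "megFractionThreshold must be in (0, 1)")
  if (!inOpen01(object@pegFractionThreshold))
    msg <- c(msg, "pegFractionThreshold must be in (0, 1)")
  if (!inOpen01(object@alpha))
    msg <- c(msg, "alpha must be in (0, 1)")
  if (!inOpen01(object@expectedMaternalRatio))
    msg <- c(msg, "expectedMaternalRatio must be in (0, 1)")
  if (length(object@minReads) != 1L || is.na(object@minReads) ||
      object@minReads < 0L)
    msg <- c(msg, "minReads must be a non-negative integer")
  if (!object@correction %in% c("none", "BH"))
    msg <- c(msg, "correction must be 'none' or 'BH'")
  if (length(msg)) msg else TRUE
})

#' @param megFractionThreshold,pegFractionThreshold,minReads,alpha,expectedMaternalRatio,correction
#'   see the slot descriptions.
#' @rdname CallConfig-class
#' @export
CallConfig <- function(megFractionThreshold = 0.8,
                       pegFractionThreshold = 0.6,
                       minReads = 5L,
                       alpha = 0.05,
                       expectedMaternalRatio = 2 / 3,
                       correction = c("none", "BH")) {
  new("CallConfig",
      megFractionThreshold = megFractionThreshold,
      pegFractionThreshold = pegFractionThreshold,
      minReads = as.integer(minReads),
      alpha = alpha,
      expectedMaternalRatio = expectedMaternalRatio,
      correction = match.arg(correction))
}

setMethod("show", "CallConfig", function(object) {
  cat("CallConfig\n",
      "  MEG maternal fraction  > ", object@megFractionThreshold, "\n",
      "  PEG paternal fraction  > ", object@pegFractionThreshold, "\n",
      "  min reads per cross      ", object@minReads, "\n",
      "  alpha                    ", object@alpha, "\n",
      "  expected maternal ratio  ",
      format(object@expectedMaternalRatio, digits = 4), "\n",
      "  correction               ", object@correction, "\n", sep = "")
})

#' Simulation configuration for reciprocal-cross allelic counts
#'
#' Parameters of the synthetic-data generator. Biallelic genes sample maternal
#' reads at the triploid-endosperm dosage proportion 2/3; planted MEGs and
#' PEGs sample at \code{megMaternalFraction} and \code{pegMaternalFraction}.
#' Per-gene, per-cross sequencing depth is drawn uniformly from
#' \code{depthRange}. With \code{overdispersion > 0} the per-gene maternal
#' proportion is itself drawn from a Beta distribution with the class mean and
#' concentration \code{1/overdispersion} (beta-binomial counts); 0 gives pure
#' binomial sampling.
#'
#' @slot nGenes number of genes to simulate.
#' @slot fracMeg,fracPeg expected proportions of planted MEGs and PEGs.
#' @slot megMaternalFraction true maternal proportion of planted MEGs
#'   (default 0.95).
#' @slot pegMaternalFraction true maternal proportion of planted PEGs
#'   (default 0.15).
#' @slot nullMaternalFraction maternal proportion of biallelic genes
#'   (fixed at 2/3 by default).
#' @slot depthRange integer pair, inclusive bounds of the uniform per-gene
#'   per-cross depth draw.
#' @slot overdispersion non-negative; 0 = binomial, otherwise beta-binomial
#'   with concentration 1/overdispersion.
#' @slot seed integer RNG seed.
#'
#' @examples
#' SimConfig(nGenes = 1000, fracMeg = 0.05, seed = 1)
#' @export
setClass("SimConfig",
         representation(nGenes = "integer",
                        fracMeg = "numeric",
                        fracPeg = "numeric",
                        megMaternalFraction = "numeric",
                        pegMaternalFraction = "numeric",
                        nullMaternalFraction = "numeric",
                        depthRange = "integer",
                        overdispersion = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  prop <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (length(object@nGenes) != 1L || object@nGenes < 1L)
    msg <- c(msg, "nGenes must be a positive integer")
  if (!prop(object@fracMeg) || !prop(object@fracPeg))
    msg <- c(msg, "fracMeg and fracPeg must be proportions in [0, 1]")
  else if (object@fracMeg + object@fracPeg > 1)
    msg <- c(msg, "fracMeg + fracPeg must not exceed 1")
  if (!prop(object@megMaternalFraction) || !prop(object@pegMaternalFraction) ||
      !prop(object@nullMaternalFraction))
    msg <- c(msg, "maternal fractions must be proportions in [0, 1]")
  if (length(object@depthRange) != 2L || any(object@depthRange < 1L) ||
      object@depthRange[1L] > object@depthRange[2L])
    msg <- c(msg, "depthRange must be a positive non-decreasing integer pair")
  if (length(object@overdispersion) != 1L || object@overdispersion < 0)
    msg <- c(msg, "overdispersion must be non-negative")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' @param nGenes,fracMeg,fracPeg,megMaternalFraction,pegMaternalFraction,nullMaternalFraction,depthRange,overdispersion,seed
#'   see the slot descriptions.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nGenes = 1000L,
                      fracMeg = 0,
                      fracPeg = 0,
                      megMaternalFraction = 0.95,
                      pegMaternalFraction = 0.15,
                      nullMaternalFraction = 2 / 3,
                      depthRange = c(20L, 200L),
                      overdispersion = 0,
                      seed = 1L) {
  new("SimConfig",
      nGenes = as.integer(nGenes),
      fracMeg = fracMeg, fracPeg = fracPeg,
      megMaternalFraction = megMaternalFraction,
      pegMaternalFraction = pegMaternalFraction,
      nullMaternalFraction = nullMaternalFraction,
      depthRange = as.integer(depthRange),
      overdispersion = overdispersion,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes;",
      "fracMeg =", object@fracMeg, "; fracPeg =", object@fracPeg, "\n",
      " theta: MEG", object@megMaternalFraction,
      "/ PEG", object@pegMaternalFraction,
      "/ null", format(object@nullMaternalFraction, digits = 4), "\n",
      " depth", object@depthRange[1L], "-", object@depthRange[2L],
      "; overdispersion", object@overdispersion,
      "; seed", object@seed, "\n")
})

#' Result of the imprinting caller
#'
#' Per-gene classifications with the per-cross maternal fractions and exact
#' test p-values that produced them, together with the configuration used.
#' Use \code{calls()} for the full table and \code{megs()} / \code{pegs()}
#' for the gene sets.
#'
#' @slot calls a \code{DataFrame} with one row per gene: \code{gene_id},
#'   \code{class} (MEG / PEG / biallelic / low_reads), per-cross maternal
#'   fractions, Fisher p-values and binomial p-values, per-cross depths.
#' @slot config the \code{CallConfig} used.
#' @slot condition free-text condition label (e.g. "dormant").
#'
#' @seealso [callImprinting()]
#' @export
setClass("ImprintingResult",
         representation(calls = "DataFrame",
                        config = "CallConfig",
                        condition = "character"))

setValidity("ImprintingResult", function(object) {
  msg <- character()
  need <- c("gene_id", "class",
            "maternal_fraction_cross1", "maternal_fraction_cross2",
            "pvalue_cross1", "pvalue_cross2")
  miss <- setdiff(need, colnames(object@calls))
  if (length(miss))
    msg <- c(msg, paste("calls is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@calls) &&
      !all(object@calls$class %in% c("MEG", "PEG", "biallelic", "low_reads")))
    msg <- c(msg, "class must be one of MEG, PEG, biallelic, low_reads")
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single label")
  if (length(msg)) msg else TRUE
})

#' @describeIn ImprintingResult-class the per-gene call table.
#' @param object an \code{ImprintingResult}.
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))

#' @rdname ImprintingResult-class
#' @export
setMethod("calls", "ImprintingResult", function(object) object@calls)

#' @describeIn ImprintingResult-class gene ids called MEG.
#' @export
setGeneric("megs", function(object) standardGeneric("megs"))

#' @rdname ImprintingResult-class
#' @export
setMethod("megs", "ImprintingResult", function(object)
  as.character(object@calls$gene_id[object@calls$class == "MEG"]))

#' @describeIn ImprintingResult-class gene ids called PEG.
#' @export
setGeneric("pegs", function(object) standardGeneric("pegs"))

#' @rdname ImprintingResult-class
#' @export
setMethod("pegs", "ImprintingResult", function(object)
  as.character(object@calls$gene_id[object@calls$class == "PEG"]))

#' @describeIn ImprintingResult-class condition label.
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname ImprintingResult-class
#' @export
setMethod("condition", "ImprintingResult", function(object) object@condition)

setMethod("show", "ImprintingResult", function(object) {
  tab <- table(factor(object@calls$class,
                      levels = c("MEG", "PEG", "biallelic", "low_reads")))
  cat("ImprintingResult (", object@condition, "): ",
      nrow(object@calls), " genes\n", sep = "")
  cat("  MEG: ", tab[["MEG"]], "  PEG: ", tab[["PEG"]],
      "  biallelic: ", tab[["biallelic"]],
      "  low_reads: ", tab[["low_reads"]], "\n", sep = "")
})

#' K-means clustering result
#'
#' @slot assignments named integer vector, gene id -> cluster index in 1..k.
#' @slot k number of clusters requested.
#' @slot centroids k x samples matrix of cluster mean profiles.
#' @slot seed RNG seed used.
#' @slot totWithinSS total within-cluster sum of squares at convergence.
#'
#' @seealso [kmeansCluster()]
#' @export
setClass("ClusterResult",
         representation(assignments = "integer",
                        k = "integer",
                        centroids = "matrix",
                        seed = "integer",
                        totWithinSS = "numeric"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by gene id")
  if (length(object@assignments) &&
      (any(object@assignments < 1L) || any(object@assignments > object@k)))
    msg <- c(msg, "cluster indices must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClusterResult-class gene -> cluster assignments.
#' @param object a \code{ClusterResult}.
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname ClusterResult-class
#' @export
setMethod("assignments", "ClusterResult", function(object) object@assignments)

#' @describeIn ClusterResult-class cluster centroid profiles.
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname ClusterResult-class
#' @export
setMethod("centroids", "ClusterResult", function(object) object@centroids)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, "over",
      length(object@assignments), "genes; sizes:",
      paste(tabulate(object@assignments, nbins = object@k), collapse = "/"),
      "\n")
})
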