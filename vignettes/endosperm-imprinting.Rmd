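---
title: "Calling dormancy-specific genomic imprinting in mature seed endosperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling dormancy-specific genomic imprinting in mature seed endosperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoimprint)
library(SummarizedExperiment)
```

## The problem and the model

The endosperm of a mature Arabidopsis seed is triploid: two genome copies
come from the mother, one from the father. Under ordinary biallelic
expression a gene's transcripts therefore carry maternal and paternal alleles
at a 2:1 ratio, and that ratio — not 1:1 — is the null against which
imprinting must be judged. Genomic imprinting shows up as a reproducible
departure from this dosage expectation that follows the parent of origin, not
the genotype: a maternally expressed imprinted gene (MEG) is maternally
biased in *both* directions of a reciprocal cross between two accessions
(here Col, the reference-genome parent, and Cvi), while a genotype effect
would flip with the cross.

`endoimprint` implements this logic end to end. Reads overlapping diagnostic
SNPs are counted per allele (`readSnpCounts()`), oriented to
maternal/paternal according to the seed parent of each cross
(`orientCounts()` with a `CrossDirection`), and summed over all SNPs in a
gene (`aggregateGeneCounts()`). A gene covered in both cross directions is
then classified by three criteria (`callImprinting()`):

1. **Fraction thresholds.** The maternal fraction $m/(m+p)$ must exceed 0.8
   in both crosses for a MEG; the paternal fraction must exceed 0.6 in both
   crosses for a PEG. The asymmetry reflects the asymmetric null: a MEG must
   clear a bar well above the biallelic expectation of 2/3, while paternal
   bias beyond 0.6 is already far from the biallelic paternal share of 1/3.
   We interpret the thresholds as fractions of total informative reads rather
   than literal ratios $m/p$, because a ratio cutoff of 0.8 would flag the
   biallelic norm itself ($m/p = 2$ at 2:1); both thresholds are
   configurable in `CallConfig`. Ties at the threshold fail (strictly
   greater).
2. **Read floor.** Genes with fewer than 5 informative reads
   (maternal + paternal, per cross) are reported as `low_reads`, not
   classified. The floor is applied per gene per cross; per-SNP or
   per-allele floors are not supported.
3. **Exact test.** The observed counts are tested against the 2:1
   expectation with a two-tailed Fisher exact test: the observed row
   $(m, p)$ against an expected row of the same total $N$ with
   $\mathrm{round}(2N/3)$ maternal reads (half rounded up). The two-tailed
   p-value sums all hypergeometric tables with fixed margins whose
   probability does not exceed the observed table's. Both per-cross
   p-values must fall below $\alpha = 0.05$. No multiple-testing correction
   is applied by default, matching the procedure the caller reproduces; a
   Benjamini–Hochberg option exists (`correction = "BH"`). A binomial exact
   test with success probability 2/3 is computed alongside
   (`pvalue_binom_*` columns) as an alternative backend; classification uses
   the Fisher p-values.

Each cross is tested separately rather than pooled: reciprocal consistency is
the point of the design, and pooling would let a strong bias in one direction
carry a weak one in the other. The pooled alternative is easy to obtain by
summing counts before calling, but it is not the default.

Genes detected in only one cross direction are *uncallable*, not biallelic;
`callImprinting()` drops them with a message and the pipeline logs the count.

## Condition-specific sets and the supporting analyses

Imprinting in mature seeds is condition-dependent: dormant (briefly
after-ripened) and non-dormant (long after-ripened) seeds yield different
MEG/PEG catalogs. `classifyConditionSpecific()` partitions the two catalogs
into condition-specific and shared parts by plain set algebra — given MEG
catalogs of sizes 71 and 50 sharing 14 genes, it returns 57 dormant-specific
and 36 non-dormant-specific MEGs.

Around the caller sit the standard expression-level analyses:

- `fpkm()` — fragments per kilobase of exon per million mapped fragments.
- `relativeToReference()` — per-gene normalization to one sample (the
  ColxCvi endosperm by convention); genes with a zero reference value are
  dropped with a warning since their relative profile is undefined.
- `kmeansCluster()` — K-means on relative profiles via `stats::kmeans`,
  best of `restarts = 25` starts under a fixed seed (default 17), so results
  are reproducible. `k = 3` by default, matching the three profile shapes the
  clustering is meant to separate; it is a free parameter. When the matrix
  has fewer distinct rows than `k`, distinct rows get one cluster each and
  duplicated rows inherit the same label — `stats::kmeans` would otherwise
  error, and any tie-break among identical profiles is arbitrary.
- `dormancyCorrelationClass()` — seed dormancy decreases along the genotype
  order Cvi > CvixCol F1 > ColxCvi F1 > Col, so "expression negatively
  correlated with dormancy" is operationalized as a strictly increasing
  profile along that order. With four values this is deliberately strict:
  exactly 1 of the 24 orderings of distinct values qualifies, so the
  background rate under exchangeable noise is 1/24 ≈ 4%. A Spearman
  alternative (`method = "spearman"`, ρ ≤ −0.8 against the dormancy rank)
  admits near-monotone profiles.
- `coldResponseClass()` — Down / Up / Unchanged by two-fold change with
  p < 0.05, the pie-chart classes of cold-responsive MEG expression. A zero
  control value with non-zero cold signal is classified Up when significant,
  with the infinite fold change flagged.
- `deTest()` — a deliberately simplified differential-expression surrogate
  (log2 fold change of library-size-normalized counts with pseudocount 0.5,
  plus an exact test on the gene-vs-rest 2×2 table). It exists for
  synthetic-data exercises and the cold-response classes and is *not* a
  replacement for a dispersion-aware DE engine on real replicated data.
- `contaminationFraction()` — the seed coat (testa) is dead maternal tissue
  and the obvious artifactual source of "maternal" reads; expressing a
  candidate MEG's testa read count as a percentage of its endosperm count
  makes the QC rule concrete (the two MEGs with any testa reads sit at
  about 1.5% and 0.14%, below the 1–2% band that rules out carry-over as
  the explanation).

## What the simulator emulates — and what it does not

`simulateAllelicCounts()` generates per-gene, per-cross counts under the
study's statistical skeleton: depth drawn uniformly per gene and cross
(default 20–200, spanning the read floor through comfortably powered genes),
maternal reads binomial with θ = 2/3 for biallelic genes, θ = 0.95 for
planted MEGs and θ = 0.15 for planted PEGs — values chosen so planted genes
sit clearly beyond the 0.8/0.6 fraction thresholds, as true imprinted genes
do. The same truth label applies in both crosses, which is precisely what
distinguishes imprinting from genotype bias. An optional beta-binomial mode
(`overdispersion > 0`, Beta concentration 1/overdispersion) adds biological
extra-variance; the default is pure binomial because no dispersion estimate
is available for this tissue. One RNG stream is seeded once per run, so all
outputs are byte-identical for a fixed seed.

`simulateExpressionPanel()` plants cluster structure over the four
dormancy-ranked genotypes: by default one strictly increasing centroid
(0.25, 0.5, 1, 2 — the negatively dormancy-correlated shape), one decreasing
(4, 2, 1, 0.5) and one flat (1, 1, 1, 1), all normalized to the ColxCvi
reference, with multiplicative log-normal noise (σ = 0.05 on the log scale,
small relative to the inter-centroid distances so cluster recovery is a test
of the machinery, not of luck). `writeFixtures()` materializes the whole
fixture set — SNP table, per-SNP counts for both crosses consistent with the
gene totals, gene counts, expression panel, truth labels — as plain TSVs.

What the simulator does **not** model: read-level effects (mapping bias
toward the reference allele, sequencing error, reads spanning several SNPs
of one gene — which the summation over SNPs can double count), SNP-density
variation between genes, library-size differences between crosses, and
correlated gene expression. Passing tests therefore demonstrate that the
caller is calibrated and powerful *given correctly oriented, unbiased
per-SNP counts*; they do not certify robustness to alignment artifacts,
which must be handled upstream.

With these conditions, the suite verifies: type-I calls on 10,000 null
genes stay (far) below 5% — the fraction thresholds plus the reciprocal
requirement compound with the test, so the observed rate is essentially
zero; planted MEGs at depth ≥ 100 are recovered at well over 90% with zero
MEG/PEG confusions; and K-means recovers the planted expression clusters at
adjusted Rand index 1.

## Numerical choices and degenerate inputs

- Exact tests sum point masses ≤ the observed mass with a 1e-7 relative tie
  slack — the same convention as `stats::fisher.test`, against which the
  implementation is verified to 1e-9, alongside an independent
  binomial-coefficient enumeration oracle for every total up to 200.
- The expected maternal count uses round-half-up (`floor(x + 0.5)`), so
  expected rows are reproducible across platforms.
- Fractions are undefined at zero total reads; such genes are `low_reads`
  regardless of the read floor.
- `logRatioDuplicatedPaternal()` (log2 of maternal over doubled paternal
  reads, 0 at exact 2:1) errors on 0/0 at pseudocount 0 rather than
  returning NaN.
- Coordinates are 1-based and fully closed throughout (VCF convention),
  since SNP inputs derive from variant callers. Counts are strand-collapsed.
  Reads matching neither parental allele (`other_reads`) are carried for QC
  but never enter maternal/paternal totals. A SNP annotated to several
  overlapping genes contributes to each, with a warning.

## Problem sizes

The test suite and the acceptance script use 10,000 null genes for
calibration, 2,000 genes (5% MEG, 5% PEG) for recovery, exhaustive exact-test
verification for all totals ≤ 200, and 150-gene expression panels — sizes at
which the binomial sampling error of every reported rate is well below the
margins being checked, while the whole suite runs in seconds.

## Known limitations

- The caller takes per-SNP or per-gene count tables as input; alignment and
  variant calling are out of scope by design.
- `deTest()` ignores biological dispersion; with real replicates use a
  dedicated DE package and feed its p-values to `coldResponseClass()`.
- The per-cross (unpooled) exact test and the gene-level read floor are
  choices among defensible alternatives; both are isolated behind
  `CallConfig` and small functions, so the alternatives are one-line changes.
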