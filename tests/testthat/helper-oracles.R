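suppressPackageStartupMessages(library(SummarizedExperiment))

# Brute-force enumeration oracle for two-tailed exact tests on a 2x2 table
# with fixed margins: every table probability is computed directly from
# binomial coefficients and the p-value is the sum of probabilities not
# exceeding the observed table's (with the standard 1e-7 relative tie slack).
oracleTwoTailHyper <- function(x, white, black, k) {
  lo <- max(0L, k - black)
  hi <- min(k, white)
  supp <- lo:hi
  logp <- lchoose(white, supp) + lchoose(black, k - supp) -
    lchoose(white + black, k)
  p <- exp(logp)
  pobs <- p[match(x, supp)]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# oracle for the test of (m, p) against the expected row at ratio
oracleFisherVsExpected <- function(m, p, ratio = 2 / 3) {
  n <- m + p
  e1 <- floor(n * ratio + 0.5)
  oracleTwoTailHyper(m, white = m + e1, black = 2L * n - (m + e1), k = n)
}

# oracle for the simplified DE exact test
oracleDeTest <- function(a, b, la, lb) {
  oracleTwoTailHyper(a, white = la, black = lb, k = a + b)
}

# small SNP table used across parsing tests
writeTestSnpTable <- function(rows, file = tempfile(fileext = ".tsv")) {
  writeLines(c("chrom\tpos\tcol_allele\tcvi_allele\tgene_id", rows), file)
  file
}

makeSnpCounts <- function(chrom, pos, col, cvi, other = 0L, lib = "L1") {
  data.frame(library_id = lib, chrom = chrom, pos = as.integer(pos),
             col_reads = as.integer(col), cvi_reads = as.integer(cvi),
             other_reads = as.integer(rep_len(other, length(pos))))
}
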