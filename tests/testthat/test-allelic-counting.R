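test_that("SNP tables parse, validate and de-duplicate", {
  f <- writeTestSnpTable(c("Chr1\t100\tA\tG\tAT1G01010",
                           "Chr1\t250\tC\tT\tAT1G01020"))
  snp <- readSnpTable(f)
  expect_length(snp, 2L)
  expect_identical(GenomicRanges::start(snp), c(100L, 250L))
  expect_identical(GenomicRanges::mcols(snp)$gene_id,
                   c("AT1G01010", "AT1G01020"))

  # 1-based coordinates: pos = 0 is rejected
  f0 <- writeTestSnpTable("Chr1\t0\tA\tG\tAT1G01010")
  expect_error(readSnpTable(f0), "1-based")

  # conflicting alleles at one site are an error
  fc <- writeTestSnpTable(c("Chr1\t100\tA\tG\tAT1G01010",
                            "Chr1\t100\tA\tT\tAT1G01010"))
  expect_error(readSnpTable(fc), "conflicting alleles")

  # exact duplicates collapse; multi-gene sites warn but are kept per gene
  fd <- writeTestSnpTable(c("Chr1\t100\tA\tG\tAT1G01010",
                            "Chr1\t100\tA\tG\tAT1G01010"))
  expect_length(readSnpTable(fd), 1L)
  fm <- writeTestSnpTable(c("Chr1\t100\tA\tG\tAT1G01010",
                            "Chr1\t100\tA\tG\tAT1G01015"))
  expect_warning(snpm <- readSnpTable(fm), "multiple genes")
  expect_length(snpm, 2L)

  # malformed pos names the line
  fb <- writeTestSnpTable(c("Chr1\t100\tA\tG\tAT1G01010",
                            "Chr1\txyz\tA\tG\tAT1G01020"))
  expect_error(readSnpTable(fb), "line\\(s\\) 3")

  # same-allele rows are invalid
  fs <- writeTestSnpTable("Chr1\t100\tA\tA\tAT1G01010")
  expect_error(readSnpTable(fs), "equals")
})

test_that("VCF-like dialect reads CHROM/POS/REF/ALT with a GENE tag", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "Chr1\t100\t.\tA\tG\t50\tPASS\tGENE=AT1G01010;DP=30",
               "Chr2\t900\t.\tC\tT\t50\tPASS\tDP=12;GENE=AT2G02020"),
             f)
  snp <- readSnpTable(f, dialect = "vcf")
  expect_length(snp, 2L)
  expect_identical(GenomicRanges::mcols(snp)$gene_id,
                   c("AT1G01010", "AT2G02020"))
  expect_identical(GenomicRanges::mcols(snp)$col_allele, c("A", "C"))

  fng <- tempfile(fileext = ".vcf")
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "Chr1\t100\t.\tA\tG\t50\tPASS\tDP=30"), fng)
  expect_error(readSnpTable(fng, dialect = "vcf"), "GENE=")
})

test_that("SNP-set intersection keeps identical sites only", {
  called <- readSnpTable(writeTestSnpTable(c(
    "Chr1\t100\tA\tG\tAT1G01010",
    "Chr1\t250\tC\tT\tAT1G01020",
    "Chr2\t50\tG\tA\tAT2G02020")))
  expect_length(intersectSnpSites(called, called), 3L)

  disjoint <- readSnpTable(writeTestSnpTable("Chr3\t999\tA\tC\tAT3G03030"))
  expect_length(intersectSnpSites(called, disjoint), 0L)

  # same position but a different Cvi allele is excluded
  refSet <- readSnpTable(writeTestSnpTable(c(
    "Chr1\t100\tA\tT\tAT1G01010",
    "Chr1\t250\tC\tT\tAT1G01020")))
  kept <- intersectSnpSites(called, refSet)
  expect_length(kept, 1L)
  expect_identical(GenomicRanges::start(kept), 250L)
})

test_that("orientation follows the seed parent and is involutive", {
  cnt <- makeSnpCounts("Chr1", 100, col = 10, cvi = 4, other = 2)
  fwd <- orientCounts(cnt, CrossDirection("Col", "Cvi"))
  expect_identical(fwd$maternal_reads, 10L)
  expect_identical(fwd$paternal_reads, 4L)
  expect_identical(fwd$other_reads, 2L)

  rev <- orientCounts(cnt, CrossDirection("Cvi", "Col"))
  expect_identical(rev$maternal_reads, 4L)
  expect_identical(rev$paternal_reads, 10L)

  # involution: orienting forward then swapping labels equals reverse
  expect_identical(fwd$paternal_reads, rev$maternal_reads)
  expect_identical(fwd$maternal_reads, rev$paternal_reads)

  zero <- orientCounts(makeSnpCounts("Chr1", 100, 0, 0),
                       CrossDirection("Col", "Cvi"))
  expect_identical(zero$maternal_reads + zero$paternal_reads, 0L)

  expect_error(orientCounts(cnt, CrossDirection("Ler", "Cvi")),
               "neither mother nor father")
})

test_that("gene aggregation sums over SNPs and conserves reads", {
  snp <- readSnpTable(writeTestSnpTable(c(
    "Chr1\t100\tA\tG\tgeneA",
    "Chr1\t200\tC\tT\tgeneA",
    "Chr2\t300\tG\tC\tgeneB")))
  cnt <- makeSnpCounts(c("Chr1", "Chr1", "Chr2"), c(100, 200, 300),
                       col = c(3, 2, 7), cvi = c(1, 0, 7))
  agg <- aggregateGeneCounts(orientCounts(cnt, CrossDirection("Col", "Cvi")),
                             snp)
  a <- agg[agg$gene_id == "geneA", ]
  expect_identical(a$maternal_reads, 5L)
  expect_identical(a$paternal_reads, 1L)
  expect_identical(a$n_snps, 2L)
  b <- agg[agg$gene_id == "geneB", ]
  expect_identical(c(b$maternal_reads, b$paternal_reads, b$n_snps),
                   c(7L, 7L, 1L))

  # conservation: per-gene totals equal oriented per-SNP totals
  expect_identical(sum(agg$maternal_reads) + sum(agg$paternal_reads),
                   sum(cnt$col_reads) + sum(cnt$cvi_reads))

  # unknown positions are skipped with a warning and a logged count
  cnt2 <- rbind(cnt, makeSnpCounts("Chr9", 1, 5, 5))
  expect_warning(
    agg2 <- aggregateGeneCounts(
      orientCounts(cnt2, CrossDirection("Col", "Cvi")), snp),
    "skipped")
  expect_identical(attr(agg2, "skipped_records"), 1L)
  expect_identical(agg2$maternal_reads, agg$maternal_reads)
})

test_that("conservation holds on simulated data with multi-SNP genes", {
  fx <- writeFixtures(tempfile("fx"),
                      SimConfig(nGenes = 60L, fracMeg = 0.1, seed = 9L))
  snp <- readSnpTable(fx[["snp_table"]])
  for (i in 1:2) {
    cross <- if (i == 1L) CrossDirection("Col", "Cvi")
             else CrossDirection("Cvi", "Col")
    cnt <- readSnpCounts(fx[[paste0("snp_counts_cross", i)]])
    agg <- aggregateGeneCounts(orientCounts(cnt, cross), snp)
    expect_identical(sum(agg$maternal_reads) + sum(agg$paternal_reads),
                     sum(cnt$col_reads) + sum(cnt$cvi_reads))
    ref <- readGeneCounts(fx[[paste0("gene_counts_cross", i)]])
    expect_identical(agg$maternal_reads, ref$maternal_reads)
    expect_identical(agg$paternal_reads, ref$paternal_reads)
    expect_identical(agg$n_snps, ref$n_snps)
  }
})

test_that("SNP and gene tables round-trip through write and read", {
  snp <- readSnpTable(writeTestSnpTable(c(
    "Chr1\t100\tA\tG\tgeneA",
    "Chr2\t300\tG\tC\tgeneB")))
  f <- tempfile(fileext = ".tsv")
  writeSnpTable(snp, f)
  expect_identical(readSnpTable(f), snp)

  gc <- data.frame(gene_id = c("geneA", "geneB"), cross = "ColxCvi",
                   maternal_reads = c(5L, 7L), paternal_reads = c(1L, 7L),
                   n_snps = c(2L, 1L))
  g <- tempfile(fileext = ".tsv")
  writeGeneCounts(gc, g)
  expect_identical(readGeneCounts(g), gc)
})
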