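test_that("maternal fraction is the share of maternal reads", {
  expect_equal(maternalFraction(10, 5), 2 / 3, tolerance = 1e-12)
  expect_identical(maternalFraction(0, 8), 0)
  expect_identical(maternalFraction(8, 0), 1)
  expect_error(maternalFraction(0, 0), "undefined")
})

test_that("Fisher test against 2:1 matches the enumeration oracle", {
  # observed row equal to the expected row: odds ratio 1, p = 1
  expect_identical(fisherVsExpected(200, 100), 1)
  # frozen values computed with the brute-force oracle
  expect_equal(fisherVsExpected(100, 0), 9.75737744687e-12,
               tolerance = 1e-9)
  expect_equal(fisherVsExpected(4, 2), 1, tolerance = 1e-9)
  # spot-check a grid against the oracle and against stats::fisher.test
  for (m in c(0L, 1L, 7L, 33L, 66L, 100L)) {
    for (p in c(0L, 2L, 34L, 50L)) {
      if (m + p == 0L) next
      got <- fisherVsExpected(m, p)
      expect_equal(got, oracleFisherVsExpected(m, p), tolerance = 1e-9)
      n <- m + p
      e1 <- floor(n * 2 / 3 + 0.5)
      ft <- stats::fisher.test(matrix(c(m, p, e1, n - e1), 2L,
                                      byrow = TRUE))$p.value
      expect_equal(got, min(1, ft), tolerance = 1e-9)
    }
  }
  expect_error(fisherVsExpected(-1, 5), "non-negative")
})

test_that("binomial backend agrees with dbinom mass summation", {
  for (m in c(0L, 5L, 40L, 66L)) {
    d <- dbinom(0:100, 100, 2 / 3)
    expect_equal(binomVsExpected(m, 100L - m),
                 min(1, sum(d[d <= d[m + 1L] * (1 + 1e-7)])),
                 tolerance = 1e-12)
  }
})

test_that("two-tailed p-value decreases away from the 2:1 expectation", {
  for (n in c(30L, 75L, 150L)) {
    e1 <- floor(n * 2 / 3 + 0.5)
    up <- fisherVsExpected(e1:n, n - (e1:n))
    expect_true(all(diff(up) <= 1e-12))
    down <- fisherVsExpected(e1:0, n - (e1:0))
    expect_true(all(diff(down) <= 1e-12))
  }
})

test_that("single-gene calls apply the three criteria", {
  meg <- callGene(list(gene_id = "g", maternal_reads = 95,
                       paternal_reads = 5),
                  list(gene_id = "g", maternal_reads = 90,
                       paternal_reads = 10))
  expect_identical(meg$class, "MEG")
  # oracle-confirmed significance at these depths
  expect_equal(meg$pvalue_cross1, 4.02062318905e-07, tolerance = 1e-9)
  expect_equal(meg$pvalue_cross2, 0.000115837731007, tolerance = 1e-9)

  bi <- callGene(list(gene_id = "g", maternal_reads = 66,
                      paternal_reads = 34),
                 list(gene_id = "g", maternal_reads = 70,
                      paternal_reads = 30))
  expect_identical(bi$class, "biallelic")

  low <- callGene(list(gene_id = "g", maternal_reads = 2,
                       paternal_reads = 1),
                  list(gene_id = "g", maternal_reads = 2,
                       paternal_reads = 1))
  expect_identical(low$class, "low_reads")

  peg <- callGene(list(gene_id = "g", maternal_reads = 10,
                       paternal_reads = 90),
                  list(gene_id = "g", maternal_reads = 15,
                       paternal_reads = 85))
  expect_identical(peg$class, "PEG")

  expect_error(callGene(list(gene_id = "a", maternal_reads = 1,
                             paternal_reads = 1),
                        list(gene_id = "b", maternal_reads = 1,
                             paternal_reads = 1)),
               "different genes")
})

test_that("threshold ties fail the strict 'more than' rule", {
  # maternal fraction exactly 0.8 in one cross: not a MEG however significant
  res <- callGene(list(gene_id = "g", maternal_reads = 400,
                       paternal_reads = 100),
                  list(gene_id = "g", maternal_reads = 380,
                       paternal_reads = 20))
  expect_identical(res$class, "biallelic")
  expect_true(res$pvalue_cross1 < 0.05 && res$pvalue_cross2 < 0.05)
})

test_that("callImprinting processes whole tables and builds sets", {
  sim <- simulateAllelicCounts(SimConfig(nGenes = 400L, fracMeg = 0.08,
                                         fracPeg = 0.04,
                                         depthRange = c(100L, 200L),
                                         seed = 21L))
  res <- callImprinting(sim$cross1, sim$cross2, condition = "dormant")
  expect_s4_class(res, "ImprintingResult")
  expect_identical(nrow(calls(res)), 400L)
  expect_identical(condition(res), "dormant")
  expect_length(intersect(megs(res), pegs(res)), 0L)

  planted <- sim$truth$gene_id[sim$truth$class == "MEG"]
  expect_gt(mean(planted %in% megs(res)), 0.9)
  expect_length(intersect(planted, pegs(res)), 0L)

  # genes present in one cross only are dropped with a message
  expect_message(
    res2 <- callImprinting(sim$cross1[-1, ], sim$cross2),
    "only one cross")
  expect_identical(nrow(calls(res2)), 399L)

  # empty input gives empty calls and empty sets
  empty <- sim$cross1[0, ]
  empty2 <- sim$cross2[0, ]
  res0 <- callImprinting(empty, empty2)
  expect_identical(nrow(calls(res0)), 0L)
  expect_length(megs(res0), 0L)
})

test_that("identical inputs give byte-identical call tables", {
  sim <- simulateAllelicCounts(SimConfig(nGenes = 300L, fracMeg = 0.05,
                                         seed = 5L))
  a <- calls(callImprinting(sim$cross1, sim$cross2))
  b <- calls(callImprinting(sim$cross1, sim$cross2))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("BH correction is available and at least as conservative", {
  sim <- simulateAllelicCounts(SimConfig(nGenes = 500L, fracMeg = 0.05,
                                         seed = 13L))
  plain <- callImprinting(sim$cross1, sim$cross2)
  bh <- callImprinting(sim$cross1, sim$cross2,
                       config = CallConfig(correction = "BH"))
  expect_true(all(megs(bh) %in% megs(plain)))
  expect_true(all(pegs(bh) %in% pegs(plain)))
})

test_that("condition-specific partition reproduces printed set logic", {
  dormant <- list(megs = paste0("m", 1:71), pegs = paste0("q", 1:5))
  nondorm <- list(megs = paste0("m", c(1:14, 100:135)),
                  pegs = paste0("q", 1:2))
  part <- classifyConditionSpecific(dormant, nondorm)
  expect_length(part$megs$dormant_specific, 57L)
  expect_length(part$megs$shared, 14L)
  expect_length(part$megs$nondormant_specific, 36L)
  expect_length(part$pegs$shared, 2L)

  same <- classifyConditionSpecific(dormant, dormant)
  expect_length(same$megs$dormant_specific, 0L)
  expect_length(same$megs$shared, 71L)

  disj <- classifyConditionSpecific(
    dormant, list(megs = paste0("x", 1:3), pegs = character()))
  expect_length(disj$megs$shared, 0L)
})

test_that("log ratio against duplicated paternal reads centers 2:1 at zero", {
  expect_identical(logRatioDuplicatedPaternal(200, 100), 0)
  expect_identical(logRatioDuplicatedPaternal(400, 100), 1)
  expect_equal(logRatioDuplicatedPaternal(0, 100, pseudocount = 1),
               log2(1 / 201), tolerance = 1e-12)
  expect_error(logRatioDuplicatedPaternal(0, 0), "undefined")
})
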