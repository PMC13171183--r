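# Chi-square enrichment, circular overlap test, coverage and frequencies.

test_that("the chi-square statistic matches hand evaluation and scales", {
  layout <- toyLayout()
  # windows: 100 in INV (10 flagged), 100 in COL (50 flagged) -> the
  # [[10,90],[50,50]] table, X^2 ~ 38.10
  win <- data.frame(
    chrom = "chr1",
    start = c(seq(400001, 599000, length.out = 100),
              seq(1, 399000, length.out = 100)),
    flag = c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(50, 50))))
  win$end <- win$start + 10
  res <- enrichmentChi2(win, "flag", layout)
  expect_equal(res$statistic, 38.0952381, tolerance = 1e-6)

  # proportional table -> statistic 0
  winP <- win
  winP$flag <- rep(c(TRUE, FALSE), 100)
  expect_equal(enrichmentChi2(winP, "flag", layout)$statistic, 0,
               tolerance = 1e-12)

  # dividing all four cells by 5 divides the statistic by 5
  win5 <- win[rep(seq_len(nrow(win)), 5), ]
  resAll <- enrichmentChi2(win5, "flag", layout, divideBy = 1)
  res5 <- enrichmentChi2(win5, "flag", layout, divideBy = 5)
  expect_equal(resAll$statistic / 5, res5$statistic, tolerance = 1e-9)

  # zero margin is an error
  winZ <- win
  winZ$flag <- FALSE
  expect_error(enrichmentChi2(winZ, "flag", layout), "margin")
})

test_that("chi-square agrees with brute-force sum((O-E)^2/E) on random tables", {
  brute <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  set.seed(8)
  for (i in 1:100) {
    tab <- matrix(sample(1:200, 4, replace = TRUE), 2)
    got <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_lt(abs(got$statistic - brute(tab)), 1e-10)
  }
})

test_that("buffered and strict enrichment coincide when the buffer is zero", {
  layout0 <- genomeLayout(c(chr1 = 1e6),
                          GenomicRanges::GRanges(
                            "chr1", IRanges::IRanges(400001, 600000)),
                          bufferBp = 0)
  set.seed(71)
  snp <- data.frame(chrom = "chr1", pos = sample.int(1e6, 500),
                    flag = sample(c(TRUE, FALSE), 500, replace = TRUE))
  a <- enrichmentChi2(snp, "flag", layout0, useBuffer = FALSE)
  b <- enrichmentChi2(snp, "flag", layout0, useBuffer = TRUE)
  expect_equal(unclass(a$table), unclass(b$table))
  expect_equal(a$statistic, b$statistic)
})

test_that("the circular overlap test matches exhaustive rotation on a toy genome", {
  layout <- genomeLayout(c(chr1 = 10))
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 3))
  snps <- data.frame(chrom = "chr1", pos = 5L)
  res <- circularOverlapTest(snps, regions, layout, nResamples = 2000,
                             seed = 12)
  # exhaustive: 1 of the 10 rotations put the SNP on the barrier site
  expect_lt(abs(mean(res$null) - 0.1), 0.03)
  expect_equal(res$observed, 0)
  # observed 0 is never exceeded -> p = 1 only if all nulls >= 0 (always)
  expect_equal(res$p.value, 1)

  # regions covering the whole genome: observed = nulls = 1, p = 1
  all <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
  resAll <- circularOverlapTest(snps, all, layout, nResamples = 50,
                                seed = 13)
  expect_equal(resAll$observed, 1)
  expect_true(all(resAll$null == 1))
  expect_equal(resAll$p.value, 1)
  expect_error(circularOverlapTest(snps[0, ], all, layout, seed = 1),
               "empty")
})

test_that("rotation preserves SNP count and spacing; null p-values are valid", {
  layout <- genomeLayout(c(chr1 = 1e5, chr2 = 5e4))
  set.seed(31)
  # spacing-preservation: check via the null distribution being a proper
  # proportion over the same number of SNPs
  snps <- data.frame(
    chrom = rep(c("chr1", "chr2"), c(30, 20)),
    pos = c(sort(sample.int(1e5, 30)), sort(sample.int(5e4, 20))))
  regions <- GenomicRanges::GRanges(
    c("chr1", "chr2"), IRanges::IRanges(c(1, 1), c(2e4, 1e4)))
  res <- circularOverlapTest(snps, regions, layout, nResamples = 200,
                             seed = 32)
  expect_equal(res$null * 50, round(res$null * 50), tolerance = 1e-9)
  expect_true(all(res$null >= 0 & res$null <= 1))

  # type-I validity: under uniform SNP placement P(p <= alpha) <= alpha + MC
  pvals <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    u <- data.frame(chrom = "chr1", pos = sample.int(1e5, 40))
    circularOverlapTest(u, regions, layout, nResamples = 99,
                        seed = 2000 + s)$p.value
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1)) {
    mcErr <- 3 * sqrt(alpha * (1 - alpha) / 200)
    expect_lte(mean(pvals <= alpha), alpha + mcErr)
  }
})

test_that("coverage summaries print the field's fraction format", {
  expect_equal(formatFraction(1050, 9468), "11.1% (1,050 out of 9,468)")
  expect_equal(formatFraction(466, 1050), "44.4% (466 out of 1,050)")
  expect_equal(formatFraction(0, 10), "0.0% (0 out of 10)")
  expect_equal(formatMbFraction(15.6e6, 145.5e6),
               "10.7% (15.6Mb out of 145.5Mb)")
})

test_that("inversion frequencies follow the allele-count formula", {
  expect_equal(inversionFrequency(10, 0, 0), 1.0)   # fixed arrangement
  expect_equal(inversionFrequency(0, 0, 7), 0.0)
  expect_equal(inversionFrequency(1, 2, 6), 4 / 18)
  expect_error(inversionFrequency(0, 0, 0), "zero")
  expect_error(inversionFrequency(-1, 1, 1), "non-negative")
})
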