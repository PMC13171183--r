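# Genome layout, masks, pair genotypes and region classification.

test_that("layout config round-trips and rejects out-of-bounds inversions", {
  cfgPath <- tempfile(fileext = ".yaml")
  writeLines(c(
    "chromosomes:",
    "  - name: chr4",
    "    length: 30000000",
    "inversions:",
    "  - chromosome: chr4",
    "    start: 10000000",
    "    end: 19500000",
    "buffer_bp: 1500000"), cfgPath)
  layout <- loadGenomeLayout(cfgPath)
  inv <- inversions(layout)
  expect_equal(length(inv), 1)
  expect_equal(GenomicRanges::width(inv), 9.5e6)
  expect_equal(bufferBp(layout), 1.5e6)

  # no inversions -> everything colinear
  writeLines(c("chromosomes:", "  - name: chr1", "    length: 1000"),
             cfgPath)
  empty <- loadGenomeLayout(cfgPath)
  expect_equal(length(inversions(empty)), 0)
  expect_equal(classifyInterval("chr1", 1, 1000, empty), "COL")

  # end beyond chromosome length
  writeLines(c(
    "chromosomes:",
    "  - name: chr1",
    "    length: 1000",
    "inversions:",
    "  - chromosome: chr1",
    "    start: 100",
    "    end: 2000"), cfgPath)
  expect_error(loadGenomeLayout(cfgPath), "bounds")

  # unknown chromosome named in the error
  writeLines(c(
    "chromosomes:",
    "  - name: chr1",
    "    length: 1000",
    "inversions:",
    "  - chromosome: chrZ",
    "    start: 1",
    "    end: 10"), cfgPath)
  expect_error(loadGenomeLayout(cfgPath), "chrZ")

  # write -> load round trip
  out <- tempfile(fileext = ".yaml")
  writeGenomeLayout(layout, out)
  again <- loadGenomeLayout(out)
  expect_equal(chromLengths(again), chromLengths(layout))
  expect_equal(GenomicRanges::start(inversions(again)),
               GenomicRanges::start(inversions(layout)))
  expect_equal(GenomicRanges::end(inversions(again)),
               GenomicRanges::end(inversions(layout)))
  expect_equal(bufferBp(again), bufferBp(layout))
})

test_that("interval classification follows the midpoint and buffer rules", {
  layout <- chr4Layout()
  # midpoint inside the inversion
  expect_equal(classifyInterval("chr4", 12e6, 13e6, layout), "INV")
  # midpoint 1.0 Mb beyond the distal breakpoint: BUFFER only if requested
  expect_equal(
    classifyInterval("chr4", 20.5e6 - 1, 20.5e6 + 1, layout,
                     useBuffer = TRUE), "BUFFER")
  expect_equal(
    classifyInterval("chr4", 20.5e6 - 1, 20.5e6 + 1, layout), "COL")
  # a window straddling a breakpoint takes its midpoint's class
  expect_equal(classifyInterval("chr4", 9.9e6, 10.3e6, layout), "INV")
  expect_equal(classifyInterval("chr4", 9.6e6, 10.2e6, layout), "COL")
  expect_error(classifyInterval("chr4", 1, 4e7, layout), "bounds")
  expect_error(classifyInterval("chr9", 1, 10, layout), "unknown")
})

test_that("region classes partition the chromosome", {
  layout <- toyLayout()
  starts <- seq(1, 1e6, by = 1000)
  cls <- classifyInterval(rep("chr1", length(starts)), starts,
                          starts + 999, layout, useBuffer = TRUE)
  spans <- tapply(rep(1000, length(starts)), cls, sum)
  expect_equal(sum(spans), 1e6)
  expect_setequal(names(spans), c("INV", "BUFFER", "COL"))
  expect_equal(unname(spans["INV"]), 200000)
  expect_equal(unname(spans["BUFFER"]), 100000)
})

test_that("callable masks merge, clip, round-trip and reject bad input", {
  layout <- genomeLayout(c(chr1 = 150))
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\t150"), bed)
  mask <- loadCallableMask(bed, layout)
  expect_equal(length(mask), 1)
  expect_equal(GenomicRanges::start(mask), 1)
  expect_equal(GenomicRanges::end(mask), 150)

  writeLines(character(), bed)
  expect_equal(length(loadCallableMask(bed, layout)), 0)

  writeLines("chrUnknown\t0\t10", bed)
  expect_error(loadCallableMask(bed, layout), "unknown chromosome")

  writeLines(c("chr1\t0\t100", "chr1\tnot_a_number\t5"), bed)
  expect_error(loadCallableMask(bed, layout), "line 2")

  writeLines(c("chr1\t0\t60", "chr1\t80\t120"), bed)
  mask <- loadCallableMask(bed, layout)
  out <- tempfile(fileext = ".bed")
  writeCallableMask(mask, out)
  again <- loadCallableMask(out, layout)
  expect_equal(GenomicRanges::start(again), GenomicRanges::start(mask))
  expect_equal(GenomicRanges::end(again), GenomicRanges::end(mask))
})

test_that("pair genotypes load biallelic SNPs and flag missing calls", {
  vcf <- tempfile(fileext = ".vcf")
  writeTestVcf(vcf, c(
    vcfRow(100, "A", "T", "0/1", "0/0"),
    vcfRow(200, "C", "G", "1/1", "0|0"),
    vcfRow(250, "AT", "A", "0/1", "0/1"),     # indel: dropped
    vcfRow(300, "G", "A,C", "1/2", "0/0"),    # multiallelic: dropped
    vcfRow(400, "T", "C", "./.", "0/1")))     # missing genotype in A
  suppressMessages(pg <- loadPairGenotypes(vcf, "popA_1", "popB_1"))
  expect_equal(nrow(pg), 3)
  expect_equal(pg$pos, c(100L, 200L, 400L))
  expect_equal(pg$gtA, c(1L, 2L, NA_integer_))
  expect_equal(pg$gtB, c(0L, 0L, 1L))

  expect_error(loadPairGenotypes(vcf, "popA_1", "nobody"), "nobody")

  writeTestVcf(vcf, character())
  suppressMessages(empty <- loadPairGenotypes(vcf, "popA_1", "popB_1"))
  expect_equal(nrow(empty), 0)
})

test_that("candidate SNP sets validate, deduplicate and sort", {
  layout <- toyLayout()
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos", "chr1\t500", "chr1\t100", "chr1\t500"), tsv)
  snps <- loadCandidateSnps(tsv, layout, label = "PC1")
  expect_equal(snps$snps$pos, c(100L, 500L))
  expect_equal(snps$label, "PC1")
  writeLines(c("chrom\tpos", "chr1\t2000000"), tsv)
  expect_error(loadCandidateSnps(tsv, layout), "bounds")
})
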