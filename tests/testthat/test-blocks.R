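# Block cutting, site classification, tallies, windows, diversity stats.

test_that("blocks contain exactly blockSites callable sites within the span cap", {
  cfg <- blockConfig(blockSites = 256, maxBlockSpan = 512,
                     windowBlocks = 4, windowStep = 2)
  layout <- genomeLayout(c(chr1 = 1e5))
  mk <- function(starts, ends) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends))
  }
  # contiguous 1024 sites -> 4 blocks
  bs <- cutBlocks(mk(1, 1024), cfg)
  expect_equal(nrow(bs$blocks), 4)
  expect_true(all(lengths(bs$sites) == 256))
  expect_equal(bs$blocks$start, c(1, 257, 513, 769))

  # 300 contiguous sites -> 1 block, 44 discarded
  bs <- cutBlocks(mk(1, 300), cfg)
  expect_equal(nrow(bs$blocks), 1)

  # sites scattered every third base: any 256-site run spans 766 bp,
  # beyond the 512 bp cap -> 0 blocks
  pos <- seq(1, by = 3, length.out = 300)
  bs <- cutBlocks(mk(pos, pos), cfg)
  expect_equal(nrow(bs$blocks), 0)

  # empty mask -> zero blocks
  expect_equal(nrow(cutBlocks(GenomicRanges::GRanges(), cfg)$blocks), 0)
})

test_that("sites classify by the pair-of-diploids mutation-type rules", {
  expect_equal(classifySite(1, 0), "hetA")
  expect_equal(classifySite(2, 0), "fixed")
  expect_equal(classifySite(0, 2), "fixed")
  expect_equal(classifySite(1, 1), "hetAB")
  expect_equal(classifySite(0, 1), "hetB")
  expect_equal(classifySite(0, 0), "invariant")
  expect_equal(classifySite(2, 2), "invariant")
  expect_equal(classifySite(NA, 1), "excluded")
  expect_error(classifySite(3, 0), "biallelic")
})

test_that("block tallies truncate at kmax and conserve site-level totals", {
  cfg <- blockConfig(blockSites = 10, maxBlockSpan = 20, kmax = 2,
                     windowBlocks = 2, windowStep = 1)
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  bs <- cutBlocks(mask, cfg)
  # block 1 (sites 1..10): 2 hetA + 1 fixed; block 2 (11..20): 3 hetA
  pg <- data.frame(chrom = "chr1",
                   pos = c(2L, 5L, 7L, 11L, 13L, 17L, 999L),
                   gtA = c(1L, 1L, 2L, 1L, 1L, 1L, 1L),
                   gtB = c(0L, 0L, 0L, 0L, 0L, 0L, 0L))
  tal <- tallyBlocks(bs, pg, cfg)
  expect_equal(tal$hetA[1:2], c(2L, 2L))     # block 2 truncated at kmax
  expect_equal(tal$fixed[1], 1L)
  expect_equal(tal$mHetA[1:2], c(FALSE, TRUE))
  expect_true(all(tal$hetA <= cfg$kmax))

  # conservation at large kmax against site-level classification, random data
  cfgBig <- blockConfig(blockSites = 10, maxBlockSpan = 20, kmax = 4,
                        windowBlocks = 2, windowStep = 1)
  set.seed(42)
  pg2 <- data.frame(chrom = "chr1", pos = sample.int(100, 60),
                    gtA = sample(0:2, 60, replace = TRUE),
                    gtB = sample(0:2, 60, replace = TRUE))
  tal2 <- tallyBlocks(cutBlocks(mask, cfgBig), pg2, cfgBig)
  siteTypes <- classifySite(pg2$gtA, pg2$gtB)
  marg <- sum(tal2$mHetA, tal2$mHetB, tal2$mHetAB, tal2$mFixed)
  expect_equal(marg, 0)
  expect_equal(sum(tal2$hetA), sum(siteTypes == "hetA"))
  expect_equal(sum(tal2$hetB), sum(siteTypes == "hetB"))
  expect_equal(sum(tal2$hetAB), sum(siteTypes == "hetAB"))
  expect_equal(sum(tal2$fixed), sum(siteTypes == "fixed"))

  # a block with no variants tallies (0,0,0,0)
  talEmpty <- tallyBlocks(bs, pg[0, ], cfg)
  expect_true(all(talEmpty[c("hetA", "hetB", "hetAB", "fixed")] == 0))
})

test_that("sliding windows have the documented count and overlap structure", {
  cfg <- blockConfig(blockSites = 4, maxBlockSpan = 8)
  fakeTallies <- function(n, chrom = "chr1") {
    out <- data.frame(chrom = chrom, start = seq_len(n) * 10L,
                      end = seq_len(n) * 10L + 5L,
                      hetA = 0L, hetB = 0L, hetAB = 0L, fixed = 0L,
                      mHetA = FALSE, mHetB = FALSE, mHetAB = FALSE,
                      mFixed = FALSE)
    attr(out, "kmax") <- 2L
    out
  }
  # default window geometry: (30000 - 12500)/2500 + 1 = 8
  w <- makeWindows(fakeTallies(30000), cfg)
  expect_equal(nrow(w$meta), 8)
  expect_equal(makeWindows(fakeTallies(12499), cfg)$meta |> nrow(), 0)
  expect_equal(makeWindows(fakeTallies(12500), cfg)$meta |> nrow(), 1)
  # each window holds windowBlocks tallies; neighbours share wb - step
  expect_true(all(lengths(w$blockIndex) == 12500))
  expect_equal(length(intersect(w$blockIndex[[1]], w$blockIndex[[2]])),
               12500 - 2500)
  # windows never span two chromosomes
  two <- rbind(fakeTallies(12600, "chr1"), fakeTallies(12600, "chr2"))
  attr(two, "kmax") <- 2L
  w2 <- makeWindows(two, cfg)
  expect_true(all(vapply(seq_len(nrow(w2$meta)), function(i)
    length(unique(two$chrom[w2$blockIndex[[i]]])) == 1, logical(1))))
})

test_that("diversity statistics follow their definitions and limits", {
  mkTal <- function(hetA, hetB, hetAB, fixed) {
    n <- length(hetA)
    out <- data.frame(hetA = hetA, hetB = hetB, hetAB = hetAB,
                      fixed = fixed, mHetA = FALSE, mHetB = FALSE,
                      mHetAB = FALSE, mFixed = FALSE)
    attr(out, "kmax") <- 2L
    out
  }
  # only fixed differences: complete differentiation
  d <- diversityStats(mkTal(0, 0, 0, c(2, 1, 2)), nSites = 1000)
  expect_equal(d$piA, 0)
  expect_equal(d$dxy, 5 / 1000)
  expect_equal(d$fst, 1)
  # identical genomes: dxy = 0, Fst undefined
  d0 <- diversityStats(mkTal(0, 0, 0, 0), nSites = 1000)
  expect_equal(d0$dxy, 0)
  expect_true(is.na(d0$fst))
  expect_error(diversityStats(mkTal(1, 0, 0, 0), nSites = 0), "positive")
})

test_that("Fst is ~0 under panmixia and positive under divergence", {
  cfg <- blockConfig()
  pan <- demographicModel("DIV", 1e5, 1e5, 1e5, Tgen = 0)
  tal <- simulateBlockTallies(pan, 5e4, cfg, seed = 301)
  d <- diversityStats(tal, nSites = 5e4 * cfg$blockSites)
  expect_lt(abs(d$fst), 0.02)
  div <- fastDivModel(Tgen = 1e6)
  tal2 <- simulateBlockTallies(div, 5e4, cfg, seed = 302)
  d2 <- diversityStats(tal2, nSites = 5e4 * cfg$blockSites)
  expect_gt(d2$fst, 0.2)
})
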