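## Pair-block construction, mutation-type classification, tallies, sliding
## windows and the window summary statistics pi, dxy and Fst.

#' Cut a callable mask into fixed-size pair-blocks
#'
#' Blocks contain exactly `cfg$blockSites` callable sites and may span at
#' most `cfg$maxBlockSpan` bp of sequence, which keeps the per-block mutation
#' opportunity constant while bounding within-block recombination distance.
#' Scanning left to right, a block is emitted whenever the next
#' `blockSites` callable sites fit within the span cap (the start otherwise
#' advances by one site); trailing incomplete blocks are discarded.
#'
#' @param mask a [GenomicRanges::GRanges] callable mask (disjoint intervals).
#' @param cfg a [blockConfig()].
#' @return a list of class `"BlockSet"`: `blocks` (data frame `chrom`,
#'   `start`, `end`) and `sites` (per-block integer vectors of callable
#'   positions).
#' @export
cutBlocks <- function(mask, cfg = blockConfig()) {
  bs <- cfg$blockSites
  cap <- cfg$maxBlockSpan
  blocks <- list()
  sites <- list()
  chroms <- unique(as.character(GenomeInfoDb::seqnames(mask)))
  for (ch in chroms) {
    gr <- mask[as.character(GenomeInfoDb::seqnames(mask)) == ch]
    pos <- unlist(mapply(seq.int, GenomicRanges::start(gr),
                         GenomicRanges::end(gr), SIMPLIFY = FALSE),
                  use.names = FALSE)
    pos <- sort(pos)
    n <- length(pos)
    i <- 1L
    while (i + bs - 1L <= n) {
      span <- pos[i + bs - 1L] - pos[i] + 1L
      if (span <= cap) {
        blocks[[length(blocks) + 1L]] <-
          data.frame(chrom = ch, start = pos[i], end = pos[i + bs - 1L])
        sites[[length(sites) + 1L]] <- pos[i:(i + bs - 1L)]
        i <- i + bs
      } else {
        i <- i + 1L
      }
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks)
            else data.frame(chrom = character(), start = integer(),
                            end = integer())
  structure(list(blocks = blocks, sites = sites), class = "BlockSet")
}

#' @exportS3Method base::print
print.BlockSet <- function(x, ...) {
  cat(sprintf("BlockSet: %d block(s) on %d chromosome(s)\n",
              nrow(x$blocks), length(unique(x$blocks$chrom))))
  invisible(x)
}

#' Classify a biallelic site by its pair-of-diploids mutation type
#'
#' Genotypes are alternate-allele counts (0, 1, 2; `NA` = missing).  A site
#' heterozygous only in the population-A individual is `hetA` (likewise
#' `hetB`); heterozygous in both, `hetAB`; opposite homozygotes, `fixed`;
#' identical homozygotes, `invariant`; any missing genotype, `excluded`.
#'
#' @param gtA,gtB diploid genotypes, vectorized.
#' @return character vector of types.
#' @examples
#' classifySite(c(1, 2, 1), c(0, 0, 1))
#' @export
classifySite <- function(gtA, gtB) {
  ok <- is.na(gtA) | gtA %in% 0:2
  if (!all(ok & (is.na(gtB) | gtB %in% 0:2)))
    stop("genotypes must be biallelic allele counts 0, 1, 2 or NA")
  out <- rep("excluded", length(gtA))
  cc <- !is.na(gtA) & !is.na(gtB)
  a <- gtA[cc]
  b <- gtB[cc]
  o <- rep("invariant", sum(cc))
  o[a == 1 & b != 1] <- "hetA"
  o[b == 1 & a != 1] <- "hetB"
  o[a == 1 & b == 1] <- "hetAB"
  o[abs(a - b) == 2] <- "fixed"
  out[cc] <- o
  out
}

.emptyTallies <- function(kmax) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    hetA = integer(), hetB = integer(), hetAB = integer(),
                    fixed = integer(), mHetA = logical(), mHetB = logical(),
                    mHetAB = logical(), mFixed = logical())
  attr(out, "kmax") <- kmax
  out
}

#' Tally mutation types per block
#'
#' Counts the four mutation types among each block's callable sites,
#' truncating at `cfg$kmax`: a count above `kmax` is stored as `kmax` with
#' the corresponding marginal flag set.  Variants at positions outside every
#' block are ignored; sites with missing genotypes are excluded.
#'
#' @param blockSet a `"BlockSet"` from [cutBlocks()].
#' @param genotypes a `"PairGenotypes"` data frame ([loadPairGenotypes()]).
#' @param cfg a [blockConfig()].
#' @return block-tally data frame (`chrom`, `start`, `end`, counts `hetA`,
#'   `hetB`, `hetAB`, `fixed` and marginal flags `mHetA` ... `mFixed`), with
#'   attribute `kmax`.
#' @export
tallyBlocks <- function(blockSet, genotypes, cfg = blockConfig()) {
  kmax <- cfg$kmax
  nb <- nrow(blockSet$blocks)
  if (nb == 0) return(.emptyTallies(kmax))
  counts <- matrix(0L, nb, 4,
                   dimnames = list(NULL, c("hetA", "hetB", "hetAB", "fixed")))
  if (nrow(genotypes)) {
    type <- classifySite(genotypes$gtA, genotypes$gtB)
    keep <- type %in% c("hetA", "hetB", "hetAB", "fixed")
    g <- genotypes[keep, , drop = FALSE]
    type <- type[keep]
    blockChrom <- blockSet$blocks$chrom
    siteKey <- paste0(rep(blockChrom, lengths(blockSet$sites)), ":",
                      unlist(blockSet$sites, use.names = FALSE))
    siteBlock <- rep(seq_len(nb), lengths(blockSet$sites))
    hit <- match(paste0(g$chrom, ":", g$pos), siteKey)
    inBlock <- !is.na(hit)
    if (any(inBlock)) {
      b <- siteBlock[hit[inBlock]]
      ty <- match(type[inBlock], c("hetA", "hetB", "hetAB", "fixed"))
      for (t in 1:4) {
        tb <- tabulate(b[ty == t], nbins = nb)
        counts[, t] <- counts[, t] + tb
      }
    }
  }
  out <- cbind(blockSet$blocks,
               as.data.frame(pmin(counts, kmax)),
               data.frame(mHetA = counts[, 1] > kmax,
                          mHetB = counts[, 2] > kmax,
                          mHetAB = counts[, 3] > kmax,
                          mFixed = counts[, 4] > kmax))
  attr(out, "kmax") <- kmax
  out
}

#' Group block tallies into sliding windows
#'
#' Windows contain exactly `cfg$windowBlocks` consecutive blocks and start
#' every `cfg$windowStep` blocks; they never cross chromosome ends.  A
#' chromosome with fewer than `windowBlocks` blocks yields no window.
#'
#' @param tallies block-tally data frame in genome order.
#' @param cfg a [blockConfig()].
#' @return a list of class `"WindowSet"`: `meta` (data frame `chrom`,
#'   `start`, `end`, `nBlocks`) and `blockIndex` (per-window integer vectors
#'   of row indices into `tallies`).
#' @export
makeWindows <- function(tallies, cfg = blockConfig()) {
  wb <- cfg$windowBlocks
  st <- cfg$windowStep
  meta <- list()
  idx <- list()
  for (ch in unique(tallies$chrom)) {
    rows <- which(tallies$chrom == ch)
    n <- length(rows)
    if (n < wb) next
    starts <- seq.int(1L, n - wb + 1L, by = st)
    for (s in starts) {
      r <- rows[s:(s + wb - 1L)]
      meta[[length(meta) + 1L]] <- data.frame(
        chrom = ch, start = tallies$start[r[1]], end = tallies$end[r[wb]],
        nBlocks = wb)
      idx[[length(idx) + 1L]] <- r
    }
  }
  meta <- if (length(meta)) do.call(rbind, meta)
          else data.frame(chrom = character(), start = integer(),
                          end = integer(), nBlocks = integer())
  structure(list(meta = meta, blockIndex = idx), class = "WindowSet")
}

#' @exportS3Method base::print
print.WindowSet <- function(x, ...) {
  cat(sprintf("WindowSet: %d window(s)\n", nrow(x$meta)))
  invisible(x)
}

#' Per-window bSFS cell counts
#'
#' @param windows a `"WindowSet"` from [makeWindows()].
#' @param tallies the block-tally data frame the windows index into.
#' @param kmax truncation bound (defaults to the tallies' attribute).
#' @return integer matrix, one row per window, `(kmax + 2)^4` columns.
#' @export
windowCounts <- function(windows, tallies, kmax = attr(tallies, "kmax")) {
  t(vapply(windows$blockIndex,
           function(r) countsVector(tallies[r, , drop = FALSE], kmax),
           integer((kmax + 2L)^4)))
}

#' Diversity and divergence statistics from block tallies
#'
#' Per-site heterozygosity of each sample (`piA`, `piB`), mean pairwise
#' between-population difference (`dxy`) and a Hudson-style differentiation
#' estimate `fst = (dxy - (piA + piB)/2) / dxy`, undefined (NA) when
#' `dxy = 0`.  Marginal-flagged counts contribute exactly `kmax`, a
#' deterministic conservative floor.
#'
#' @param tallies block-tally data frame.
#' @param nSites number of callable sites underlying the tallies.
#' @return a list of class `"DiversityStats"`:
#'   `piA`, `piB`, `dxy`, `fst`, `nSites`.
#' @export
diversityStats <- function(tallies, nSites) {
  if (length(nSites) != 1 || nSites <= 0)
    stop("nSites must be a positive count")
  sA <- sum(tallies$hetA)
  sB <- sum(tallies$hetB)
  sAB <- sum(tallies$hetAB)
  sF <- sum(tallies$fixed)
  piA <- (sA + sAB) / nSites
  piB <- (sB + sAB) / nSites
  dxy <- (0.5 * sA + 0.5 * sB + 0.5 * sAB + sF) / nSites
  fst <- if (dxy > 0) (dxy - (piA + piB) / 2) / dxy else NA_real_
  structure(list(piA = piA, piB = piB, dxy = dxy, fst = fst,
                 nSites = nSites), class = "DiversityStats")
}

#' @exportS3Method base::print
print.DiversityStats <- function(x, ...) {
  cat(sprintf(
    "pi_A=%.3g pi_B=%.3g dxy=%.3g Fst=%s (n=%d sites)\n",
    x$piA, x$piB, x$dxy,
    if (is.na(x$fst)) "undefined" else sprintf("%.3g", x$fst),
    as.integer(x$nSites)))
  invisible(x)
}
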