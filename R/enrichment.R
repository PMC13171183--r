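## Inversion enrichment tests, the circular-resampling overlap test, and
## coverage/frequency summaries.

#' Format a count fraction as the field reports them
#'
#' One-decimal percentage with the counts in parentheses, e.g.
#' `"11.1% (1,050 out of 9,468)"`.
#'
#' @param num,den numerator and denominator counts.
#' @return character scalar.
#' @export
formatFraction <- function(num, den) {
  sprintf("%.1f%% (%s out of %s)", round(100 * num / den, 1),
          format(num, big.mark = ",", scientific = FALSE, trim = TRUE),
          format(den, big.mark = ",", scientific = FALSE, trim = TRUE))
}

#' @rdname formatFraction
#' @param bpNum,bpDen numerator and denominator in bp (printed in Mb).
#' @export
formatMbFraction <- function(bpNum, bpDen) {
  sprintf("%.1f%% (%.1fMb out of %.1fMb)", round(100 * bpNum / bpDen, 1),
          bpNum / 1e6, bpDen / 1e6)
}

#' Chi-square enrichment of flagged items inside the inversion
#'
#' Builds the 2x2 table (flagged / unflagged x inversion side / colinear)
#' and applies an uncorrected Pearson chi-square test.  Items are windows
#' (rows with `chrom`, `start`, `end`, classified by midpoint) or SNPs
#' (rows with `chrom`, `pos`).  With `useBuffer`, items whose midpoint falls
#' within the breakpoint buffer count towards the inversion side.  For
#' overlapping sliding windows, `divideBy = 5` (window step / window length)
#' converts the counts to approximately non-overlapping window numbers;
#' all four cells are divided and rounded to the nearest integer.
#'
#' @param items data frame of positions or windows.
#' @param flag logical vector (or name of a logical column in `items`)
#'   marking the significant/barrier items.
#' @param layout a [GenomeLayout-class].
#' @param useBuffer extend the inversion side by the breakpoint buffer.
#' @param divideBy divide all contingency cells by this count (default 1).
#' @param correct apply the Yates continuity correction (default FALSE, as
#'   appropriate for large counts).
#' @return a list of class `"ContingencyResult"`: `table`, `statistic`,
#'   `p.value`, `divideBy`, `expectedWarning`.
#' @export
enrichmentChi2 <- function(items, flag, layout, useBuffer = FALSE,
                           divideBy = 1, correct = FALSE) {
  if (is.character(flag) && length(flag) == 1) flag <- items[[flag]]
  stopifnot(is.logical(flag), length(flag) == nrow(items))
  if (all(c("start", "end") %in% names(items))) {
    cls <- classifyInterval(items$chrom, items$start, items$end, layout,
                            useBuffer = useBuffer)
  } else {
    cls <- classifyInterval(items$chrom, items$pos, items$pos, layout,
                            useBuffer = useBuffer)
  }
  side <- factor(ifelse(cls == "COL", "COL", "INV"), levels = c("INV", "COL"))
  tab <- table(flagged = factor(flag, levels = c(TRUE, FALSE)), side = side)
  tab <- round(tab / divideBy)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the contingency table is zero")
  test <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(table = tab, statistic = unname(test$statistic),
                 p.value = test$p.value, divideBy = divideBy,
                 expectedWarning = any(test$expected < 1)),
            class = "ContingencyResult")
}

#' @exportS3Method base::print
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("Chi-square = %.4g, P = %.4g%s\n", x$statistic, x$p.value,
              if (x$expectedWarning) " (warning: expected cell < 1)" else ""))
  print(x$table)
  invisible(x)
}

#' Circular-resampling overlap test between candidate SNPs and regions
#'
#' The observed proportion of candidate SNPs falling inside the regions is
#' compared with a null distribution obtained by rotating the SNP positions:
#' each resample draws one uniform offset per chromosome and shifts all SNP
#' positions by it modulo the chromosome length, preserving the inter-SNP
#' spacing (and hence local clustering) while breaking the association with
#' the fixed regions.  `p = (1 + #\{null >= observed\}) / (nResamples + 1)`.
#'
#' @param snps a `"CandidateSNPSet"` or data frame with `chrom`, `pos`.
#' @param regions a [GenomicRanges::GRanges] or `"BarrierRegions"`.
#' @param layout a [GenomeLayout-class].
#' @param nResamples number of rotations (default 1000).
#' @param seed integer seed.
#' @return a list of class `"OverlapTestResult"`: `observed`, `null`
#'   (numeric vector), `p.value`, `nResamples`, `seed`.
#' @export
circularOverlapTest <- function(snps, regions, layout, nResamples = 1000,
                                seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (inherits(snps, "CandidateSNPSet")) snps <- snps$snps
  if (inherits(regions, "BarrierRegions")) regions <- regions$regions
  if (nrow(snps) == 0) stop("empty candidate SNP set")
  cl <- chromLengths(layout)
  regChrom <- as.character(GenomeInfoDb::seqnames(regions))
  regByChrom <- lapply(names(cl), function(ch) {
    i <- regChrom == ch
    list(start = GenomicRanges::start(regions)[i],
         end = GenomicRanges::end(regions)[i])
  })
  names(regByChrom) <- names(cl)
  inRegion <- function(chrom, pos) {
    hit <- logical(length(pos))
    for (ch in unique(chrom)) {
      r <- regByChrom[[ch]]
      j <- chrom == ch
      if (is.null(r) || !length(r$start)) next
      o <- order(r$start)
      idx <- findInterval(pos[j], r$start[o])
      hit[j] <- idx > 0 & pos[j] <= r$end[o][pmax(idx, 1)]
    }
    hit
  }
  observed <- mean(inRegion(snps$chrom, snps$pos))
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nResamples), function(r) {
      off <- floor(stats::runif(length(cl)) * cl)
      names(off) <- names(cl)
      newPos <- ((snps$pos - 1 + off[snps$chrom]) %% cl[snps$chrom]) + 1
      mean(inRegion(snps$chrom, newPos))
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (nResamples + 1)
  structure(list(observed = observed, null = null, p.value = p,
                 nResamples = nResamples, seed = as.integer(seed)),
            class = "OverlapTestResult")
}

#' @exportS3Method base::print
print.OverlapTestResult <- function(x, ...) {
  cat(sprintf(
    "Circular overlap test: observed %.3f, null mean %.3f, P = %.4g (%d resamples)\n",
    x$observed, mean(x$null), x$p.value, x$nResamples))
  invisible(x)
}

#' Coverage summary of a calibrated barrier scan
#'
#' Emits the headline fractions of a scan in the field's reporting format:
#' share of windows with positive `deltaB0`, share of those passing the FPR
#' criterion, genome fraction inside merged barrier regions, and the
#' fraction of each inversion covered by barriers.
#'
#' @param scan calibrated scan data frame (see [calibrateFpr()]).
#' @param regions a `"BarrierRegions"` from [mergeBarriers()].
#' @param layout a [GenomeLayout-class].
#' @return named character vector of formatted fractions.
#' @export
summarizeCoverage <- function(scan, regions, layout) {
  out <- regions$summary
  inv <- inversions(layout)
  if (length(inv)) {
    ov <- GenomicRanges::intersect(regions$regions, inv,
                                   ignore.strand = TRUE)
    out <- c(out, inversionInBarriers = formatMbFraction(
      sum(GenomicRanges::width(ov)), sum(GenomicRanges::width(inv))))
    colBp <- regions$genomeBp - sum(GenomicRanges::width(inv))
    out <- c(out, colinearInBarriers = formatMbFraction(
      regions$totalBp - sum(GenomicRanges::width(ov)), colBp))
  }
  out
}

#' Inversion karyotype frequency
#'
#' Allele frequency of the inverted arrangement from genotype counts:
#' `(2 * homInv + het) / (2 * total)`.
#'
#' @param homInv,het,homStd counts of inverted homozygotes, heterozygotes
#'   and standard homozygotes (vectorized, e.g. one entry per population).
#' @return numeric frequency in `[0, 1]`.
#' @examples
#' inversionFrequency(10, 0, 0)        # fixed
#' inversionFrequency(1, 2, 6)         # 4/18
#' @export
inversionFrequency <- function(homInv, het, homStd) {
  if (any(c(homInv, het, homStd) < 0)) stop("counts must be non-negative")
  total <- homInv + het + homStd
  if (any(total == 0)) stop("zero total genotype count")
  (2 * homInv + het) / (2 * total)
}
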