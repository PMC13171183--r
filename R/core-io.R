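## Genome data model, readers/writers and region classification.
##
## Internally all intervals are held as GenomicRanges objects in the usual
## 1-based, closed convention; BED files and the 0-based half-open breakpoint
## coordinates of layout configs are converted on load and on write, so no
## other part of the package ever mixes conventions.

#' Construct a genome layout
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param inversions a [GenomicRanges::GRanges] of inversion intervals
#'   (1-based, closed), or `NULL` for none.
#' @param bufferBp breakpoint buffer in bp over which recombination
#'   suppression is assumed to extend beyond the inversion (default 1.5 Mb).
#' @return a [GenomeLayout-class].
#' @examples
#' genomeLayout(c(chr4 = 3e7),
#'              GenomicRanges::GRanges("chr4",
#'                                     IRanges::IRanges(10000001, 19500000)))
#' @export
genomeLayout <- function(chromLengths, inversions = NULL,
                         bufferBp = 1500000) {
  if (is.null(inversions))
    inversions <- GenomicRanges::GRanges()
  methods::new("GenomeLayout",
               chromLengths = stats::setNames(as.numeric(chromLengths),
                                              names(chromLengths)),
               inversions = inversions, bufferBp = as.numeric(bufferBp))
}

#' Load a genome layout from a YAML config
#'
#' The config lists chromosomes (`name`, `length`), inversion intervals
#' (`chromosome`, `start`, `end`; 0-based half-open, BED-style) and an
#' optional `buffer_bp` (default 1,500,000).
#'
#' @param path path to the YAML file.
#' @return a validated [GenomeLayout-class]; inversions out of chromosome
#'   bounds or on unknown chromosomes are a hard error naming the interval.
#' @examples
#' cfg <- system.file("extdata", "example_layout.yaml", package = "invscan")
#' loadGenomeLayout(cfg)
#' @seealso [writeGenomeLayout()]
#' @export
loadGenomeLayout <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chromosomes) || !length(cfg$chromosomes))
    stop("layout config must list at least one chromosome")
  cl <- stats::setNames(
    vapply(cfg$chromosomes, function(x) as.numeric(x$length), numeric(1)),
    vapply(cfg$chromosomes, function(x) as.character(x$name), character(1)))
  inv <- GenomicRanges::GRanges()
  if (length(cfg$inversions)) {
    ic <- vapply(cfg$inversions, function(x) as.character(x$chromosome),
                 character(1))
    is0 <- vapply(cfg$inversions, function(x) as.numeric(x$start), numeric(1))
    ie <- vapply(cfg$inversions, function(x) as.numeric(x$end), numeric(1))
    bad <- !(ic %in% names(cl))
    if (any(bad))
      stop(sprintf("inversion %s:%d-%d: unknown chromosome '%s'",
                   ic[bad][1], is0[bad][1], ie[bad][1], ic[bad][1]))
    inv <- GenomicRanges::GRanges(ic, IRanges::IRanges(is0 + 1, ie))
  }
  buf <- if (is.null(cfg$buffer_bp)) 1500000 else as.numeric(cfg$buffer_bp)
  layout <- genomeLayout(cl, inv, buf)
  methods::validObject(layout)
  layout
}

#' Write a genome layout to a YAML config
#'
#' Inversions are written back in the 0-based half-open convention used by
#' [loadGenomeLayout()], so write/load round-trips are exact.
#'
#' @param layout a [GenomeLayout-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeLayout <- function(layout, path) {
  inv <- inversions(layout)
  cfg <- list(
    chromosomes = unname(Map(function(n, l) list(name = n, length = l),
                             names(chromLengths(layout)),
                             as.numeric(chromLengths(layout)))),
    inversions = unname(Map(function(c, s, e)
        list(chromosome = c, start = s - 1, end = e),
      as.character(GenomeInfoDb::seqnames(inv)),
      GenomicRanges::start(inv), GenomicRanges::end(inv))),
    buffer_bp = bufferBp(layout))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Classify genomic intervals relative to an inversion
#'
#' An interval is assigned `INV` if its midpoint lies inside an inversion;
#' `BUFFER` if (with `useBuffer = TRUE`) the midpoint lies within
#' `bufferBp(layout)` of an inversion breakpoint; otherwise `COL` (colinear).
#' The midpoint rule makes the assignment of windows straddling a breakpoint
#' deterministic.
#'
#' @param chrom,start,end interval coordinates (1-based, closed), vectorized.
#' @param layout a [GenomeLayout-class].
#' @param useBuffer include the breakpoint buffer class.
#' @return character vector in `c("INV", "BUFFER", "COL")`.
#' @export
classifyInterval <- function(chrom, start, end, layout, useBuffer = FALSE) {
  cl <- chromLengths(layout)
  if (any(!(chrom %in% names(cl))))
    stop("interval on unknown chromosome")
  if (any(start < 1 | end > cl[chrom] | start > end))
    stop("interval outside chromosome bounds")
  mid <- floor((as.numeric(start) + as.numeric(end)) / 2)
  out <- rep("COL", length(mid))
  inv <- inversions(layout)
  if (length(inv)) {
    ic <- as.character(GenomeInfoDb::seqnames(inv))
    is <- GenomicRanges::start(inv)
    ie <- GenomicRanges::end(inv)
    buf <- bufferBp(layout)
    for (i in seq_along(inv)) {
      inside <- chrom == ic[i] & mid >= is[i] & mid <= ie[i]
      out[inside] <- "INV"
      if (useBuffer) {
        near <- chrom == ic[i] & !inside &
          mid >= is[i] - buf & mid <= ie[i] + buf
        out[near & out == "COL"] <- "BUFFER"
      }
    }
  }
  out
}

#' Load a callable-site mask from a BED file
#'
#' Overlapping or adjacent input intervals are merged and intervals are
#' clipped to chromosome bounds.  An interval on a chromosome not present in
#' the layout is an error.
#'
#' @param path BED file (0-based half-open, converted on import).
#' @param layout a [GenomeLayout-class].
#' @return a reduced [GenomicRanges::GRanges] of callable intervals.
#' @export
loadCallableMask <- function(path, layout) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") &
    !startsWith(lines, "browser") & !startsWith(lines, "#")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  starts <- suppressWarnings(
    as.numeric(vapply(fields, function(f) f[2][1], character(1))))
  ends <- suppressWarnings(
    as.numeric(vapply(fields, function(f) f[3][1], character(1))))
  bad <- which(nf < 3 | !is.finite(starts) | !is.finite(ends) |
               starts < 0 | ends < starts)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s",
                 which(keep)[bad[1]], path))
  if (!any(keep)) return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "BED")
  cl <- chromLengths(layout)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  if (any(!(chr %in% names(cl))))
    stop(sprintf("mask interval on unknown chromosome '%s'",
                 setdiff(chr, names(cl))[1]))
  GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1)
  GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), cl[chr])
  GenomicRanges::reduce(gr)
}

#' Write a callable mask to BED
#'
#' @param mask a [GenomicRanges::GRanges].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeCallableMask <- function(mask, path) {
  rtracklayer::export(mask, path, format = "BED")
  invisible(path)
}

#' Load pair genotypes for one sample from each population
#'
#' Reads a VCF and keeps biallelic SNP records for the two named samples;
#' multiallelic and indel records are dropped (count reported via
#' `message()`).  Genotypes are coded as alternate-allele counts 0/1/2 with
#' `NA` for missing; sites with a missing genotype in either sample are kept
#' but flagged so downstream block tallying can exclude them.
#'
#' @param path VCF path.
#' @param sampleA,sampleB sample names in the VCF header (population A / B).
#' @return a data frame of class `"PairGenotypes"` with columns `chrom`,
#'   `pos` (1-based), `gtA`, `gtB`.
#' @export
loadPairGenotypes <- function(path, sampleA, sampleB) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(c(sampleA, sampleB), samples)
  if (length(missing))
    stop(sprintf("sample '%s' not present in VCF header", missing[1]))
  nTotal <- nrow(v@fix)
  if (is.null(nTotal) || nTotal == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      gtA = integer(), gtB = integer())
    class(out) <- c("PairGenotypes", "data.frame")
    return(out)
  }
  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nDropped <- sum(!snp)
  if (nDropped)
    message(sprintf("dropped %d non-biallelic-SNP record(s)", nDropped))
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    a1 <- substr(g, 1, 1)
    a2 <- substr(g, 3, 3)
    ifelse(a1 %in% c("0", "1") & a2 %in% c("0", "1"),
           (a1 == "1") + (a2 == "1"), NA_integer_)
  }
  out <- data.frame(
    chrom = v@fix[snp, "CHROM"],
    pos = as.integer(v@fix[snp, "POS"]),
    gtA = as.integer(code(gt[snp, sampleA])),
    gtB = as.integer(code(gt[snp, sampleB])))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  dup <- duplicated(out[c("chrom", "pos")])
  if (any(dup)) {
    message(sprintf("dropped %d duplicate-position record(s)", sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("PairGenotypes", "data.frame")
  out
}

#' Load a candidate SNP set from TSV
#'
#' Expects a header with columns `chrom` and `pos` (1-based positions, as in
#' a VCF).  Positions are deduplicated, sorted and bounds-checked against
#' the layout.
#'
#' @param path TSV path.
#' @param layout a [GenomeLayout-class].
#' @param label free-text label for the set (e.g. the associated variable).
#' @return a list of class `"CandidateSNPSet"` with elements `label` and
#'   `snps` (data frame `chrom`, `pos`).
#' @export
loadCandidateSnps <- function(path, layout, label = basename(path)) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(x)))
    stop("candidate SNP TSV must have 'chrom' and 'pos' columns")
  candidateSnpSet(x$chrom, x$pos, layout, label)
}

#' Construct a candidate SNP set
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param layout a [GenomeLayout-class] for bounds checking.
#' @param label free-text label.
#' @return a list of class `"CandidateSNPSet"`.
#' @export
candidateSnpSet <- function(chrom, pos, layout, label = "candidates") {
  cl <- chromLengths(layout)
  if (any(!(chrom %in% names(cl))))
    stop("candidate SNP on unknown chromosome")
  if (any(pos < 1 | pos > cl[chrom]))
    stop("candidate SNP position outside chromosome bounds")
  snps <- unique(data.frame(chrom = as.character(chrom),
                            pos = as.integer(pos)))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  structure(list(label = label, snps = snps), class = "CandidateSNPSet")
}

#' @exportS3Method base::print
print.CandidateSNPSet <- function(x, ...) {
  cat(sprintf("CandidateSNPSet '%s': %d SNPs on %d chromosome(s)\n",
              x$label, nrow(x$snps), length(unique(x$snps$chrom))))
  invisible(x)
}
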