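# Shared in-code fixtures: toy layouts, a tiny VCF writer and small models.

toyLayout <- function(len = 1e6, invStart = 400001, invEnd = 600000,
                      buffer = 50000) {
  genomeLayout(c(chr1 = len),
               GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(invStart, invEnd)),
               bufferBp = buffer)
}

# the 9.5 Mb chr4 inversion geometry used throughout the scenario generator
chr4Layout <- function() {
  genomeLayout(c(chr4 = 3e7),
               GenomicRanges::GRanges("chr4",
                                      IRanges::IRanges(10000001, 19500000)),
               bufferBp = 1500000)
}

writeTestVcf <- function(path, rows,
                         samples = c("popA_1", "popB_1"),
                         contig = "chr1") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=1000000>", contig),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

vcfRow <- function(pos, ref, alt, gtA, gtB, chrom = "chr1") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gtA, gtB),
        collapse = "\t")
}

fastDivModel <- function(Tgen = 5e5, mu = 2.8e-9) {
  demographicModel("DIV", NeA = 1e5, NeB = 2e5, NeAnc = 1.5e5, Tgen = Tgen,
                   mu = mu)
}

# mean per-block mutation-type counts from a cell-count or frequency vector
typeMeans <- function(freq, kmax) {
  L <- kmax + 2L
  arr <- array(freq / sum(freq), dim = rep(L, 4))
  val <- c(0:kmax, kmax + 1)
  vapply(1:4, function(d) sum(apply(arr, d, sum) * val), numeric(1))
}
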