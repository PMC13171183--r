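## Structured-coalescent synthetic data: block tallies, window sets, full
## scenario datasets and the Monte Carlo oracle for the likelihood engine.
## Blocks are simulated independently (no within-window linkage): the
## composite likelihood treats blocks as independent, so linkage affects
## only the variance of window statistics, not their expectation.

.rawToTallies <- function(raw, kmax, coords = NULL) {
  cnt <- pmin(raw, kmax)
  out <- data.frame(hetA = cnt[, 1], hetB = cnt[, 2], hetAB = cnt[, 3],
                    fixed = cnt[, 4],
                    mHetA = raw[, 1] > kmax, mHetB = raw[, 2] > kmax,
                    mHetAB = raw[, 3] > kmax, mFixed = raw[, 4] > kmax)
  if (!is.null(coords)) out <- cbind(coords, out)
  attr(out, "kmax") <- kmax
  out
}

.simRaw <- function(model, nBlocks, cfg) {
  simulate_blocks_cpp(
    as.integer(nBlocks), model@NeA, model@NeB, model@NeAnc, model@Tgen,
    if (model@kind == "DIV") 0 else model@me,
    destA = model@direction == "BtoA", mu = model@mu,
    blockSites = cfg$blockSites)
}

#' Simulate block tallies under a demographic model
#'
#' Each block draws an independent four-lineage structured-coalescent
#' genealogy (two demes until `Tgen`, then the ancestral deme), lays down
#' Poisson mutations on the per-type branch-length exposures and truncates
#' the counts at `cfg$kmax`.  Bit-identical output for identical
#' `(model, nBlocks, cfg, seed)`.
#'
#' @param model a [DemographicModel-class].
#' @param nBlocks number of independent blocks.
#' @param cfg a [blockConfig()].
#' @param seed integer seed (mandatory).
#' @return a block-tally data frame (no coordinates), attribute `kmax`.
#' @examples
#' m <- demographicModel("DIV", 1e5, 1e5, 1e5, Tgen = 5e5)
#' t <- simulateBlockTallies(m, 100, seed = 1)
#' @export
simulateBlockTallies <- function(model, nBlocks, cfg = blockConfig(), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  raw <- withr::with_seed(as.integer(seed), .simRaw(model, nBlocks, cfg))
  .rawToTallies(raw, cfg$kmax)
}

#' Monte Carlo oracle for the bSFS table
#'
#' Empirical frequencies of the truncated mutation-type tuples over
#' `nReps` independently simulated blocks; sums to one exactly.  Used to
#' cross-validate [bsfsTable()] (the two are independent code paths: event
#' simulation versus marginalization of the Markov chain).
#'
#' @param model a [DemographicModel-class].
#' @param cfg a [blockConfig()].
#' @param nReps number of simulated blocks (>= 1e4 recommended).
#' @param seed integer seed.
#' @return named numeric vector of cell frequencies (see [bsfsCellLabels()]).
#' @export
mcBsfsOracle <- function(model, cfg = blockConfig(), nReps = 1e5, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  raw <- withr::with_seed(as.integer(seed), .simRaw(model, nReps, cfg))
  countsVector(raw, cfg$kmax) / nReps
}

#' Simulate a set of windows, optionally heterogeneous across windows
#'
#' Windows are independent; each contains `blocksPerWindow` independent
#' blocks drawn from its own model.  Per-window seeds are derived as
#' `seed XOR windowIndex`, so any window can be reproduced in isolation.
#'
#' @param models a single [DemographicModel-class] (recycled) or a list with
#'   one model per window.
#' @param nWindows number of windows.
#' @param blocksPerWindow blocks per window.
#' @param cfg a [blockConfig()].
#' @param seed master integer seed.
#' @return integer matrix of per-window bSFS cell counts
#'   (`nWindows` x `(kmax + 2)^4`).
#' @export
simulateWindowSet <- function(models, nWindows, blocksPerWindow,
                              cfg = blockConfig(), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is(models, "DemographicModel")) models <- rep(list(models), nWindows)
  stopifnot(length(models) == nWindows)
  C <- (cfg$kmax + 2L)^4
  out <- matrix(0L, nWindows, C)
  for (i in seq_len(nWindows)) {
    raw <- withr::with_seed(bitwXor(as.integer(seed), i),
                            .simRaw(models[[i]], blocksPerWindow, cfg))
    out[i, ] <- countsVector(raw, cfg$kmax)
  }
  colnames(out) <- bsfsCellLabels(cfg$kmax)
  out
}

#' Default scenario genome layout
#'
#' Five ~29.1 Mb chromosomes (145.5 Mb total) with one 9.5 Mb inversion on
#' chr4 between 10 Mb and 19.5 Mb and a 1.5 Mb breakpoint buffer — the
#' geometry of the study system the generator emulates.
#'
#' @return a [GenomeLayout-class].
#' @export
defaultScenarioLayout <- function() {
  cl <- stats::setNames(rep(29100000, 5), c("chrX", "chr2", "chr3", "chr4",
                                            "chr5"))
  inv <- GenomicRanges::GRanges("chr4", IRanges::IRanges(10000001, 19500000))
  genomeLayout(cl, inv, 1500000)
}

#' Table 1-scale default models for scenario generation
#'
#' Background: IM with forwards-time gene flow B -> A at the colinear
#' parameter scale (NeAnc 438,089; NeA 147,816; NeB 1,070,603;
#' T 958,812 generations; me 4.95e-7).  Inversion override: older split
#' (T 1,347,905) and reduced migration (me 2.06e-7) at the inverted-region
#' scale (NeAnc 646,563; NeA 179,131; NeB 1,137,026).
#'
#' @name scenarioModels
#' @return a [DemographicModel-class].
#' @export
backgroundModel <- function() {
  demographicModel("IM", NeA = 147816, NeB = 1070603, NeAnc = 438089,
                   Tgen = 958812, me = 4.95e-7, direction = "BtoA")
}

#' @rdname scenarioModels
#' @export
inversionModel <- function() {
  demographicModel("IM", NeA = 179131, NeB = 1137026, NeAnc = 646563,
                   Tgen = 1347905, me = 2.06e-7, direction = "BtoA")
}

#' Generate a full synthetic scenario dataset
#'
#' Tiles the genome with non-overlapping windows, simulates colinear windows
#' from the background model and inversion windows from the override model
#' (classified by window midpoint), places candidate SNPs uniformly with an
#' optional enrichment towards true-barrier windows, and keeps truth labels
#' for every window.
#'
#' @param layout a [GenomeLayout-class] (default [defaultScenarioLayout()]).
#' @param background background [DemographicModel-class].
#' @param inversionOverride model for windows inside inversions, or `NULL`
#'   to use the background everywhere.
#' @param nWindows number of windows tiling the genome.
#' @param blocksPerWindow blocks simulated per window.
#' @param nSnps number of candidate SNPs.
#' @param enrichmentFactor density ratio of candidate SNPs in true-barrier
#'   windows relative to elsewhere; 1 = uniform placement; < 1 is an error.
#' @param cfg a [blockConfig()].
#' @param seed master integer seed.
#' @return a list of class `"ScenarioDataset"`: `layout`, `mask`, `windows`
#'   (meta with region class and truth label), `counts` (per-window bSFS
#'   cell counts), `snps` (a `"CandidateSNPSet"`), `background`, `override`,
#'   `cfg`, `seed`.
#' @export
generateScenario <- function(layout = defaultScenarioLayout(),
                             background = backgroundModel(),
                             inversionOverride = inversionModel(),
                             nWindows = 100, blocksPerWindow = 1250,
                             nSnps = 1000, enrichmentFactor = 1,
                             cfg = blockConfig(), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (enrichmentFactor < 1) stop("enrichmentFactor must be >= 1")
  cl <- chromLengths(layout)
  nPer <- diff(c(0, round(cumsum(cl / sum(cl)) * nWindows)))
  meta <- do.call(rbind, lapply(seq_along(cl), function(i) {
    n <- nPer[i]
    if (n == 0) return(NULL)
    span <- floor(cl[i] / n)
    s <- (seq_len(n) - 1) * span + 1
    data.frame(chrom = names(cl)[i], start = s, end = s + span - 1)
  }))
  rownames(meta) <- NULL
  meta$class <- classifyInterval(meta$chrom, meta$start, meta$end, layout)
  useOverride <- meta$class == "INV" & !is.null(inversionOverride)
  meta$isTrueBarrier <- useOverride &
    (if (is.null(inversionOverride)) FALSE
     else inversionOverride@me < background@me)
  models <- lapply(useOverride, function(o)
    if (o) inversionOverride else background)
  counts <- simulateWindowSet(models, nrow(meta), blocksPerWindow, cfg,
                              seed = seed)
  snps <- withr::with_seed(bitwXor(as.integer(seed), 999983L),
    .placeSnps(meta, layout, nSnps, enrichmentFactor))
  mask <- GenomicRanges::GRanges(names(cl), IRanges::IRanges(1, cl))
  structure(list(layout = layout, mask = mask, windows = meta,
                 counts = counts, snps = snps, background = background,
                 override = inversionOverride, cfg = cfg, seed = seed),
            class = "ScenarioDataset")
}

.placeSnps <- function(meta, layout, nSnps, factor) {
  cl <- chromLengths(layout)
  barrier <- meta[meta$isTrueBarrier, , drop = FALSE]
  aB <- sum(barrier$end - barrier$start + 1)
  G <- sum(cl)
  pB <- if (aB > 0) factor * aB / (factor * aB + (G - aB)) else 0
  inB <- stats::rbinom(nSnps, 1, pB) == 1
  pos <- integer(nSnps)
  chrom <- character(nSnps)
  nIn <- sum(inB)
  if (nIn) {
    w <- barrier$end - barrier$start + 1
    row <- sample.int(nrow(barrier), nIn, replace = TRUE, prob = w)
    chrom[inB] <- barrier$chrom[row]
    pos[inB] <- barrier$start[row] +
      floor(stats::runif(nIn) * (barrier$end[row] - barrier$start[row] + 1))
  }
  nOut <- nSnps - nIn
  if (nOut) {
    # uniform over the genome outside the barrier windows, by rejection
    got <- 0L
    oc <- character(0)
    op <- integer(0)
    while (got < nOut) {
      m <- (nOut - got) * 2L + 10L
      ci <- sample.int(length(cl), m, replace = TRUE, prob = cl)
      pp <- floor(stats::runif(m) * cl[ci]) + 1
      cc <- names(cl)[ci]
      bad <- rep(FALSE, m)
      if (nrow(barrier)) {
        for (j in seq_len(nrow(barrier)))
          bad <- bad | (cc == barrier$chrom[j] & pp >= barrier$start[j] &
                        pp <= barrier$end[j])
      }
      keep <- which(!bad)[seq_len(min(sum(!bad), nOut - got))]
      oc <- c(oc, cc[keep])
      op <- c(op, pp[keep])
      got <- got + length(keep)
    }
    chrom[!inB] <- oc
    pos[!inB] <- op
  }
  candidateSnpSet(chrom, pos, layout, label = "scenario")
}

#' @exportS3Method base::print
print.ScenarioDataset <- function(x, ...) {
  cat(sprintf(
    "ScenarioDataset: %d windows (%d INV, %d true barriers), %d SNPs\n",
    nrow(x$windows), sum(x$windows$class == "INV"),
    sum(x$windows$isTrueBarrier), nrow(x$snps$snps)))
  invisible(x)
}
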