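## Sliding-window barrier scan: per-window Delta_B0 on the parameter grid,
## per-window simulated-null FPR calibration, and merging of barrier
## windows into barrier regions.
##
## Delta_B0 = lnCL(best grid point with me = 0) - lnCL(best grid point with
## me = background), both maximized over the Ne grid and the admissible
## split times; positive values support locally reduced gene flow.

#' Scan windows for local support of reduced gene flow
#'
#' For each window, computes the two constrained grid maxima (me fixed at 0
#' and at the background estimate, Ne values and the admissible split times
#' free) and their difference `deltaB0`.  bSFS tables are cached and shared
#' across windows.
#'
#' @param counts per-window bSFS cell-count matrix ([windowCounts()] or
#'   [simulateWindowSet()]).
#' @param grid a `"GridSpec"` whose `me` sequence contains 0 and
#'   `meBackground`.
#' @param meBackground background effective migration rate (from the global
#'   IM fit).
#' @param direction forwards-time gene-flow direction of the background fit.
#' @param cfg a [blockConfig()].
#' @param mu mutation rate (the study's local mode used 2.9e-9).
#' @param meta optional per-window data frame (coordinates, class) bound to
#'   the result.
#' @param cache environment for table caching (created if `NULL`; also
#'   attached to the result for reuse by [calibrateFpr()]).
#' @return data frame, one row per window: `lnCL_DIV`, `lnCL_IM_bg`,
#'   `deltaB0`, the best background parameters `bestNeA`, `bestNeB`,
#'   `bestNeAnc`, `bestT`, plus any `meta` columns; attributes carry the
#'   grid, background rate and log-probability matrix for calibration.
#' @export
scanWindows <- function(counts, grid, meBackground, direction = "BtoA",
                        cfg = blockConfig(), mu = 2.9e-9, meta = NULL,
                        cache = NULL) {
  stopifnot(inherits(grid, "GridSpec"))
  if (!any(grid$me == 0))
    stop("the grid's me sequence must contain 0")
  if (!any(grid$me == meBackground))
    stop("the grid's me sequence must contain the background estimate")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)

  ne <- expand.grid(NeA = grid$NeA, NeB = grid$NeB, NeAnc = grid$NeAnc,
                    KEEP.OUT.ATTRS = FALSE)
  cols <- do.call(rbind, lapply(grid$Toptions, function(Tv) {
    do.call(rbind, lapply(c(0, meBackground), function(me) {
      cbind(ne, me = me, Tgen = Tv)
    }))
  }))
  logP <- do.call(cbind, lapply(unique(cols$Tgen), function(Tv) {
    sub <- cols[cols$Tgen == Tv, c("NeA", "NeB", "NeAnc", "me")]
    .gridLogP(sub, Tv, direction, cfg, mu, cache)
  }))
  # cbind column order matches cols row order (both grouped by Tgen)
  lnCL <- counts %*% logP
  iDiv <- which(cols$me == 0)
  iBg <- which(cols$me == meBackground)
  lnDIV <- apply(lnCL[, iDiv, drop = FALSE], 1, max)
  bgIdx <- apply(lnCL[, iBg, drop = FALSE], 1, which.max)
  lnBG <- lnCL[cbind(seq_len(nrow(lnCL)), iBg[bgIdx])]
  bestRows <- cols[iBg[bgIdx], , drop = FALSE]
  out <- data.frame(
    window = seq_len(nrow(counts)),
    lnCL_DIV = lnDIV, lnCL_IM_bg = lnBG, deltaB0 = lnDIV - lnBG,
    bestNeA = bestRows$NeA, bestNeB = bestRows$NeB,
    bestNeAnc = bestRows$NeAnc, bestT = bestRows$Tgen)
  if (!is.null(meta)) out <- cbind(meta, out)
  attr(out, "grid") <- grid
  attr(out, "meBackground") <- meBackground
  attr(out, "direction") <- direction
  attr(out, "cfg") <- cfg
  attr(out, "mu") <- mu
  attr(out, "logP") <- logP
  attr(out, "cols") <- cols
  attr(out, "cache") <- cache
  out
}

#' Calibrate the scan with per-window simulated nulls
#'
#' For each window, simulates `nSims` replicate windows under that window's
#' best background history (its best-fitting Ne values and split time, with
#' me fixed at the background level), recomputes `deltaB0` for each
#' replicate, and labels the window a barrier when its observed `deltaB0`
#' is positive and exceeds the largest null value (false positive rate
#' <= 1/(nSims + 1) per window under the null).  Null simulations are
#' seeded per window as `seed XOR windowIndex`.
#'
#' @param scan result of [scanWindows()].
#' @param blocksPerWindow blocks per simulated replicate window (match the
#'   observed windows).
#' @param nSims null replicates per window (default 100).
#' @param seed master integer seed.
#' @return `scan` with columns `nullMax` and `isBarrier` added.
#' @export
calibrateFpr <- function(scan, blocksPerWindow, nSims = 100, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  grid <- attr(scan, "grid")
  meBg <- attr(scan, "meBackground")
  direction <- attr(scan, "direction")
  cfg <- attr(scan, "cfg")
  logP <- attr(scan, "logP")
  cols <- attr(scan, "cols")
  iDiv <- which(cols$me == 0)
  iBg <- which(cols$me == meBg)
  nullMax <- numeric(nrow(scan))
  for (i in seq_len(nrow(scan))) {
    m <- demographicModel(if (meBg > 0) "IM" else "DIV",
                          NeA = scan$bestNeA[i], NeB = scan$bestNeB[i],
                          NeAnc = scan$bestNeAnc[i], Tgen = scan$bestT[i],
                          me = meBg, direction = direction,
                          mu = attr(scan, "mu"))
    nullCounts <- withr::with_seed(bitwXor(as.integer(seed), i), {
      t(vapply(seq_len(nSims), function(r)
        countsVector(.simRaw(m, blocksPerWindow, cfg), cfg$kmax),
        integer((cfg$kmax + 2L)^4)))
    })
    nullLn <- nullCounts %*% logP
    nullDelta <- apply(nullLn[, iDiv, drop = FALSE], 1, max) -
      apply(nullLn[, iBg, drop = FALSE], 1, max)
    nullMax[i] <- max(nullDelta)
  }
  scan$nullMax <- nullMax
  scan$isBarrier <- scan$deltaB0 > 0 & scan$deltaB0 > nullMax
  scan
}

#' Merge barrier windows into barrier regions
#'
#' Overlapping or adjacent barrier windows are merged per chromosome; the
#' summary reports the intermediate fractions (share of windows with
#' positive `deltaB0`, share of those passing the FPR criterion) and the
#' genomic extent of the merged regions.
#'
#' @param scan calibrated scan (with `chrom`/`start`/`end` meta columns and
#'   `isBarrier`).
#' @param layout a [GenomeLayout-class].
#' @return a list of class `"BarrierRegions"`: `regions` (GRanges),
#'   `nRegions`, `totalBp`, `genomeBp`, `fraction`, `nWindows`,
#'   `nDeltaPos`, `nBarrier` and a formatted `summary` character vector.
#' @export
mergeBarriers <- function(scan, layout) {
  stopifnot(all(c("chrom", "start", "end", "isBarrier") %in% names(scan)))
  bw <- scan[scan$isBarrier, , drop = FALSE]
  regions <- if (nrow(bw))
    GenomicRanges::reduce(GenomicRanges::GRanges(
      bw$chrom, IRanges::IRanges(bw$start, bw$end)))
  else GenomicRanges::GRanges()
  totalBp <- sum(GenomicRanges::width(regions))
  genomeBp <- sum(chromLengths(layout))
  nW <- nrow(scan)
  nPos <- sum(scan$deltaB0 > 0)
  nBar <- sum(scan$isBarrier)
  summary <- c(
    deltaPositive = formatFraction(nPos, nW),
    passedFpr = formatFraction(nBar, max(nPos, 1)),
    genomeInBarriers = formatMbFraction(totalBp, genomeBp))
  structure(list(regions = regions, nRegions = length(regions),
                 totalBp = totalBp, genomeBp = genomeBp,
                 fraction = totalBp / genomeBp, nWindows = nW,
                 nDeltaPos = nPos, nBarrier = nBar, summary = summary),
            class = "BarrierRegions")
}

#' @exportS3Method base::print
print.BarrierRegions <- function(x, ...) {
  cat(sprintf("BarrierRegions: %d region(s), %s of the genome\n",
              x$nRegions, x$summary[["genomeInBarriers"]]))
  cat(sprintf("  windows with deltaB0 > 0: %s; passing FPR: %s\n",
              x$summary[["deltaPositive"]], x$summary[["passedFpr"]]))
  invisible(x)
}
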