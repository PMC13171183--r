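## Exact bSFS likelihood engine.
##
## The probability of each truncated mutation-type tuple in a block is
## computed from a continuous-time Markov chain over (lineage configuration
## x truncated mutation-count vector) for the four lineages of one diploid
## sampled from each population: within-deme coalescence at rate 1/(2*Ne)
## per pair, backwards-in-time migration of destination-deme lineages into
## the source deme at rate me, and mutation at rate mu*blockSites per
## lineage, classified by the leaves the lineage subtends.  At Tgen the
## chain drops into a single ancestral deme of size NeAnc and runs to the
## MRCA.  Lineage configurations are lumped under the exchangeability of the
## two leaves within each diploid.  Blocks are assumed non-recombining with
## a constant mutation rate.

.invscanEnv <- new.env(parent = emptyenv())

# mutation type of a lineage by subtended-leaf bitmask (a1=1,a2=2,b1=4,b2=8):
# 1 = hetA, 2 = hetB, 3 = hetAB, 4 = fixed, NA = MRCA (invisible)
.MASK_TYPE <- c(1L, 1L, 4L, 2L, 3L, 3L, 2L, 2L, 3L, 3L, 2L, 4L, 1L, 1L,
                NA_integer_)

# masks 0..15 relabelled under a1<->a2 and/or b1<->b2
.permMasks <- function(swapA, swapB) {
  m <- 0:15
  out <- m
  if (swapA)
    out <- bitwOr(bitwAnd(out, 12L),
                  bitwOr(bitwShiftL(bitwAnd(out, 1L), 1L),
                         bitwShiftR(bitwAnd(out, 2L), 1L)))
  if (swapB)
    out <- bitwOr(bitwAnd(out, 3L),
                  bitwOr(bitwShiftL(bitwAnd(out, 4L), 1L),
                         bitwShiftR(bitwAnd(out, 8L), 1L)))
  out
}

.PERMS <- list(.permMasks(FALSE, FALSE), .permMasks(TRUE, FALSE),
               .permMasks(FALSE, TRUE), .permMasks(TRUE, TRUE))

# canonical representative of a lineage configuration under the
# within-individual leaf-exchange symmetry
.canonConfig <- function(masks, demes) {
  bestKey <- NULL
  bestM <- NULL
  bestD <- NULL
  for (p in .PERMS) {
    pm <- p[masks + 1L]
    o <- order(pm, demes)
    key <- paste(sprintf("%02d%d", pm[o], demes[o]), collapse = ".")
    if (is.null(bestKey) || key < bestKey) {
      bestKey <- key
      bestM <- pm[o]
      bestD <- demes[o]
    }
  }
  list(key = bestKey, masks = bestM, demes = bestD)
}

# enumerate the lumped two-phase chain once per session
.bsfsStructure <- function() {
  if (!is.null(.invscanEnv$structure)) return(.invscanEnv$structure)

  addEdge <- function(env, from, to, cls) {
    key <- paste(from, to, cls, sep = "|")
    env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + 1
  }

  ## --- phase 1: two demes (1 = A = destination, 2 = B = source) ---
  idx1 <- new.env(parent = emptyenv())
  info1 <- list()
  e1 <- new.env(parent = emptyenv())
  s0 <- .canonConfig(c(1L, 2L, 4L, 8L), c(1L, 1L, 2L, 2L))
  idx1[[s0$key]] <- 1L
  info1[[1]] <- s0
  queue <- list(s0)
  while (length(queue)) {
    st <- queue[[1]]
    queue <- queue[-1]
    from <- idx1[[st$key]]
    k <- length(st$masks)
    if (k == 1) next  # MRCA: absorbing
    push <- function(newM, newD, cls) {
      cn <- .canonConfig(newM, newD)
      to <- idx1[[cn$key]]
      if (is.null(to)) {
        to <- length(info1) + 1L
        idx1[[cn$key]] <- to
        info1[[to]] <<- cn
        queue[[length(queue) + 1L]] <<- cn
      }
      addEdge(e1, from, to, cls)
    }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (st$demes[i] != st$demes[j]) next
      newM <- st$masks[-j]
      newM[i] <- bitwOr(st$masks[i], st$masks[j])
      push(newM, st$demes[-j], cls = st$demes[i] - 1L)  # 0=coalA, 1=coalB
    }
    for (i in seq_len(k)) {
      if (st$demes[i] != 1L) next   # destination-deme lineages migrate out
      newD <- st$demes
      newD[i] <- 2L
      push(st$masks, newD, cls = 2L)  # 2 = migration
    }
  }
  ns1 <- length(info1)

  ## --- phase 2: single ancestral deme ---
  canonMasks <- function(masks) .canonConfig(masks, rep(1L, length(masks)))
  idx2 <- new.env(parent = emptyenv())
  info2 <- list()
  e2 <- new.env(parent = emptyenv())
  getIdx2 <- function(cn) {
    to <- idx2[[cn$key]]
    if (is.null(to)) {
      to <- length(info2) + 1L
      idx2[[cn$key]] <- to
      info2[[to]] <<- cn
    }
    to
  }
  map12 <- integer(ns1)
  queue2 <- list()
  for (g in seq_len(ns1)) {
    cn <- canonMasks(info1[[g]]$masks)
    new <- is.null(idx2[[cn$key]])
    map12[g] <- getIdx2(cn)
    if (new) queue2[[length(queue2) + 1L]] <- cn
  }
  while (length(queue2)) {
    st <- queue2[[1]]
    queue2 <- queue2[-1]
    from <- idx2[[st$key]]
    k <- length(st$masks)
    if (k == 1) next
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      newM <- st$masks[-j]
      newM[i] <- bitwOr(st$masks[i], st$masks[j])
      cn <- canonMasks(newM)
      new <- is.null(idx2[[cn$key]])
      to <- getIdx2(cn)
      if (new) queue2[[length(queue2) + 1L]] <- cn
      addEdge(e2, from, to, cls = 3L)
    }
  }
  ns2 <- length(info2)
  abs2 <- idx2[[canonMasks(15L)$key]]

  splitEdges <- function(env) {
    keys <- ls(env)
    if (!length(keys)) {
      return(list(from = integer(), to = integer(), cls = integer(),
                  mult = numeric()))
    }
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    list(from = as.integer(parts[, 1]) - 1L,
         to   = as.integer(parts[, 2]) - 1L,
         cls  = as.integer(parts[, 3]),
         mult = vapply(keys, function(k) env[[k]], numeric(1), USE.NAMES = FALSE))
  }
  ed1 <- splitEdges(e1)
  ed2 <- splitEdges(e2)

  mutMult <- function(info) {
    t(vapply(info, function(st) {
      ty <- .MASK_TYPE[st$masks]
      tabulate(ty[!is.na(ty)], nbins = 4L)
    }, integer(4)))
  }
  mut1 <- mutMult(info1)
  mut2 <- mutMult(info2)

  nlin2 <- vapply(info2, function(st) length(st$masks), integer(1))
  ord2 <- setdiff(order(nlin2, decreasing = TRUE), abs2)
  ord2 <- ord2[nlin2[ord2] > 1]

  str <- list(
    ns1 = ns1, e1from = ed1$from, e1to = ed1$to, e1cls = ed1$cls,
    e1mult = ed1$mult, mut1 = mut1, map12 = map12 - 1L,
    s0 = idx1[[s0$key]] - 1L,
    ns2 = ns2, abs2 = abs2 - 1L, e2from = ed2$from, e2to = ed2$to,
    e2mult = ed2$mult, mut2 = mut2, ord2 = ord2 - 1L
  )
  .invscanEnv$structure <- str
  str
}

#' Block configuration for bSFS tallies
#'
#' Defaults follow the standard blockwise-SFS setup: blocks of 256 callable
#' sites with a maximum genomic span of twice the site count, truncation at
#' `kmax = 2`, and sliding windows of 12,500 blocks advanced in steps of
#' 2,500 blocks.
#'
#' @param blockSites callable sites per block.
#' @param maxBlockSpan maximum genomic span of a block in bp.
#' @param kmax truncation bound on per-block mutation-type counts.
#' @param windowBlocks blocks per sliding window.
#' @param windowStep step between window starts, in blocks.
#' @return a validated list of class `"BlockConfig"`.
#' @examples
#' blockConfig(kmax = 2)
#' @export
blockConfig <- function(blockSites = 256L, maxBlockSpan = 2L * blockSites,
                        kmax = 2L, windowBlocks = 12500L,
                        windowStep = 2500L) {
  cfg <- list(blockSites = as.integer(blockSites),
              maxBlockSpan = as.integer(maxBlockSpan),
              kmax = as.integer(kmax),
              windowBlocks = as.integer(windowBlocks),
              windowStep = as.integer(windowStep))
  stopifnot(cfg$blockSites >= 1, cfg$kmax >= 1,
            cfg$maxBlockSpan >= cfg$blockSites,
            cfg$windowStep >= 1, cfg$windowStep <= cfg$windowBlocks)
  class(cfg) <- "BlockConfig"
  cfg
}

#' Construct a two-population demographic model
#'
#' @param kind `"DIV"` or `"IM"`.
#' @param NeA,NeB,NeAnc diploid effective sizes (individuals).
#' @param Tgen split time in generations.
#' @param me effective migration rate per generation (forwards in time,
#'   fraction of the destination population replaced); must be 0 for DIV.
#' @param direction forwards-time direction of gene flow, `"BtoA"` (default)
#'   or `"AtoB"`.
#' @param mu mutation rate per site per generation.
#' @param gen generation time in years.
#' @return a [DemographicModel-class] object.
#' @examples
#' demographicModel("IM", NeA = 147816, NeB = 1070603, NeAnc = 438089,
#'                  Tgen = 958812, me = 4.95e-7)
#' @export
demographicModel <- function(kind = c("IM", "DIV"), NeA, NeB, NeAnc, Tgen,
                             me = 0, direction = c("BtoA", "AtoB"),
                             mu = 2.8e-9, gen = 1) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  methods::new("DemographicModel", kind = kind, NeA = as.numeric(NeA),
               NeB = as.numeric(NeB), NeAnc = as.numeric(NeAnc),
               Tgen = as.numeric(Tgen), me = as.numeric(me),
               direction = direction, mu = as.numeric(mu),
               gen = as.numeric(gen))
}

#' Cell labels of the truncated bSFS
#'
#' Cells are ordered with the hetA level varying fastest, then hetB, hetAB
#' and fixed; levels are `0..kmax` plus the `">kmax"` marginal.
#'
#' @param kmax truncation bound.
#' @return character vector of length `(kmax + 2)^4`.
#' @export
bsfsCellLabels <- function(kmax) {
  lv <- c(as.character(0:kmax), paste0(">", kmax))
  g <- expand.grid(hetA = lv, hetB = lv, hetAB = lv, fixed = lv,
                   stringsAsFactors = FALSE)
  paste0(g$hetA, ",", g$hetB, ",", g$hetAB, ",", g$fixed)
}

#' Exact bSFS probability table under a demographic model
#'
#' Computes the probability of every truncated mutation-type tuple for a
#' block of `cfg$blockSites` callable sites under `model`, by marginalizing
#' the augmented two-phase coalescent Markov chain (see Details in the
#' package vignette).  Probabilities sum to one over the truncated space,
#' marginal (`">kmax"`) cells included.
#'
#' @param model a [DemographicModel-class].
#' @param cfg a [blockConfig()]; `blockSites` and `kmax` are used.
#' @return a [BsfsTable-class].
#' @examples
#' m <- demographicModel("DIV", 1e5, 1e5, 1e5, Tgen = 2e5)
#' tab <- bsfsTable(m, blockConfig(kmax = 2))
#' sum(cellProbs(tab))
#' @export
bsfsTable <- function(model, cfg = blockConfig()) {
  stopifnot(is(model, "DemographicModel"))
  methods::validObject(model)
  if (cfg$kmax > 4L)
    stop("kmax > 4 is intractable for the exact table")
  st <- .bsfsStructure()
  swap <- model@kind == "IM" && model@direction == "AtoB"
  NeA <- if (swap) model@NeB else model@NeA
  NeB <- if (swap) model@NeA else model@NeB
  p <- bsfs_core_cpp(
    st$ns1, st$e1from, st$e1to, st$e1cls, st$e1mult, st$mut1, st$map12,
    st$s0, st$ns2, st$abs2, st$e2from, st$e2to, st$e2mult, st$mut2, st$ord2,
    coalA = 1 / (2 * NeA), coalB = 1 / (2 * NeB),
    mig = if (model@kind == "DIV") 0 else model@me,
    coalAnc = 1 / (2 * model@NeAnc),
    mutRate = model@mu * cfg$blockSites, Tgen = model@Tgen,
    kmax = cfg$kmax)
  if (any(!is.finite(p))) stop("non-finite rates in bSFS computation")
  if (swap) {
    L <- cfg$kmax + 2L
    p <- as.vector(aperm(array(p, dim = rep(L, 4)), c(2, 1, 3, 4)))
  }
  methods::new("BsfsTable", probs = p, kmax = cfg$kmax,
               blockSites = cfg$blockSites, model = model)
}

#' Aggregate block tallies into a bSFS count vector
#'
#' Collapses per-block truncated tallies into counts over the
#' `(kmax + 2)^4` cells of the truncated bSFS, marginal-flagged counts going
#' into the `">kmax"` cells.
#'
#' @param tallies a block-tally data frame (see [tallyBlocks()] /
#'   [simulateBlockTallies()]), or a 4-column matrix of raw (untruncated)
#'   counts.
#' @param kmax truncation bound.
#' @return named integer vector of cell counts summing to the block count.
#' @export
countsVector <- function(tallies, kmax) {
  L <- kmax + 2L
  if (is.matrix(tallies)) {
    lv <- pmin(tallies, kmax + 1L)
    lA <- lv[, 1]; lB <- lv[, 2]; lAB <- lv[, 3]; lF <- lv[, 4]
  } else {
    lvl <- function(cnt, flag) ifelse(flag, kmax + 1L, cnt)
    lA <- lvl(tallies$hetA, tallies$mHetA)
    lB <- lvl(tallies$hetB, tallies$mHetB)
    lAB <- lvl(tallies$hetAB, tallies$mHetAB)
    lF <- lvl(tallies$fixed, tallies$mFixed)
  }
  idx <- 1L + lA + L * lB + L^2 * lAB + L^3 * lF
  stats::setNames(tabulate(idx, nbins = L^4), bsfsCellLabels(kmax))
}

#' Composite log-likelihood of block tallies under a bSFS table
#'
#' Blocks are treated as independent: `lnCL = sum_c n_c log P_c` over the
#' truncated cells.  If a cell with zero model probability carries observed
#' blocks the result is `-Inf`, with the offending cells attached as the
#' `"zeroCells"` attribute.
#'
#' @param x block tallies (as for [countsVector()]) or an already aggregated
#'   cell-count vector.
#' @param table a [BsfsTable-class] built at the same `kmax`.
#' @return the composite log-likelihood (scalar).
#' @export
compositeLoglik <- function(x, table) {
  stopifnot(is(table, "BsfsTable"))
  n <- if (is.numeric(x) && is.null(dim(x)) && !is.data.frame(x)) x
       else countsVector(x, table@kmax)
  if (length(n) != length(table@probs))
    stop("tally truncation does not match the table's kmax")
  p <- table@probs
  bad <- n > 0 & p <= 0
  if (any(bad)) {
    out <- -Inf
    attr(out, "zeroCells") <- bsfsCellLabels(table@kmax)[bad]
    return(out)
  }
  use <- n > 0
  sum(n[use] * log(p[use]))
}

#' Expected mutation-type counts per block under a bSFS table
#'
#' Marginal (`">kmax"`) levels contribute `kmax + 1`, a lower bound, so the
#' values are conservative floors of the true expectations.
#'
#' @param table a [BsfsTable-class].
#' @return named numeric vector (hetA, hetB, hetAB, fixed).
#' @export
expectedTypeCounts <- function(table) {
  stopifnot(is(table, "BsfsTable"))
  L <- table@kmax + 2L
  arr <- array(table@probs, dim = rep(L, 4))
  val <- c(0:table@kmax, table@kmax + 1)
  ex <- vapply(1:4, function(d) sum(apply(arr, d, sum) * val), numeric(1))
  stats::setNames(ex, c("hetA", "hetB", "hetAB", "fixed"))
}
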