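#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib invscan, .registration = TRUE
NULL

#' Genome layout: chromosomes, inversions and breakpoint buffers
#'
#' Holds the chromosome table of a genome together with the coordinates of
#' polymorphic inversions and the breakpoint buffer distance over which
#' recombination suppression is assumed to extend into the colinear
#' regions (1.5 Mb in the default, a conservative field estimate).
#'
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot inversions [GenomicRanges::GRanges] of inversion intervals.
#' @slot bufferBp single non-negative number, breakpoint buffer in bp.
#'
#' @seealso [loadGenomeLayout()], [classifyInterval()]
#' @export
setClass("GenomeLayout",
  representation(
    chromLengths = "numeric",
    inversions   = "ANY",
    bufferBp     = "numeric"
  )
)

setValidity("GenomeLayout", function(object) {
  msg <- character()
  cl <- object@chromLengths
  if (length(cl) == 0 || is.null(names(cl)) || any(!nzchar(names(cl))))
    msg <- c(msg, "chromLengths must be a named vector of chromosome lengths")
  if (any(cl <= 0)) msg <- c(msg, "chromosome lengths must be positive")
  if (anyDuplicated(names(cl))) msg <- c(msg, "duplicated chromosome names")
  if (length(object@bufferBp) != 1 || object@bufferBp < 0)
    msg <- c(msg, "bufferBp must be a single non-negative number")
  inv <- object@inversions
  if (length(inv)) {
    ic <- as.character(GenomeInfoDb::seqnames(inv))
    bad <- !(ic %in% names(cl))
    if (any(bad)) {
      msg <- c(msg, sprintf(
        "inversion %s:%d-%d lies on an unknown chromosome",
        ic[bad][1], GenomicRanges::start(inv)[bad][1],
        GenomicRanges::end(inv)[bad][1]))
    } else if (any(GenomicRanges::start(inv) < 1 |
                   GenomicRanges::end(inv) > cl[ic])) {
      i <- which(GenomicRanges::start(inv) < 1 |
                 GenomicRanges::end(inv) > cl[ic])[1]
      msg <- c(msg, sprintf(
        "inversion %s:%d-%d exceeds chromosome bounds",
        ic[i], GenomicRanges::start(inv)[i], GenomicRanges::end(inv)[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Two-population demographic model (DIV or IM)
#'
#' Parameter bundle for a population split at `Tgen` generations ago
#' (backwards in time) with optional unidirectional post-divergence gene
#' flow.  All sizes are diploid effective sizes in individuals; `me` is the
#' per-generation effective migration probability per lineage, forwards in
#' time from the source into the destination population.  `direction`
#' `"BtoA"` means forwards-time migration from population B into population
#' A (so that, backwards in time, lineages sampled in A trace back to B).
#'
#' @slot kind `"DIV"` (strict divergence, `me = 0`) or `"IM"`.
#' @slot NeA,NeB,NeAnc diploid effective sizes of population A, population B
#'   and the ancestral population.
#' @slot Tgen split time in generations.
#' @slot me effective migration rate per generation (0 for DIV).
#' @slot direction `"BtoA"` or `"AtoB"`, forwards-time source -> destination.
#' @slot mu mutation rate per site per generation.
#' @slot gen generation time in years per generation.
#'
#' @seealso [demographicModel()], [scaledMigration()]
#' @export
setClass("DemographicModel",
  representation(
    kind = "character", NeA = "numeric", NeB = "numeric", NeAnc = "numeric",
    Tgen = "numeric", me = "numeric", direction = "character",
    mu = "numeric", gen = "numeric"
  )
)

setValidity("DemographicModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("DIV", "IM")) msg <- c(msg, "kind must be DIV or IM")
  if (!object@direction %in% c("BtoA", "AtoB"))
    msg <- c(msg, "direction must be 'BtoA' or 'AtoB'")
  if (any(c(object@NeA, object@NeB, object@NeAnc) <= 0))
    msg <- c(msg, "effective sizes must be positive")
  if (object@Tgen < 0) msg <- c(msg, "Tgen must be non-negative")
  if (object@me < 0) msg <- c(msg, "me must be non-negative")
  if (object@kind == "DIV" && object@me != 0)
    msg <- c(msg, "a DIV model must have me = 0")
  if (object@mu <= 0) msg <- c(msg, "mu must be positive")
  if (object@gen <= 0) msg <- c(msg, "gen must be positive")
  if (length(msg)) msg else TRUE
})

#' Truncated blockwise site frequency spectrum under a model
#'
#' Probability distribution over truncated mutation-type tuples
#' (hetA, hetB, hetAB, fixed), each coordinate taking levels
#' `0, 1, ..., kmax, ">kmax"`, for blocks of `blockSites` callable sites
#' under a [DemographicModel-class].  Probabilities sum to one over the full
#' truncated space including the marginal cells.
#'
#' @slot probs numeric vector of cell probabilities, in the canonical cell
#'   order (hetA fastest; see [bsfsCellLabels()]).
#' @slot kmax truncation bound.
#' @slot blockSites callable sites per block.
#' @slot model the generating [DemographicModel-class].
#'
#' @seealso [bsfsTable()], [compositeLoglik()]
#' @export
setClass("BsfsTable",
  representation(
    probs = "numeric", kmax = "integer", blockSites = "integer",
    model = "DemographicModel"
  )
)

setValidity("BsfsTable", function(object) {
  if (abs(sum(object@probs) - 1) > 1e-6)
    return("cell probabilities must sum to 1")
  if (any(object@probs < -1e-12)) return("negative cell probability")
  TRUE
})

#' Result of a composite-likelihood model fit
#'
#' @slot model fitted [DemographicModel-class].
#' @slot lnCL composite log-likelihood at the optimum.
#' @slot convergence optimizer convergence code (0 = converged).
#' @slot nEval number of likelihood evaluations used.
#' @slot seed the seed the optimizer was started from.
#'
#' @seealso [optimizeModel()]
#' @export
setClass("FitResult",
  representation(
    model = "DemographicModel", lnCL = "numeric", convergence = "integer",
    nEval = "integer", seed = "integer"
  )
)

setValidity("FitResult", function(object) {
  if (!is.finite(object@lnCL)) return("lnCL must be finite")
  TRUE
})
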