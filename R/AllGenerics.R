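#' Accessors for invscan S4 objects
#'
#' Small accessor generics: chromosome lengths, inversion ranges and buffer
#' of a [GenomeLayout-class]; parameters, scaled migration rate and split
#' time of a [DemographicModel-class]; cell probabilities of a
#' [BsfsTable-class]; fitted model and log composite likelihood of a
#' [FitResult-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("inversions", function(x) standardGeneric("inversions"))
#' @rdname accessors
#' @export
setGeneric("bufferBp", function(x) standardGeneric("bufferBp"))
#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setGeneric("scaledMigration", function(x) standardGeneric("scaledMigration"))
#' @rdname accessors
#' @export
setGeneric("splitTimeYears", function(x) standardGeneric("splitTimeYears"))
#' @rdname accessors
#' @export
setGeneric("cellProbs", function(x) standardGeneric("cellProbs"))
#' @rdname accessors
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))
#' @rdname accessors
#' @export
setGeneric("lnCL", function(x) standardGeneric("lnCL"))

#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeLayout", function(x) x@chromLengths)
#' @rdname accessors
#' @export
setMethod("inversions", "GenomeLayout", function(x) x@inversions)
#' @rdname accessors
#' @export
setMethod("bufferBp", "GenomeLayout", function(x) x@bufferBp)

#' @rdname accessors
#' @export
setMethod("modelParams", "DemographicModel", function(x) {
  c(NeA = x@NeA, NeB = x@NeB, NeAnc = x@NeAnc, Tgen = x@Tgen, me = x@me)
})

#' @rdname accessors
#' @export
setMethod("scaledMigration", "DemographicModel", function(x) {
  NeDest <- if (x@direction == "BtoA") x@NeA else x@NeB
  4 * NeDest * x@me
})

#' @rdname accessors
#' @export
setMethod("splitTimeYears", "DemographicModel", function(x) x@Tgen * x@gen)

#' @rdname accessors
#' @export
setMethod("cellProbs", "BsfsTable", function(x) {
  stats::setNames(x@probs, bsfsCellLabels(x@kmax))
})

#' @rdname accessors
#' @export
setMethod("fittedModel", "FitResult", function(x) x@model)
#' @rdname accessors
#' @export
setMethod("lnCL", "FitResult", function(x) x@lnCL)
#' @rdname accessors
#' @export
setMethod("modelParams", "FitResult", function(x) modelParams(x@model))
#' @rdname accessors
#' @export
setMethod("scaledMigration", "FitResult", function(x) scaledMigration(x@model))
#' @rdname accessors
#' @export
setMethod("splitTimeYears", "FitResult", function(x) splitTimeYears(x@model))

setMethod("show", "GenomeLayout", function(object) {
  cat(sprintf("GenomeLayout: %d chromosome(s), %.1f Mb total\n",
              length(object@chromLengths), sum(object@chromLengths) / 1e6))
  cat(sprintf("  inversions: %d; breakpoint buffer: %.2f Mb\n",
              length(object@inversions), object@bufferBp / 1e6))
})

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("%s model (%s)\n", object@kind,
              if (object@kind == "IM") paste("forwards", object@direction)
              else "no post-divergence gene flow"))
  cat(sprintf("  NeA=%.4g NeB=%.4g NeAnc=%.4g  T=%.4g gen (%.4g yr)\n",
              object@NeA, object@NeB, object@NeAnc, object@Tgen,
              splitTimeYears(object)))
  cat(sprintf("  me=%.4g (M=%.4g)  mu=%.3g  g=%.3g yr/gen\n",
              object@me, scaledMigration(object), object@mu, object@gen))
})

setMethod("show", "BsfsTable", function(object) {
  cat(sprintf("bSFS table: kmax=%d, %d-site blocks, %d cells\n",
              object@kmax, object@blockSites, length(object@probs)))
  p <- cellProbs(object)
  top <- sort(p, decreasing = TRUE)[1:5]
  cat("  top cells:\n")
  for (i in seq_along(top))
    cat(sprintf("    %-14s %.5f\n", names(top)[i], top[i]))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: lnCL = %.4f (convergence %d, %d evaluations)\n",
              object@lnCL, object@convergence, object@nEval))
  show(object@model)
})
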