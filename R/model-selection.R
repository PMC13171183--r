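## Global model choice (DIV vs IM in both directions), parametric-bootstrap
## significance and confidence intervals, inverted-vs-colinear contrasts,
## and unit conversion.  Composite likelihoods invalidate chi-square
## asymptotics, so all significance statements come from the bootstrap.

#' Fit the three candidate demographic scenarios
#'
#' Fits DIV, IM with forwards-time gene flow B -> A, and IM with gene flow
#' A -> B, with shared bounds and seed, and records the better IM direction.
#'
#' @inheritParams optimizeModel
#' @return a list of class `"CandidateFits"`: `DIV`, `IM_BtoA`, `IM_AtoB`
#'   ([FitResult-class] each), `bestIM`, `bestIMdirection`.
#' @export
fitCandidateModels <- function(tallies, bounds = NULL, seed = 1,
                               cfg = blockConfig(), nStarts = 5,
                               maxit = 500, mu = 2.8e-9, gen = 1) {
  counts <- if (is.numeric(tallies) && is.null(dim(tallies)) &&
                !is.data.frame(tallies)) tallies
            else countsVector(tallies, cfg$kmax)
  div <- optimizeModel(counts, "DIV", bounds = bounds, seed = seed,
                       cfg = cfg, nStarts = nStarts, maxit = maxit,
                       mu = mu, gen = gen)
  # anchor the IM fits at the DIV optimum (me at the lower bound) so the
  # nested-model inequality holds at the optimizer level, not just in theory
  b <- if (is.null(bounds)) .defaultBounds() else bounds
  anchor <- list(c(modelParams(div)[1:4], me = b$me[1]))
  imBA <- optimizeModel(counts, "IM", "BtoA", bounds = bounds, seed = seed,
                        cfg = cfg, nStarts = nStarts, maxit = maxit,
                        mu = mu, gen = gen, extraStarts = anchor)
  imAB <- optimizeModel(counts, "IM", "AtoB", bounds = bounds, seed = seed,
                        cfg = cfg, nStarts = nStarts, maxit = maxit,
                        mu = mu, gen = gen, extraStarts = anchor)
  bestDir <- if (lnCL(imBA) >= lnCL(imAB)) "BtoA" else "AtoB"
  structure(list(DIV = div, IM_BtoA = imBA, IM_AtoB = imAB,
                 bestIM = if (bestDir == "BtoA") imBA else imAB,
                 bestIMdirection = bestDir),
            class = "CandidateFits")
}

#' @exportS3Method base::print
print.CandidateFits <- function(x, ...) {
  cat(sprintf(
    "Candidate fits: lnCL DIV %.2f | IM B->A %.2f | IM A->B %.2f (best IM: %s)\n",
    lnCL(x$DIV), lnCL(x$IM_BtoA), lnCL(x$IM_AtoB), x$bestIMdirection))
  invisible(x)
}

#' Parametric-bootstrap comparison of IM against DIV
#'
#' Simulates `nReps` replicate datasets of matched block count under the
#' fitted DIV history, refits DIV and IM (in the observed best direction) to
#' each, and compares the observed improvement
#' `deltaLnCL = lnCL(best IM) - lnCL(DIV)` with the null distribution.
#' `p = (1 + #\{null >= observed\}) / (nReps + 1)` (so the smallest
#' attainable p with 100 replicates is 1/101); the DIV model is rejected at
#' `alpha` when `p <= alpha`.
#'
#' @param fits a `"CandidateFits"` from [fitCandidateModels()].
#' @param nBlocks block count of the observed data (replicates match it).
#' @param nReps bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param alpha rejection level (default 0.05).
#' @param cfg,bounds,nStarts,maxit fitting controls for the replicates.
#' @return a list of class `"ModelComparison"`: `observedDelta`,
#'   `nullDelta`, `p.value`, `rejectDIV`, `bestIMdirection`, `nFailed`.
#' @export
bootstrapModelComparison <- function(fits, nBlocks, nReps = 100, seed,
                                     alpha = 0.05, cfg = blockConfig(),
                                     bounds = NULL, nStarts = 2,
                                     maxit = 300) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(fits, "CandidateFits"))
  observed <- lnCL(fits$bestIM) - lnCL(fits$DIV)
  divModel <- fittedModel(fits$DIV)
  dir <- fits$bestIMdirection
  nullDelta <- rep(NA_real_, nReps)
  for (r in seq_len(nReps)) {
    repSeed <- bitwXor(as.integer(seed), 7919L * r)
    tal <- simulateBlockTallies(divModel, nBlocks, cfg, seed = repSeed)
    counts <- countsVector(tal, cfg$kmax)
    d <- try({
      fd <- optimizeModel(counts, "DIV", bounds = bounds, seed = repSeed,
                          cfg = cfg, nStarts = nStarts, maxit = maxit,
                          mu = divModel@mu, gen = divModel@gen)
      fi <- optimizeModel(counts, "IM", dir, bounds = bounds,
                          seed = repSeed, cfg = cfg, nStarts = nStarts,
                          maxit = maxit, mu = divModel@mu,
                          gen = divModel@gen)
      max(lnCL(fi) - lnCL(fd), 0)
    }, silent = TRUE)
    if (!inherits(d, "try-error")) nullDelta[r] <- d
  }
  nFailed <- sum(is.na(nullDelta))
  nullDelta <- nullDelta[!is.na(nullDelta)]
  p <- (1 + sum(nullDelta >= observed)) / (length(nullDelta) + 1)
  structure(list(observedDelta = max(observed, 0), nullDelta = nullDelta,
                 p.value = p, rejectDIV = p <= alpha,
                 bestIMdirection = dir, nFailed = nFailed),
            class = "ModelComparison")
}

#' @exportS3Method base::print
print.ModelComparison <- function(x, ...) {
  cat(sprintf(
    "IM vs DIV: observed deltaLnCL = %.3f, null 95th pct = %.3f, P = %.4g -> %s\n",
    x$observedDelta, stats::quantile(x$nullDelta, 0.95),
    x$p.value, if (x$rejectDIV) "DIV rejected" else "DIV retained"))
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for fitted parameters
#'
#' Re-simulates `nReps` datasets under the fitted model at matched block
#' count, refits the same model kind/direction to each, and reports the
#' per-parameter mean and a halfwidth of twice the standard deviation
#' across replicates.
#'
#' @param fit a [FitResult-class].
#' @param nBlocks blocks per replicate dataset.
#' @param nReps bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param cfg,bounds,nStarts,maxit fitting controls for the replicates.
#' @return a list of class `"BootstrapCI"`: `estimate`, `mean`, `sd`,
#'   `halfwidth` (= 2 sd), `lower`, `upper` (estimate -/+ halfwidth),
#'   `replicates` (matrix), `nFailed`.
#' @export
bootstrapParameterCI <- function(fit, nBlocks, nReps = 100, seed,
                                 cfg = blockConfig(), bounds = NULL,
                                 nStarts = 2, maxit = 300) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(is(fit, "FitResult"))
  model <- fittedModel(fit)
  reps <- matrix(NA_real_, nReps, 7,
                 dimnames = list(NULL, c("NeA", "NeB", "NeAnc", "Tgen",
                                         "me", "M", "Tyears")))
  for (r in seq_len(nReps)) {
    repSeed <- bitwXor(as.integer(seed), 104729L * r)
    tal <- simulateBlockTallies(model, nBlocks, cfg, seed = repSeed)
    f <- try(optimizeModel(countsVector(tal, cfg$kmax), model@kind,
                           model@direction, bounds = bounds,
                           seed = repSeed, cfg = cfg, nStarts = nStarts,
                           maxit = maxit, mu = model@mu, gen = model@gen),
             silent = TRUE)
    if (!inherits(f, "try-error"))
      reps[r, ] <- c(modelParams(f), M = scaledMigration(f),
                     Tyears = splitTimeYears(f))
  }
  ok <- stats::complete.cases(reps)
  est <- c(modelParams(fit), M = scaledMigration(fit),
           Tyears = splitTimeYears(fit))
  sd <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
  sd[is.na(sd)] <- 0
  structure(list(estimate = est, mean = colMeans(reps[ok, , drop = FALSE]),
                 sd = sd, halfwidth = 2 * sd,
                 lower = est - 2 * sd, upper = est + 2 * sd,
                 replicates = reps[ok, , drop = FALSE],
                 nFailed = sum(!ok)),
            class = "BootstrapCI")
}

#' @exportS3Method base::print
print.BootstrapCI <- function(x, ...) {
  cat("Parametric bootstrap CIs (estimate +/- 2 SD):\n")
  for (p in names(x$estimate))
    cat(sprintf("  %-7s %.6g  [%.6g, %.6g]\n", p, x$estimate[p],
                x$lower[p], x$upper[p]))
  invisible(x)
}

#' Convert a coalescent-unit split time to absolute units
#'
#' `Ne = theta / (4 mu)`; `t = Tcoal * 2 * Ne * g` years.
#'
#' @param Tcoal split time in coalescent units of `2 Ne` generations.
#' @param thetaSite per-site diversity parameter.
#' @param mu mutation rate per site per generation (> 0).
#' @param gen generation time in years (default 1).
#' @return list with `Ne` (individuals) and `years`.
#' @examples
#' convertTime(5, 0.00112, 2.8e-9)   # Ne = 100,000; t = 1,000,000 years
#' @export
convertTime <- function(Tcoal, thetaSite, mu, gen = 1) {
  if (mu <= 0) stop("mu must be positive")
  stopifnot(Tcoal >= 0, thetaSite >= 0, gen > 0)
  Ne <- thetaSite / (4 * mu)
  list(Ne = Ne, years = Tcoal * 2 * Ne * gen)
}

#' Contrast inverted-region and colinear-region fits
#'
#' Reports the divergence-time difference (in years), the migration-rate
#' ratio and the scaled migration rates M of two fits of the same model
#' kind and direction, and flags "inversion predates background divergence"
#' when the T difference exceeds the combined bootstrap uncertainty (when
#' CIs are supplied).
#'
#' @param fitInv,fitCol [FitResult-class] fits for the inverted and
#'   colinear regions (same kind and direction).
#' @param ciInv,ciCol optional `"BootstrapCI"` objects for the two fits.
#' @return a list of class `"InvColContrast"`: `T_inv`, `T_col`,
#'   `deltaT_years`, `meRatio`, `M_inv`, `M_col`, `inversionPredates`.
#' @export
compareInvCol <- function(fitInv, fitCol, ciInv = NULL, ciCol = NULL) {
  mi <- fittedModel(fitInv)
  mc <- fittedModel(fitCol)
  if (mi@kind != mc@kind || (mi@kind == "IM" && mi@direction != mc@direction))
    stop("fits must share model kind and direction")
  Ti <- splitTimeYears(fitInv)
  Tc <- splitTimeYears(fitCol)
  meRatio <- if (mc@me > 0) mi@me / mc@me
             else if (mi@me == 0) 1 else Inf
  predates <- NA
  if (!is.null(ciInv) && !is.null(ciCol)) {
    predates <- (Ti - ciInv$halfwidth[["Tyears"]]) >
      (Tc + ciCol$halfwidth[["Tyears"]])
  } else if (Ti == Tc) {
    predates <- FALSE
  }
  structure(list(T_inv = Ti, T_col = Tc, deltaT_years = Ti - Tc,
                 meRatio = meRatio, M_inv = scaledMigration(fitInv),
                 M_col = scaledMigration(fitCol),
                 inversionPredates = predates),
            class = "InvColContrast")
}

#' @exportS3Method base::print
print.InvColContrast <- function(x, ...) {
  cat(sprintf(
    "INV vs COL: T %.0f vs %.0f yr (delta %.0f); me ratio %.3g; M %.3g vs %.3g\n",
    x$T_inv, x$T_col, x$deltaT_years, x$meRatio, x$M_inv, x$M_col))
  if (isTRUE(x$inversionPredates))
    cat("  inversion predates background divergence (beyond +/- 2 SD)\n")
  invisible(x)
}

#' Export a fit (or fits) as JSON
#'
#' @param x a [FitResult-class], `"CandidateFits"`, or `"BootstrapCI"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFitJson <- function(x, path) {
  asList <- function(f) {
    m <- fittedModel(f)
    list(kind = m@kind, direction = m@direction,
         params = as.list(modelParams(f)), M = scaledMigration(f),
         T_years = splitTimeYears(f), lnCL = lnCL(f),
         mu = m@mu, gen = m@gen, seed = f@seed)
  }
  out <- if (is(x, "FitResult")) asList(x)
         else if (inherits(x, "CandidateFits"))
           lapply(x[c("DIV", "IM_BtoA", "IM_AtoB")], asList)
         else unclass(x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
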