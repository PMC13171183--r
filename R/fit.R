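## Composite-likelihood optimization and grid evaluation.

.defaultBounds <- function() {
  list(Ne = c(1e3, 1e7), T = c(1e2, 1e7), me = c(1e-12, 1e-4))
}

# moment-style starting values from the aggregated cell counts
.heuristicInit <- function(counts, cfg, mu, bounds) {
  kmax <- cfg$kmax
  L <- kmax + 2L
  nb <- sum(counts)
  arr <- array(counts, dim = rep(L, 4))
  val <- c(0:kmax, kmax + 1)
  m <- vapply(1:4, function(d) sum(apply(arr, d, sum) * val), numeric(1)) / nb
  bs <- cfg$blockSites
  piA <- (m[1] + m[3]) / bs
  piB <- (m[2] + m[3]) / bs
  dxy <- (0.5 * (m[1] + m[2] + m[3]) + m[4]) / bs
  clamp <- function(x, b) pmin(pmax(x, b[1] * 1.01), b[2] * 0.99)
  NeA <- clamp(piA / (4 * mu), bounds$Ne)
  NeB <- clamp(piB / (4 * mu), bounds$Ne)
  NeAnc <- clamp((NeA + NeB) / 2, bounds$Ne)
  T0 <- clamp((dxy / mu - 4 * NeAnc) / 2, bounds$T)
  me0 <- clamp(0.25 / (4 * NeA), bounds$me)
  c(NeA = NeA, NeB = NeB, NeAnc = NeAnc, Tgen = T0, me = me0)
}

#' Maximize the composite log-likelihood over a demographic model
#'
#' Seeded multi-start Nelder-Mead on log-parameters: the first start is a
#' moment-style initialization from the observed tallies, the remaining
#' starts are log-normal perturbations of it.  Deterministic given `seed`.
#' The optimizer maximizes over (NeA, NeB, NeAnc, Tgen) for DIV and
#' additionally me for IM, inside `bounds`.
#'
#' @param tallies block tallies or an aggregated cell-count vector.
#' @param kind `"DIV"` or `"IM"`.
#' @param direction forwards-time gene-flow direction (IM only).
#' @param bounds list with elements `Ne`, `T`, `me`, each `c(lower, upper)`.
#' @param seed integer seed for the start perturbations.
#' @param cfg a [blockConfig()].
#' @param nStarts number of optimizer starts (default 5).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param mu,gen mutation rate and generation time attached to the fit.
#' @param extraStarts optional list of additional start points, each a
#'   numeric vector `(NeA, NeB, NeAnc, Tgen[, me])` in natural units (e.g.
#'   a DIV optimum with a near-zero `me`, which anchors the IM fit so the
#'   nested-model inequality holds at the optimizer level).
#' @return a [FitResult-class]; non-convergence is flagged in
#'   `@convergence`, with the best point found still returned.
#' @export
optimizeModel <- function(tallies, kind = c("IM", "DIV"),
                          direction = c("BtoA", "AtoB"), bounds = NULL,
                          seed = 1, cfg = blockConfig(), nStarts = 5,
                          maxit = 500, mu = 2.8e-9, gen = 1,
                          extraStarts = list()) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (is.null(bounds)) bounds <- .defaultBounds()
  counts <- if (is.numeric(tallies) && is.null(dim(tallies)) &&
                !is.data.frame(tallies)) tallies
            else countsVector(tallies, cfg$kmax)
  nPar <- if (kind == "IM") 5L else 4L
  lower <- log(c(rep(bounds$Ne[1], 3), bounds$T[1], bounds$me[1]))[1:nPar]
  upper <- log(c(rep(bounds$Ne[2], 3), bounds$T[2], bounds$me[2]))[1:nPar]
  nEval <- 0L
  makeModel <- function(p) {
    demographicModel(kind, NeA = p[1], NeB = p[2], NeAnc = p[3],
                     Tgen = p[4], me = if (kind == "IM") p[5] else 0,
                     direction = direction, mu = mu, gen = gen)
  }
  obj <- function(lp) {
    if (any(lp < lower) || any(lp > upper))
      return(1e12 + sum(pmax(lower - lp, 0) + pmax(lp - upper, 0)) * 1e6)
    nEval <<- nEval + 1L
    p <- exp(lp)
    -compositeLoglik(counts, bsfsTable(makeModel(p), cfg))
  }
  init <- .heuristicInit(counts, cfg, mu, bounds)[1:nPar]
  starts <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nStarts), function(i) {
      if (i == 1) log(init)
      else pmin(pmax(log(init) + stats::rnorm(nPar, 0, 0.5), lower), upper)
    })
  })
  starts <- c(starts, lapply(extraStarts, function(s)
    pmin(pmax(log(s[1:nPar]), lower), upper)))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  methods::new("FitResult", model = makeModel(exp(best$par)),
               lnCL = -best$value, convergence = as.integer(best$convergence),
               nEval = nEval, seed = as.integer(seed))
}

#' Parameter grid for window scans
#'
#' @param NeA,NeB,NeAnc,me numeric value sequences (defaults are the study's
#'   grid dimensions: 12 x 12 x 12 x 16).
#' @param Toptions admissible split times (generations); the scan maximizes
#'   over them jointly with the Ne values.
#' @return a list of class `"GridSpec"`.
#' @seealso [gridAround()], [evaluateGrid()], [scanWindows()]
#' @export
gridSpec <- function(NeA, NeB, NeAnc, me, Toptions) {
  g <- list(NeA = as.numeric(NeA), NeB = as.numeric(NeB),
            NeAnc = as.numeric(NeAnc), me = as.numeric(unique(me)),
            Toptions = as.numeric(Toptions))
  stopifnot(all(lengths(g) >= 1), all(g$NeA > 0), all(g$NeB > 0),
            all(g$NeAnc > 0), all(g$me >= 0), all(g$Toptions >= 0))
  class(g) <- "GridSpec"
  g
}

#' Logarithmic grid centred on a background model
#'
#' Ne sequences are log-spaced over `span`-fold ranges around the background
#' values; the migration sequence is an exact 0 followed by log-spaced
#' values bracketing the background rate, with the background value itself
#' substituted for the nearest grid value so it is always on the grid.
#'
#' @param model background [DemographicModel-class].
#' @param n grid dimensions `c(NeA, NeB, NeAnc, me)` (default
#'   `c(12, 12, 12, 16)`).
#' @param span fold-range of each Ne sequence (default 16: values span
#'   background/4 to background*4).
#' @param Toptions admissible split times; default the model's `Tgen`.
#' @return a `"GridSpec"`.
#' @export
gridAround <- function(model, n = c(12, 12, 12, 16), span = 16,
                       Toptions = model@Tgen) {
  lsp <- function(center, k) {
    exp(seq(log(center / sqrt(span)), log(center * sqrt(span)),
            length.out = k))
  }
  meBg <- model@me
  nme <- n[4]
  if (meBg > 0) {
    mes <- lsp(meBg, nme - 1L)
    mes[which.min(abs(log(mes) - log(meBg)))] <- meBg
    mes <- c(0, mes)
  } else {
    mes <- c(0, lsp(1e-7, nme - 1L))
  }
  gridSpec(lsp(model@NeA, n[1]), lsp(model@NeB, n[2]),
           lsp(model@NeAnc, n[3]), mes, Toptions)
}

#' Evaluate the composite log-likelihood on a full parameter grid
#'
#' Computes `lnCL` for every `(NeA, NeB, NeAnc, me)` combination at a fixed
#' split time.  bSFS tables are cached per unique parameter combination in
#' `cache`, so repeated calls (e.g. across windows) reuse them.
#'
#' @param tallies block tallies or aggregated cell counts.
#' @param grid a `"GridSpec"`.
#' @param Tfixed split time in generations.
#' @param direction forwards-time gene-flow direction for `me > 0` points.
#' @param cfg a [blockConfig()].
#' @param mu mutation rate.
#' @param cache an environment for table caching (optional).
#' @return data frame with the grid coordinates and `lnCL`, one row per
#'   grid point.
#' @export
evaluateGrid <- function(tallies, grid, Tfixed, direction = "BtoA",
                         cfg = blockConfig(), mu = 2.8e-9, cache = NULL) {
  stopifnot(inherits(grid, "GridSpec"))
  counts <- if (is.numeric(tallies) && is.null(dim(tallies)) &&
                !is.data.frame(tallies)) tallies
            else countsVector(tallies, cfg$kmax)
  pts <- expand.grid(NeA = grid$NeA, NeB = grid$NeB, NeAnc = grid$NeAnc,
                     me = grid$me, KEEP.OUT.ATTRS = FALSE)
  logP <- .gridLogP(pts, Tfixed, direction, cfg, mu, cache)
  pts$lnCL <- as.vector(counts %*% logP)
  pts$Tgen <- Tfixed
  pts
}

# log-probability matrix (cells x grid points), cached per parameter key
.gridLogP <- function(pts, Tfixed, direction, cfg, mu, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  C <- (cfg$kmax + 2L)^4
  logP <- matrix(NA_real_, C, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    key <- paste(pts$NeA[i], pts$NeB[i], pts$NeAnc[i], pts$me[i], Tfixed,
                 direction, sep = "|")
    p <- cache[[key]]
    if (is.null(p)) {
      m <- demographicModel(if (pts$me[i] > 0) "IM" else "DIV",
                            NeA = pts$NeA[i], NeB = pts$NeB[i],
                            NeAnc = pts$NeAnc[i], Tgen = Tfixed,
                            me = pts$me[i], direction = direction, mu = mu)
      p <- log(pmax(bsfsTable(m, cfg)@probs, 1e-300))
      cache[[key]] <- p
    }
    logP[, i] <- p
  }
  logP
}
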