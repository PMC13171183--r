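# The exact bSFS probability engine and the composite likelihood.

cfg <- blockConfig()

test_that("tables normalize to 1 within 1e-8 across random parameter draws", {
  set.seed(99)
  for (i in 1:100) {
    kind <- sample(c("DIV", "IM"), 1)
    m <- demographicModel(kind,
                          NeA = runif(1, 2e4, 2e6),
                          NeB = runif(1, 2e4, 2e6),
                          NeAnc = runif(1, 2e4, 2e6),
                          Tgen = runif(1, 0, 3e6),
                          me = if (kind == "IM") 10^runif(1, -9, -6) else 0,
                          direction = sample(c("BtoA", "AtoB"), 1))
    p <- bsfsTable(m, cfg)@probs
    expect_lt(abs(sum(p) - 1), 1e-8)
    expect_true(all(p >= -1e-12))
  }
})

test_that("the no-mutation limit concentrates all mass on (0,0,0,0)", {
  m <- demographicModel("DIV", 1e5, 2e5, 1.5e5, Tgen = 5e5, mu = 1e-16)
  p <- cellProbs(bsfsTable(m, cfg))
  expect_gt(p[["0,0,0,0"]], 1 - 1e-6)
})

test_that("swapping population labels permutes hetA and hetB (DIV)", {
  L <- cfg$kmax + 2L
  a <- bsfsTable(demographicModel("DIV", 1e5, 4e5, 2e5, Tgen = 3e5), cfg)
  b <- bsfsTable(demographicModel("DIV", 4e5, 1e5, 2e5, Tgen = 3e5), cfg)
  pa <- array(a@probs, dim = rep(L, 4))
  pb <- array(b@probs, dim = rep(L, 4))
  expect_equal(as.vector(aperm(pa, c(2, 1, 3, 4))), as.vector(pb),
               tolerance = 1e-12)
})

test_that("IM direction maps onto the mirrored parameterization", {
  L <- cfg$kmax + 2L
  ba <- bsfsTable(demographicModel("IM", 1e5, 5e5, 2e5, Tgen = 4e5,
                                   me = 3e-7, direction = "BtoA"), cfg)
  ab <- bsfsTable(demographicModel("IM", 5e5, 1e5, 2e5, Tgen = 4e5,
                                   me = 3e-7, direction = "AtoB"), cfg)
  pa <- array(ba@probs, dim = rep(L, 4))
  pb <- array(ab@probs, dim = rep(L, 4))
  expect_equal(as.vector(aperm(pa, c(2, 1, 3, 4))), as.vector(pb),
               tolerance = 1e-12)
})

test_that("expected fixed differences increase weakly with split time", {
  Ts <- c(1e5, 3e5, 6e5, 1e6, 2e6)
  ef <- vapply(Ts, function(Tg)
    expectedTypeCounts(bsfsTable(fastDivModel(Tgen = Tg), cfg))[["fixed"]],
    numeric(1))
  expect_true(all(diff(ef) > -1e-12))
})

test_that("the exact table matches the Monte Carlo oracle per cell and in TV", {
  models <- list(
    fastDivModel(Tgen = 5e5),
    demographicModel("DIV", 4e5, 4e5, 4e5, Tgen = 1.5e6),
    demographicModel("DIV", 5e4, 8e5, 2e5, Tgen = 2e5),
    backgroundModel(),
    inversionModel(),
    demographicModel("IM", 2e5, 2e5, 2e5, Tgen = 1e6, me = 2e-6,
                     direction = "AtoB"))
  n <- 1e6
  for (i in seq_along(models)) {
    p <- bsfsTable(models[[i]], cfg)@probs
    f <- mcBsfsOracle(models[[i]], cfg, nReps = n, seed = 4000 + i)
    tv <- 0.5 * sum(abs(p - f))
    expect_lt(tv, 0.01)
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(f - p) <= 3 * pmax(se, 1e-6)))
  }
})

test_that("composite log-likelihood is the count-weighted log-probability", {
  tab <- bsfsTable(fastDivModel(), cfg)
  counts <- integer(length(tab@probs))
  cell <- which.min(abs(tab@probs - 0.25))
  counts[cell] <- 1L
  expect_equal(compositeLoglik(counts, tab), log(tab@probs[cell]))
  # linearity: doubling every tally doubles lnCL
  set.seed(1)
  counts <- as.integer(rmultinom(1, 500, tab@probs))
  expect_equal(compositeLoglik(counts * 2L, tab),
               2 * compositeLoglik(counts, tab))
  # observed mass on a zero-probability cell reports -Inf with diagnostics
  probs <- tab@probs
  zero <- which.min(probs)
  probs[1] <- probs[1] + probs[zero]
  probs[zero] <- 0
  tab0 <- methods::new("BsfsTable", probs = probs, kmax = cfg$kmax,
                       blockSites = cfg$blockSites, model = tab@model)
  counts0 <- integer(length(probs))
  counts0[zero] <- 3L
  ll <- compositeLoglik(counts0, tab0)
  expect_identical(unclass(ll)[1], -Inf)
  expect_length(attr(ll, "zeroCells"), 1)
})

test_that("a 1-D profile over split time peaks near the generating value", {
  truth <- fastDivModel(Tgen = 5e5)
  counts <- countsVector(simulateBlockTallies(truth, 3e4, cfg, seed = 77),
                         cfg$kmax)
  Ts <- exp(seq(log(1e5), log(2.5e6), length.out = 17))
  prof <- vapply(Ts, function(Tg)
    compositeLoglik(counts, bsfsTable(fastDivModel(Tgen = Tg), cfg)),
    numeric(1))
  best <- Ts[which.max(prof)]
  expect_gt(best, 5e5 / 1.5)
  expect_lt(best, 5e5 * 1.5)
})

test_that("grid evaluation enumerates the grid and is maximized at idealized truth", {
  grid <- gridSpec(NeA = c(8e4, 1.2e5), NeB = c(1.5e5, 2.5e5),
                   NeAnc = c(1e5, 2e5), me = c(0, 3e-7),
                   Toptions = 5e5)
  truthRow <- 7   # an arbitrary grid point
  pts <- expand.grid(NeA = grid$NeA, NeB = grid$NeB, NeAnc = grid$NeAnc,
                     me = grid$me, KEEP.OUT.ATTRS = FALSE)
  m <- demographicModel(if (pts$me[truthRow] > 0) "IM" else "DIV",
                        NeA = pts$NeA[truthRow], NeB = pts$NeB[truthRow],
                        NeAnc = pts$NeAnc[truthRow], Tgen = 5e5,
                        me = pts$me[truthRow])
  ideal <- bsfsTable(m, cfg)@probs * 1e6   # idealized tallies N * P
  res <- evaluateGrid(ideal, grid, Tfixed = 5e5, cfg = cfg)
  expect_equal(nrow(res), 16)   # 2 x 2 x 2 x 2
  expect_equal(which.max(res$lnCL), truthRow)   # Gibbs' inequality
})

test_that("grid caching returns identical values to uncached evaluation", {
  grid <- gridSpec(NeA = c(1e5, 2e5), NeB = 2e5, NeAnc = 1.5e5,
                   me = c(0, 2e-7), Toptions = 4e5)
  counts <- countsVector(
    simulateBlockTallies(backgroundModel(), 2000, cfg, seed = 5), cfg$kmax)
  cacheEnv <- new.env()
  r1 <- evaluateGrid(counts, grid, 4e5, cfg = cfg, cache = cacheEnv)
  r2 <- evaluateGrid(counts, grid, 4e5, cfg = cfg, cache = cacheEnv)
  r3 <- evaluateGrid(counts, grid, 4e5, cfg = cfg)
  expect_identical(r1$lnCL, r2$lnCL)
  expect_identical(r1$lnCL, r3$lnCL)
})
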