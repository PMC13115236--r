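test_that("basis conversion matches closed forms and round-trips", {
  expect_equal(convertBasis(45, "wet", "dry"), 100 * 45 / 55)
  expect_equal(convertBasis(12, "wet", "dry"), 100 * 12 / 88)
  expect_equal(convertBasis(convertBasis(50, "dry", "wet"), "wet", "dry"), 50)
  expect_equal(convertBasis(50, "dry", "dry"), 50)
  expect_error(convertBasis(100, "wet", "dry"), "< 100")
  expect_error(convertBasis(-2, "dry", "wet"), "positive")
})

test_that("drying rate is the per-interval difference quotient", {
  cu <- DryingCurve(30, c(0, 2, 4), c(40, 30, 25), basis = "dry")
  dr <- dryingRate(cu)
  expect_equal(dr$rate, c(-5, -2.5))
  expect_equal(dr$moisture_mid, c(35, 27.5))
  flat <- DryingCurve(30, 0:3, rep(20, 4), basis = "dry")
  expect_true(all(dryingRate(flat)$rate == 0))
  expect_error(dryingRate(DryingCurve(30, 0, 40, "dry")), "2 points")
})

test_that("finite-difference rate approaches the analytic derivative", {
  ## M(t) = 12 + 68 exp(-k t): central difference at the interval
  ## midpoint has O(dt^2) error
  k <- 0.1
  for (dt in c(1, 0.5)) {
    t <- seq(0, 20, by = dt)
    cu <- DryingCurve(40, t, 12 + 68 * exp(-k * t), basis = "dry")
    dr <- dryingRate(cu)
    tm <- (t[-1] + t[-length(t)]) / 2
    analytic <- -k * 68 * exp(-k * tm)
    expect_lt(max(abs(dr$rate - analytic)), 68 * k^3 * dt^2 / 8)
  }
})

test_that("critical moisture recovers planted rate breakpoints", {
  meq <- 12
  makeCurve <- function(bp, dt = 0.5) {
    m <- 40; M <- m
    while (m > meq + 1) {
      r <- if (m > bp) -2 else -2 * (m - meq) / (bp - meq)
      m <- m + dt * r
      M <- c(M, m)
    }
    DryingCurve(30, seq_along(M) * dt - dt, M, basis = "dry")
  }
  for (bp in c(22.97, 23.83, 23)) {
    res <- criticalMoisture(makeCurve(bp))
    expect_true(res$detected)
    expect_lt(abs(res$critical - bp), 1.5)  # within a sampling interval
  }
  ## single-slope rate curve: no transition
  t <- seq(0, 30, by = 1)
  single <- DryingCurve(30, t, 12 + 68 * exp(-0.1 * t), basis = "dry")
  expect_false(criticalMoisture(single)$detected)
  expect_true(is.na(criticalMoisture(single)$critical))
  expect_error(criticalMoisture(DryingCurve(30, 0:2, c(40, 30, 25), "dry")),
               "4 points")
})

test_that("equilibrium moisture is the series minimum with plateau entry", {
  cu <- DryingCurve(30, 0:4, c(40, 20, 13, 12, 12), basis = "dry")
  eq <- equilibriumMoisture(cu)
  expect_equal(eq$meq, 12)
  expect_equal(eq$plateauIndex, 4L)     # first time the minimum is reached
  expect_equal(eq$plateauTime, 3)
  dec <- DryingCurve(30, 0:3, c(40, 30, 20, 15), basis = "dry")
  expect_equal(equilibriumMoisture(dec)$meq, 15)
  ## noisy synthetic plateau: minimum within 3 sigma of the truth
  g <- simDryingCurve(durationH = 300, noiseSD = 0.1, nTerms = 50L,
                      seed = 11)
  expect_lt(abs(equilibriumMoisture(g$curve)$meq - g$truth$meq), 0.3)
})

test_that("moisture ratio linearizes and drops sub-equilibrium points", {
  cu <- DryingCurve(30, c(0, 5), c(80, 46), basis = "dry")
  mr <- moistureRatio(cu, meq = 12)
  expect_equal(mr@logRatio[1], 0)
  expect_equal(mr@logRatio[2], log(0.5), tolerance = 1e-12)
  expect_equal(mr@timesS, c(0, 5) * 3600)
  cu2 <- DryingCurve(30, c(0, 5, 10), c(80, 46, 12), basis = "dry")
  expect_warning(mr2 <- moistureRatio(cu2, meq = 12), "dropped 1")
  expect_equal(length(mr2@logRatio), 2L)
  expect_error(moistureRatio(cu, meq = 90), "m0 must exceed meq")
  ## wet-basis input is converted before the ratio
  wet <- DryingCurve(30, c(0, 5), c(44.44444444444444, 31.50684931506849),
                     basis = "wet")
  mrw <- moistureRatio(wet, meq = 12)
  expect_equal(mrw@m0, 80, tolerance = 1e-9)
})

test_that("linearized fit recovers exact lines and matches a grid oracle", {
  a <- -1.46982169e-5; b <- -0.59745164
  t <- seq(0, 52, by = 2) * 3600
  series <- new("MoistureRatioSeries", timesS = t, logRatio = a * t + b,
                m0 = 80, meq = 12, nDropped = 0L)
  fit <- linearizedFit(series)
  expect_equal(fit@slope, a, tolerance = 1e-12)
  expect_equal(fit@intercept, b, tolerance = 1e-12)
  expect_equal(fit@mse, 0, tolerance = 1e-20)
  ## 5-point toy vs exhaustive grid minimization
  x <- c(0, 1, 2, 3, 4); y <- c(0.1, -0.8, -2.2, -2.9, -4.1)
  toy <- new("MoistureRatioSeries", timesS = x, logRatio = y,
             m0 = 80, meq = 12, nDropped = 0L)
  ft <- linearizedFit(toy)
  g <- gridOLS(x, y, ft@slope + c(-0.1, 0.1), ft@intercept + c(-0.1, 0.1))
  expect_lt(abs(ft@slope - g$slope), g$stepA)
  expect_lt(abs(ft@intercept - g$intercept), g$stepB)
  expect_lte(sum((ft@slope * x + ft@intercept - y)^2), g$sse + 1e-12)
})

test_that("intercept shape function matches printed pairs and is monotone", {
  expect_equal(shapeIntercept(2.256442), -0.59745164, tolerance = 1e-6)
  expect_equal(shapeIntercept(2.058683), -0.44401679, tolerance = 1e-5)
  expect_lt(abs(shapeIntercept(1e-3)), 1e-5)           # b -> 0 as mu -> 0
  grid <- seq(0.01, pi - 0.01, length.out = 1000)
  expect_true(all(diff(shapeIntercept(grid)) < 0))     # strictly decreasing
  expect_error(shapeIntercept(3.5), "0, pi")
})

test_that("eigenvalue solver inverts the intercept shape function", {
  expect_equal(solveMuFromIntercept(-0.59745164), 2.256442,
               tolerance = 1e-6)
  expect_equal(solveMuFromIntercept(-0.67151457), 2.333156,
               tolerance = 1e-6)
  for (b in seq(-3, -0.1, by = 0.29))
    expect_equal(shapeIntercept(solveMuFromIntercept(b)), b,
                 tolerance = 1e-10)
  expect_error(solveMuFromIntercept(0.2), "negative")
})

test_that("Biot follows from the eigenvalue and is strictly increasing", {
  expect_equal(biotFromMu(2.256442), 2.845864, tolerance = 1e-6)
  expect_equal(biotFromMu(pi / 2), 1, tolerance = 1e-12)
  expect_equal(biotFromMu(1e-3), 1e-6 / 3, tolerance = 1e-3)  # mu^2/3 limit
  grid <- seq(0.01, pi - 0.01, length.out = 1000)
  expect_true(all(diff(biotFromMu(grid)) > 0))
  expect_error(biotFromMu(pi), "0, pi")
})

test_that("eigenvalue sets are bracketed per branch and hit the limits", {
  for (biot in c(0.5, 2.0925, 2.8459, 10)) {
    mu <- eigenRoots(rootsForBiot(biot, 6))
    n <- seq_along(mu)
    expect_true(all(mu > (n - 1) * pi & mu < n * pi))
    expect_true(all(diff(mu) > 0))
    ## residual of the defining equation at each root
    expect_lt(max(abs(1 - mu / tan(mu) - biot)), 1e-8)
  }
  ## spacing approaches pi for large n
  mu <- eigenRoots(rootsForBiot(2.8459, 12))
  expect_lt(abs(diff(mu)[11] - pi), 0.02)
  ## infinite-Biot (Dirichlet) limit: first root -> pi
  expect_lt(abs(eigenRoots(rootsForBiot(1e8, 1)) - pi), 1e-3)
})

test_that("diffusivity and mass-transfer coefficient follow the closed forms", {
  expect_equal(dEffFromSlope(-1.46982169e-5, 2.2564421, RADIUS_L),
               1.46982169e-5 * RADIUS_L^2 / 2.2564421^2, tolerance = 1e-12)
  expect_equal(dEffFromSlope(-3e-5, 2, 2 * RADIUS_L) /
                 dEffFromSlope(-3e-5, 2, RADIUS_L), 4)  # L^2 scaling
  expect_error(dEffFromSlope(1e-5, 2, RADIUS_L), "negative")
  expect_equal(hmFromBiot(1, RADIUS_L, RADIUS_L), 1)
  expect_equal(hmFromBiot(2.845864, 4.538592e-13, RADIUS_L),
               2.845864 * 4.538592e-13 / RADIUS_L)
})

test_that("transport chain satisfies its internal consistency invariants", {
  cf <- tableCoefficients()
  for (i in seq_len(nrow(cf))) {
    tp <- transportFromCoefficients(cf$slope_per_s[i], cf$intercept[i],
                                    RADIUS_L, cf$temperature_C[i])
    mu <- firstEigenvalue(tp)
    expect_lt(abs(1 - mu / tan(mu) - biotNumber(tp)), 1e-9)
    expect_equal(massTransferCoef(tp) * RADIUS_L,
                 biotNumber(tp) * effectiveDiffusivity(tp))
  }
})

test_that("noise-free first-term curves are inverted essentially exactly", {
  g <- simDryingCurve(dEff = 5e-13, biot = 3, radiusL = RADIUS_L,
                      durationH = 52)
  est <- estimateTransport(g$curve, meq = g$truth$meq, radiusL = RADIUS_L,
                           m0 = g$truth$m0)
  expect_lt(abs(effectiveDiffusivity(est) / g$truth$dEff - 1), 0.01)
  expect_lt(abs(biotNumber(est) / g$truth$biot - 1), 0.01)
  ## round trip through each printed coefficient pair: regenerating a
  ## curve from the estimated transport parameters and re-estimating
  ## reproduces them to 5 significant figures
  cf <- tableCoefficients()
  for (i in seq_len(nrow(cf))) {
    tp <- transportFromCoefficients(cf$slope_per_s[i], cf$intercept[i],
                                    RADIUS_L, cf$temperature_C[i])
    g2 <- simDryingCurve(dEff = effectiveDiffusivity(tp),
                         biot = biotNumber(tp), radiusL = RADIUS_L,
                         durationH = 52)
    est2 <- estimateTransport(g2$curve, meq = g2$truth$meq,
                              radiusL = RADIUS_L, m0 = g2$truth$m0)
    expect_equal(firstEigenvalue(est2), firstEigenvalue(tp),
                 tolerance = 1e-5)
    expect_equal(effectiveDiffusivity(est2), effectiveDiffusivity(tp),
                 tolerance = 1e-5)
    expect_equal(massTransferCoef(est2), massTransferCoef(tp),
                 tolerance = 1e-5)
  }
})

test_that("noisy curves are inverted within Monte-Carlo tolerance", {
  ok <- vapply(1:100, function(s) {
    g <- simDryingCurve(noiseSD = 0.2, seed = s, durationH = 52)
    est <- estimateTransport(g$curve, meq = g$truth$meq,
                             radiusL = RADIUS_L, m0 = g$truth$m0)
    abs(effectiveDiffusivity(est) / g$truth$dEff - 1) < 0.15 &&
      abs(biotNumber(est) / g$truth$biot - 1) < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("series solution honors first-term dominance and the surface IC", {
  ## large Fourier number: one term suffices
  for (fo in c(2, 3, 5))
    expect_equal(seriesPhi(1, fo, 2.8459, 1) / seriesPhi(1, fo, 2.8459, 50),
                 1, tolerance = 1e-6)
  ## Fo = 0 at the surface: partial sums creep toward 1
  errs <- sapply(c(10, 50, 200), function(k)
    abs(seriesPhi(1, 0, 2.8459, k) - 1))
  expect_true(all(diff(errs) < 0))
  ## interior point x/L = 0 uses the sin(z)/z limit without blowing up
  expect_true(is.finite(seriesPhi(0, 0.5, 2.8459, 10)))
})

test_that("multi-term oracle curves are inverted within 2% when fit at Fo > 0.2", {
  g <- simDryingCurve(nTerms = 50L, durationH = 52)
  est <- estimateTransport(g$curve, meq = g$truth$meq, radiusL = RADIUS_L,
                           m0 = g$truth$m0, minFourier = 0.2)
  expect_lt(abs(effectiveDiffusivity(est) / g$truth$dEff - 1), 0.02)
})
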