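## Moisture-transport estimation from thin-layer drying curves via the
## first-term analytical solution of Fickian diffusion in a sphere with
## a convective (Robin) surface condition.

#' Convert moisture content between wet and dry basis
#'
#' Wet basis expresses water per total mass, dry basis per dry-solid
#' mass: d = 100 w / (100 - w) and w = 100 d / (100 + d).
#'
#' @param moisture moisture content (%), vectorized.
#' @param from,to `"wet"` or `"dry"`.
#' @return Moisture content (%) on the `to` basis.
#' @examples
#' convertBasis(45, "wet", "dry")   # 81.82
#' convertBasis(12, "wet", "dry")   # 13.64
#' @export
convertBasis <- function(moisture, from = c("wet", "dry"),
                         to = c("dry", "wet")) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == "wet" && any(moisture >= 100))
    stop("wet-basis moisture must be < 100%")
  if (any(moisture <= 0))
    stop("moisture must be positive")
  if (from == to) return(moisture)
  if (from == "wet") 100 * moisture / (100 - moisture)
  else               100 * moisture / (100 + moisture)
}

#' Drying rate between consecutive measurements
#'
#' The rate over each interval is the change in moisture divided by the
#' time step, paired with the midpoint moisture, the series from which
#' the constant-rate/falling-rate transition is read.
#'
#' @param curve a [DryingCurve-class].
#' @return A data.frame with columns `moisture_mid` and `rate` (%/h),
#'   one row per interval.
#' @export
dryingRate <- function(curve) {
  stopifnot(is(curve, "DryingCurve"))
  t <- dryingTimes(curve); m <- moisture(curve)
  if (length(t) < 2) stop("at least 2 points required")
  if (any(diff(t) == 0)) stop("duplicate times")
  data.frame(moisture_mid = (m[-1] + m[-length(m)]) / 2,
             rate = diff(m) / diff(t))
}

#' Critical moisture content
#'
#' Locates the transition between the constant-rate and the falling-rate
#' drying period on the rate-vs-moisture series by exhaustive
#' two-segment piecewise-linear least squares: every interior partition
#' of the (moisture, rate) points into two contiguous segments (each
#' with at least two points) is fitted, and the partition minimizing
#' the total SSE defines the breakpoint. A guard requires the
#' two-segment fit to reduce the single-line SSE by at least
#' `fGuard`; otherwise no transition is reported.
#'
#' @param curve a [DryingCurve-class] with at least 4 points.
#' @param fGuard minimum SSE reduction factor of the segmented over the
#'   single-line fit (default 2).
#' @return A list with `critical` (moisture % at the breakpoint, the
#'   midpoint of the adjoining segment boundary moistures, or `NA` when
#'   no transition is detected), `sse`, `sseSingle` and `detected`.
#' @export
criticalMoisture <- function(curve, fGuard = 2) {
  rates <- dryingRate(curve)
  n <- nrow(rates)
  if (n < 4) stop("at least 4 points (3 rate intervals) required; got fewer")
  ## order along moisture so segments are contiguous in moisture
  o <- order(rates$moisture_mid)
  x <- rates$moisture_mid[o]; y <- rates$rate[o]
  sseLine <- function(idx) {
    if (length(idx) < 2) return(Inf)
    fit <- stats::lm.fit(cbind(1, x[idx]), y[idx])
    sum(fit$residuals^2)
  }
  sseSingle <- sseLine(seq_len(n))
  best <- list(sse = Inf, k = NA_integer_)
  for (k in 2:(n - 2)) {              # k = last index of lower segment
    s <- sseLine(seq_len(k)) + sseLine((k + 1):n)
    if (s < best$sse) best <- list(sse = s, k = k)
  }
  detected <- is.finite(best$sse) &&
    (best$sse == 0 && sseSingle > 0 || sseSingle / max(best$sse, 1e-300) >= fGuard)
  crit <- if (detected) (x[best$k] + x[best$k + 1]) / 2 else NA_real_
  list(critical = crit, sse = best$sse, sseSingle = sseSingle,
       detected = detected)
}

#' Equilibrium moisture content
#'
#' The lowest moisture value reached after prolonged drying, together
#' with the time at which the series first enters the terminal plateau
#' (first point within `tol` % moisture of the minimum).
#'
#' @param curve a [DryingCurve-class].
#' @param tol absolute plateau tolerance (% moisture, default 0.1).
#' @return List with `meq`, `plateauTime` (h) and `plateauIndex`.
#' @export
equilibriumMoisture <- function(curve, tol = 0.1) {
  stopifnot(is(curve, "DryingCurve"))
  m <- moisture(curve)
  if (length(m) == 0) stop("empty curve")
  meq <- min(m)
  i <- which(m <= meq + tol)[1]
  list(meq = meq, plateauTime = dryingTimes(curve)[i], plateauIndex = i)
}

#' Log moisture-ratio series
#'
#' Computes ln((M - Meq)/(M0 - Meq)) with times converted from hours to
#' seconds, the linearization of the first-term sphere solution. Wet
#' basis curves are converted to dry basis first. Points with
#' M <= Meq (measurement noise can cross the equilibrium value) are
#' dropped with a warning reporting the count.
#'
#' @param curve a [DryingCurve-class].
#' @param meq equilibrium moisture (dry basis, %).
#' @param m0 initial moisture (dry basis, %). Defaults to the moisture
#'   at t = 0 when the curve starts at zero, otherwise required: a
#'   first-term curve sampled only at positive times does not contain
#'   its own initial condition.
#' @return A [MoistureRatioSeries-class].
#' @export
moistureRatio <- function(curve, meq, m0 = NULL) {
  stopifnot(is(curve, "DryingCurve"))
  m <- moisture(curve)
  if (moistureBasis(curve) == "wet") m <- convertBasis(m, "wet", "dry")
  t <- dryingTimes(curve)
  if (is.null(m0)) {
    if (t[1] != 0)
      stop("curve does not start at t = 0; supply m0 explicitly")
    m0 <- m[1]
  }
  if (m0 <= meq) stop("m0 must exceed meq")
  keep <- m > meq
  if (any(!keep))
    warning(sprintf("dropped %d point(s) with moisture <= meq", sum(!keep)))
  new("MoistureRatioSeries",
      timesS = t[keep] * 3600,
      logRatio = log((m[keep] - meq) / (m0 - meq)),
      m0 = m0, meq = meq, nDropped = sum(!keep))
}

#' Ordinary least-squares fit of the linearized drying line
#'
#' Regresses the log moisture ratio on time in seconds. The slope is
#' a = -mu^2 D / L^2 (1/s) and the intercept approximates the log of
#' the surface shape factor of the first eigenfunction.
#'
#' @param series a [MoistureRatioSeries-class] with at least 3 points.
#' @return A [KineticFit-class].
#' @export
linearizedFit <- function(series) {
  stopifnot(is(series, "MoistureRatioSeries"))
  t <- series@timesS; y <- series@logRatio
  if (length(t) < 3) stop("at least 3 points required")
  if (stats::var(t) == 0) stop("degenerate series: all times equal")
  fit <- stats::lm.fit(cbind(1, t), y)
  new("KineticFit", slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      mse = mean(fit$residuals^2), n = length(t))
}

#' Surface shape factor of the first sphere eigenfunction (log scale)
#'
#' b(mu) = ln( 2 sin(mu) (sin(mu) - mu cos(mu)) /
#'             (mu (mu - sin(mu) cos(mu))) ), the intercept of the
#' linearized drying line evaluated at the sphere surface (x/L = 1).
#' Strictly decreasing on (0, pi) with b -> 0 as mu -> 0+.
#'
#' @param mu first eigenvalue, in (0, pi).
#' @return Intercept b (<= 0), vectorized over `mu`.
#' @export
shapeIntercept <- function(mu) {
  if (any(mu <= 0 | mu >= pi)) stop("mu must lie in (0, pi)")
  log(2 * sin(mu) * (sin(mu) - mu * cos(mu)) /
        (mu * (mu - sin(mu) * cos(mu))))
}

## generic bisection: f must change sign on (lo, hi)
.bisect <- function(f, lo, hi, tol = 1e-12, maxIter = 60L) {
  flo <- f(lo)
  if (flo * f(hi) > 0) stop("root not bracketed")
  for (i in seq_len(maxIter)) {
    if ((hi - lo) < tol) break
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' Solve the first eigenvalue from the drying-line intercept
#'
#' Inverts [shapeIntercept()] by bisection: the unique root of
#' b(mu) = b on (0, pi). The interval is halved until its width falls
#' below `tol` (about 50 iterations from the full interval).
#'
#' @param b fitted intercept, must be negative.
#' @param tol bisection interval-width tolerance (default 1e-12).
#' @param maxIter iteration cap (default 60).
#' @return First eigenvalue mu.
#' @examples
#' solveMuFromIntercept(-0.59745164)  # 2.256442
#' @export
solveMuFromIntercept <- function(b, tol = 1e-12, maxIter = 60L) {
  if (length(b) > 1)
    return(vapply(b, solveMuFromIntercept, numeric(1),
                  tol = tol, maxIter = maxIter))
  if (b >= 0) stop("intercept must be negative (no root for b >= 0)")
  ## delta = 1e-6: below that, sin(mu) - mu*cos(mu) ~ mu^3/3 underflows
  ## to cancellation noise; all physical roots are O(1)
  .bisect(function(mu) shapeIntercept(mu) - b, 1e-6, pi - 1e-6,
          tol = tol, maxIter = maxIter)
}

#' Biot number from the first eigenvalue
#'
#' Biot = 1 - mu cot(mu), the sphere boundary condition linking the
#' first eigenvalue to the ratio of internal diffusive to external
#' convective resistance. Strictly increasing on (0, pi), -> 0 as
#' mu -> 0+ and -> Inf as mu -> pi-.
#'
#' @param mu eigenvalue(s) in (0, pi).
#' @return Biot number(s).
#' @export
biotFromMu <- function(mu) {
  if (any(mu <= 0 | mu >= pi)) stop("mu must lie in (0, pi)")
  1 - mu / tan(mu)
}

#' Eigenvalues of the sphere boundary condition for a given Biot number
#'
#' Finds the first `k` positive roots of 1 - mu cot(mu) = Biot. The
#' function is strictly increasing between consecutive vertical
#' asymptotes at multiples of pi, so root n is bracketed on
#' ((n-1) pi + delta, n pi - delta) and located by bisection.
#'
#' @param biot Biot number, positive.
#' @param k number of roots (default 6).
#' @param tol bisection tolerance (default 1e-12).
#' @return A [RootSet-class].
#' @examples
#' eigenRoots(rootsForBiot(2.8459, 2))  # 2.2564 5.0621
#' @export
rootsForBiot <- function(biot, k = 6L, tol = 1e-12) {
  stopifnot(biot > 0, k >= 1)
  delta <- 1e-9
  roots <- vapply(seq_len(k), function(n) {
    .bisect(function(mu) 1 - mu / tan(mu) - biot,
            (n - 1) * pi + delta, n * pi - delta, tol = tol, maxIter = 200L)
  }, numeric(1))
  new("RootSet", biot = biot, roots = roots)
}

#' Effective moisture diffusivity from the drying-line slope
#'
#' D = |a| L^2 / mu^2, inverting slope a = -mu^2 D / L^2.
#'
#' @param slope fitted slope a (1/s), negative.
#' @param mu first eigenvalue, in (0, pi).
#' @param radiusL characteristic length L (m), the bean radius.
#' @return Effective moisture diffusivity (m^2/s).
#' @export
dEffFromSlope <- function(slope, mu, radiusL) {
  if (any(slope >= 0)) stop("slope must be negative")
  if (any(mu <= 0 | mu >= pi)) stop("mu must lie in (0, pi)")
  stopifnot(radiusL > 0)
  abs(slope) * radiusL^2 / mu^2
}

#' Convective mass-transfer coefficient
#'
#' h_m = Biot * D / L, from the definition Biot = h_m L / D.
#'
#' @param biot Biot number.
#' @param dEff effective moisture diffusivity (m^2/s).
#' @param radiusL characteristic length L (m).
#' @return Mass-transfer coefficient (m/s).
#' @export
hmFromBiot <- function(biot, dEff, radiusL) {
  stopifnot(all(biot > 0), all(dEff > 0), radiusL > 0)
  biot * dEff / radiusL
}

#' Transport parameters from fitted drying-line coefficients
#'
#' Chains [solveMuFromIntercept()], [biotFromMu()], [dEffFromSlope()]
#' and [hmFromBiot()] starting from a fitted (slope, intercept) pair.
#'
#' @param slope slope a (1/s), negative.
#' @param intercept intercept b, negative.
#' @param radiusL characteristic length L (m).
#' @param temperature drying-air temperature (degrees C), for labelling.
#' @param fitMse mean squared error of the underlying fit, if known.
#' @return A [TransportParams-class].
#' @examples
#' transportFromCoefficients(-1.46982169e-5, -0.59745164, 3.968e-4, 30)
#' @export
transportFromCoefficients <- function(slope, intercept, radiusL,
                                      temperature = NA_real_,
                                      fitMse = NA_real_) {
  mu <- solveMuFromIntercept(intercept)
  biot <- biotFromMu(mu)
  dEff <- dEffFromSlope(slope, mu, radiusL)
  new("TransportParams", mu = mu, biot = biot, dEff = dEff,
      hM = hmFromBiot(biot, dEff, radiusL), radiusL = radiusL,
      temperature = temperature, fitMse = fitMse)
}

#' Estimate moisture-transport parameters from a drying curve
#'
#' Full inverse pipeline: log moisture ratio, ordinary least squares of
#' the linearized drying line, eigenvalue from the intercept, Biot
#' number, effective diffusivity from the slope, and the convective
#' mass-transfer coefficient.
#'
#' @param curve a [DryingCurve-class].
#' @param meq equilibrium moisture (dry basis, %). When `NULL`, the
#'   series minimum ([equilibriumMoisture()]) is used and the point(s)
#'   at the minimum are dropped from the ratio.
#' @param radiusL characteristic length L (m).
#' @param m0 initial moisture (dry basis, %); see [moistureRatio()].
#' @param minFourier optional lower Fourier-number cutoff
#'   (Fo = D t / L^2 estimated from a provisional fit): points below it
#'   are refitted away, restricting the regression to the regime where
#'   the first series term dominates. `NULL` (default) fits all points.
#' @return A [TransportParams-class].
#' @export
estimateTransport <- function(curve, meq = NULL, radiusL, m0 = NULL,
                              minFourier = NULL) {
  if (is.null(meq)) meq <- equilibriumMoisture(curve)$meq
  series <- moistureRatio(curve, meq, m0 = m0)
  fit <- linearizedFit(series)
  if (!is.null(minFourier)) {
    ## provisional D from the full fit sets the Fo scale, then refit
    mu0 <- solveMuFromIntercept(fit@intercept)
    d0 <- dEffFromSlope(fit@slope, mu0, radiusL)
    keep <- d0 * series@timesS / radiusL^2 > minFourier
    if (sum(keep) >= 3) {
      sub <- new("MoistureRatioSeries", timesS = series@timesS[keep],
                 logRatio = series@logRatio[keep], m0 = series@m0,
                 meq = series@meq, nDropped = series@nDropped)
      fit <- linearizedFit(sub)
    }
  }
  transportFromCoefficients(fit@slope, fit@intercept, radiusL,
                            temperature = temperature(curve),
                            fitMse = fit@mse)
}

#' Dimensionless moisture from the eigenfunction series
#'
#' Evaluates the analytical sphere solution
#' phi(x/L, Fo) = sum_n c_n(mu_n) sin(mu_n x/L)/(mu_n x/L)
#' exp(-mu_n^2 Fo) with c_n = 2 (sin mu_n - mu_n cos mu_n) /
#' (mu_n - sin mu_n cos mu_n), truncated at `nTerms` terms. At
#' x/L -> 0 the spatial factor takes its sin(z)/z -> 1 limit. At large
#' Fourier number the first term dominates, which is the regime the
#' linearized estimation relies on.
#'
#' @param xOverL dimensionless position in the unit interval (scalar).
#' @param fourier Fourier number(s) Fo = D t / L^2, >= 0.
#' @param biot Biot number.
#' @param nTerms number of series terms (>= 1).
#' @return Dimensionless moisture ratio, same length as `fourier`.
#' @export
seriesPhi <- function(xOverL, fourier, biot, nTerms = 1L) {
  stopifnot(xOverL >= 0, xOverL <= 1, all(fourier >= 0), nTerms >= 1)
  mu <- eigenRoots(rootsForBiot(biot, nTerms))
  cn <- 2 * (sin(mu) - mu * cos(mu)) / (mu - sin(mu) * cos(mu))
  z <- mu * xOverL
  spatial <- ifelse(z == 0, 1, sin(z) / ifelse(z == 0, 1, z))
  amp <- cn * spatial
  sapply(fourier, function(fo) sum(amp * exp(-mu^2 * fo)))
}
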