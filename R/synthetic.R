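## Seeded synthetic generators emulating the study conditions: drying
## curves from the forward sphere solution, hyperspectral cubes whose
## planted absorbance peaks are linked to cup score through the
## fixed-coefficient score model, and sensory score tables. Every
## generator is a pure function of its arguments including the seed,
## and emits the ground truth needed by recovery tests.

#' Generate a synthetic thin-layer drying curve
#'
#' Forward evaluation of the sphere solution at the surface:
#' M(t) = Meq + (M0 - Meq) phi(1, Fo(t), Biot) with Fo = D t / L^2,
#' plus optional Gaussian measurement noise on moisture. With
#' `nTerms = 1` the series is truncated to its first term (the regime
#' the linearized estimation assumes) and the curve starts at the
#' first positive sampling time, since the single-term sum does not
#' satisfy the initial condition at Fo = 0; with many terms (e.g. 50,
#' the oracle regime) the curve starts at t = 0 with M = M0 exactly.
#'
#' Defaults reproduce the study conditions: initial moisture 45% wet
#' basis (81.82% dry), equilibrium near 12% wet basis, sampling every
#' 2 h, and the 30 degC transport parameters.
#'
#' @param dEff true effective diffusivity (m^2/s).
#' @param biot true Biot number.
#' @param radiusL characteristic length L (m).
#' @param m0 initial moisture (dry basis, %).
#' @param meq equilibrium moisture (dry basis, %).
#' @param temperature label (degrees C).
#' @param dtH sampling interval (h, default 2).
#' @param durationH total drying time (h).
#' @param noiseSD Gaussian noise SD on moisture (%; applied in the
#'   measurement domain, default 0).
#' @param nTerms series terms (1 = first-term, >= 50 = oracle).
#' @param seed integer seed.
#' @param replicateId replicate label.
#' @return List with `curve` (a [DryingCurve-class]) and `truth`
#'   (list: dEff, biot, mu, hM, slope, intercept, m0, meq).
#' @export
simDryingCurve <- function(dEff = 4.538592e-13, biot = 2.845864,
                           radiusL = 3.968e-4, m0 = 81.8182,
                           meq = 13.6364, temperature = 30, dtH = 2,
                           durationH = 52, noiseSD = 0, nTerms = 1L,
                           seed = 1L, replicateId = "r1") {
  stopifnot(dEff > 0, biot > 0, radiusL > 0, m0 > meq)
  times <- seq(0, durationH, by = dtH)
  if (nTerms == 1L) times <- times[times > 0]
  fo <- dEff * (times * 3600) / radiusL^2
  ratio <- seriesPhi(1, fo, biot, nTerms)
  ratio[times == 0] <- 1               # exact initial condition
  m <- meq + (m0 - meq) * ratio
  if (noiseSD > 0)
    m <- m + withSeed(seed, stats::rnorm(length(m), 0, noiseSD))
  mu <- eigenRoots(rootsForBiot(biot, 1L))
  list(curve = DryingCurve(temperature, times, m, basis = "dry",
                           replicateId = replicateId),
       truth = list(dEff = dEff, biot = biot, mu = mu,
                    hM = hmFromBiot(biot, dEff, radiusL),
                    slope = -mu^2 * dEff / radiusL^2,
                    intercept = shapeIntercept(mu),
                    m0 = m0, meq = meq, radiusL = radiusL))
}

## truncated-normal draw by rejection
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

## spectral construction shared by the cube and matrix generators:
## returns per-sample noiseless absorbance spectra whose post-SG values
## at the planted centers invert the score model to the drawn scores.
## The score-linked excursion follows an equal-magnitude direction
## (signs matching the model gradient) rather than the minimum-norm
## gradient itself, so all four planted bands carry comparable
## score-driven variance.
.plantSpectra <- function(scores, wl, peakCenters, peakFWHM, baselineAbs,
                          baseTotals, config) {
  centerBands <- vapply(peakCenters, function(c0)
    which.min(abs(wl - c0)), integer(1))
  sigma <- peakFWHM / (2 * sqrt(2 * log(2)))
  unitPeaks <- vapply(centerBands, function(b)
    exp(-(wl - wl[b])^2 / (2 * sigma^2)), numeric(length(wl)))
  ## SG center attenuation per peak, measured with the package's own
  ## smoother so the compensation matches the analysis exactly
  kappa <- vapply(seq_along(centerBands), function(j)
    sgSmooth(unitPeaks[, j], config)[centerBands[j]], numeric(1))
  g <- .scoreGradient()
  u <- sign(g) / sum(sign(g) * g)       # unit score response, equal bands
  yBase <- cupScoreModel(baseTotals[1], baseTotals[2],
                         baseTotals[3], baseTotals[4])
  spectra <- matrix(0, length(scores), length(wl))
  totals <- matrix(0, length(scores), 4)
  for (i in seq_along(scores)) {
    tot <- baseTotals + (scores[i] - yBase) * u   # exact inversion
    amp <- (tot - baselineAbs) / kappa  # pre-compensate SG attenuation
    if (any(amp <= 0))
      stop("planted amplitude non-positive; raise baseTotals")
    spectra[i, ] <- baselineAbs + drop(unitPeaks %*% amp)
    totals[i, ] <- tot
  }
  list(spectra = spectra, totals = totals, centerBands = centerBands,
       kappa = kappa)
}

#' Generate synthetic hyperspectral cubes linked to cup score
#'
#' Per sample: a cup score is drawn from a truncated normal, the four
#' planted Gaussian absorbance peaks (480, 600, 720, 940 nm) are
#' scaled so that the fixed-coefficient score model evaluated at the
#' post-smoothing center absorbances returns the drawn score exactly,
#' the spectrum is converted to reflectance and embedded in an
#' elliptical bean region on a brighter background, per-pixel Gaussian
#' noise is added in the absorbance domain, and the raw signal is
#' synthesized against flat white and dark reference frames.
#'
#' Peak centers snap to the nearest grid band and amplitudes are
#' pre-compensated for the Savitzky-Golay center attenuation, so the
#' noiseless preprocessing round trip is exact. The generator targets
#' the statistical structure of the data, not radiometric realism: the
#' printed score model's shallow gradient forces planted absorbances
#' far outside the physical range.
#'
#' @param nSamples number of cubes.
#' @param dims image height and width (pixels).
#' @param nBands number of bands (default 112 over 400-1000 nm).
#' @param wlRange wavelength range (nm).
#' @param peakCenters nominal planted peak centers (nm).
#' @param peakFWHM peak full width at half maximum (nm, default 30:
#'   wide enough to survive the default 23-point smoothing window on
#'   the ~5.4 nm band grid).
#' @param baselineAbs off-peak bean absorbance.
#' @param baseTotals center absorbance totals at the mean score;
#'   excursions follow the score-model gradient.
#' @param noiseSD per-pixel absorbance noise SD.
#' @param backgroundR background stage reflectance.
#' @param whiteLevel,darkLevel flat reference frame signal levels.
#' @param scoreMean,scoreSD,scoreRange truncated-normal score
#'   distribution (defaults N(83.4, 1.5^2) truncated to 80..88).
#' @param temps temperatures cycled over samples (labels only; the
#'   default linkage is score-only).
#' @param config [SGConfig-class] the analysis will use.
#' @param seed integer seed.
#' @return List with `cubes` (list of raw [HyperCube-class]), `refs`
#'   (a [ReferenceFrames-class]), `scores` (data.frame sample_id,
#'   temperature, cup_score) and `truth` (list with wavelengths,
#'   center bands, per-sample planted center totals and noiseless
#'   spectra, SG attenuations, bean mask).
#' @export
simHyperCubes <- function(nSamples = 12L, dims = c(32L, 32L),
                          nBands = 112L, wlRange = c(400, 1000),
                          peakCenters = c(480, 600, 720, 940),
                          peakFWHM = 30, baselineAbs = 0.7,
                          baseTotals = c(32, 32, 32, 32),
                          noiseSD = 0.02, backgroundR = 0.9,
                          whiteLevel = 0.94, darkLevel = 0,
                          scoreMean = 83.4, scoreSD = 1.5,
                          scoreRange = c(80, 88),
                          temps = c(30, 40, 50, 60),
                          config = SGConfig(), seed = 1L) {
  stopifnot(noiseSD >= 0, all(peakCenters > wlRange[1]),
            all(peakCenters < wlRange[2]))
  wl <- seq(wlRange[1], wlRange[2], length.out = nBands)
  withSeed(seed, {
    scores <- .rtruncnorm(nSamples, scoreMean, scoreSD,
                          scoreRange[1], scoreRange[2])
    planted <- .plantSpectra(scores, wl, peakCenters, peakFWHM,
                             baselineAbs, baseTotals, config)
    ## elliptical bean mask, shared geometry
    h <- dims[1]; w <- dims[2]
    rr <- outer(((seq_len(h) - (h + 1) / 2) / (0.35 * h))^2,
                ((seq_len(w) - (w + 1) / 2) / (0.42 * w))^2, "+")
    beanMask <- rr <= 1
    span <- whiteLevel - darkLevel
    cubes <- vector("list", nSamples)
    for (i in seq_len(nSamples)) {
      refl <- array(0, dim = c(h, w, nBands))
      nBean <- sum(beanMask)
      aNoise <- matrix(stats::rnorm(nBean * nBands, 0, noiseSD),
                       nBean, nBands)
      beanA <- sweep(aNoise, 2, planted$spectra[i, ], "+")
      bg <- backgroundR +
        matrix(stats::rnorm((h * w - nBean) * nBands, 0, noiseSD),
               h * w - nBean, nBands)
      bg[bg <= 0] <- 1e-4
      flat <- matrix(0, h * w, nBands)
      flat[as.vector(beanMask), ] <- 10^(-beanA)
      flat[!as.vector(beanMask), ] <- bg
      refl[] <- flat
      cubes[[i]] <- HyperCube(darkLevel + refl * span, wl)
    }
    refs <- ReferenceFrames(
      white = array(whiteLevel, dim = c(1, w, nBands)),
      dark = array(darkLevel, dim = c(1, w, nBands)))
    list(cubes = cubes, refs = refs,
         scores = data.frame(
           sample_id = sprintf("s%02d", seq_len(nSamples)),
           temperature = rep_len(temps, nSamples),
           cup_score = scores),
         truth = list(wavelengths = wl,
                      centerBands = planted$centerBands,
                      centerTotals = planted$totals,
                      spectra = planted$spectra,
                      kappa = planted$kappa, beanMask = beanMask))
  })
}

#' Generate a synthetic absorbance spectra matrix linked to cup score
#'
#' The imaging-free counterpart of [simHyperCubes()]: per-sample
#' absorbance profiles (as produced by median-ROI extraction) with the
#' same planted score linkage, plus per-band Gaussian noise. Suitable
#' for exercising the regression stage on many samples cheaply.
#'
#' @inheritParams simHyperCubes
#' @param noiseSD per-band absorbance noise SD on the profile.
#' @return List with `X` (samples x bands absorbance matrix, bands
#'   named by wavelength), `scores` (data.frame as in
#'   [simHyperCubes()]) and `truth`.
#' @export
simSpectraSet <- function(nSamples = 80L, nBands = 112L,
                          wlRange = c(400, 1000),
                          peakCenters = c(480, 600, 720, 940),
                          peakFWHM = 30, baselineAbs = 0.7,
                          baseTotals = c(32, 32, 32, 32),
                          noiseSD = 0.02, scoreMean = 83.4,
                          scoreSD = 1.5, scoreRange = c(80, 88),
                          temps = c(30, 40, 50, 60),
                          config = SGConfig(), seed = 1L) {
  wl <- seq(wlRange[1], wlRange[2], length.out = nBands)
  withSeed(seed, {
    scores <- .rtruncnorm(nSamples, scoreMean, scoreSD,
                          scoreRange[1], scoreRange[2])
    planted <- .plantSpectra(scores, wl, peakCenters, peakFWHM,
                             baselineAbs, baseTotals, config)
    X <- planted$spectra +
      matrix(stats::rnorm(nSamples * nBands, 0, noiseSD),
             nSamples, nBands)
    colnames(X) <- wl
    rownames(X) <- sprintf("s%02d", seq_len(nSamples))
    list(X = X,
         scores = data.frame(
           sample_id = rownames(X),
           temperature = rep_len(temps, nSamples),
           cup_score = scores),
         truth = list(wavelengths = wl,
                      centerBands = planted$centerBands,
                      centerTotals = planted$totals,
                      spectra = planted$spectra,
                      kappa = planted$kappa))
  })
}

#' Generate a synthetic sensory score table
#'
#' Seeded Gaussian draws of replicate cup scores around per-temperature
#' means, clipped to the valid 0-100 score range. Defaults follow the
#' study's summary statistics (per-temperature means near 83.4 with
#' SDs of 0.9-1.7 cup points, three replicates).
#'
#' @param means named per-temperature mean cup scores.
#' @param sds per-temperature SDs (recycled).
#' @param nReplicates replicates per temperature.
#' @param seed integer seed.
#' @return data.frame with `temperature`, `replicate`, `cup_score`.
#' @export
simSensoryTable <- function(means = c(`30` = 83.2, `40` = 83.5,
                                      `50` = 83.6, `60` = 83.26),
                            sds = c(1.66, 1.45, 0.88, 1.71),
                            nReplicates = 3L, seed = 1L) {
  stopifnot(length(means) >= 1)
  sds <- rep_len(sds, length(means))
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_along(means), function(i) {
      data.frame(temperature = as.numeric(names(means)[i]),
                 replicate = seq_len(nReplicates),
                 cup_score = pmin(100, pmax(0,
                   stats::rnorm(nReplicates, means[i], sds[i]))))
    }))
    rownames(out) <- NULL
    out
  })
}
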