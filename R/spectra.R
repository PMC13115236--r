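## Hyperspectral preprocessing: white/dark reflectance calibration,
## ROI segmentation, median spectrum extraction, absorbance conversion
## and Savitzky-Golay smoothing.

#' White/dark reflectance correction
#'
#' Corrected reflectance Rc = (S - D)/(W - D) per pixel and band, where
#' S is the raw signal and W, D the white and dark reference frames.
#' Line references (1 x W x B), as produced by push-broom scanners that
#' calibrate per column, are broadcast over image rows. Pixels where
#' W - D <= `eps` carry no dynamic range and are masked `NA`; negative
#' corrected values (noise below the dark level) are clipped to 0.
#'
#' @param raw a raw [HyperCube-class].
#' @param refs a [ReferenceFrames-class].
#' @param eps minimum admissible white-minus-dark signal (default 1e-9).
#' @return A calibrated [HyperCube-class].
#' @export
correctReflectance <- function(raw, refs, eps = 1e-9) {
  stopifnot(is(raw, "HyperCube"), is(refs, "ReferenceFrames"))
  s <- cubeData(raw)
  d <- dim(s)
  w <- refs@white; dk <- refs@dark
  if (dim(w)[1] == 1L && d[1] > 1L) {        # broadcast line reference
    w <- array(rep(w, each = d[1]), dim = d)
    dk <- array(rep(dk, each = d[1]), dim = d)
  }
  if (!identical(dim(w), d))
    stop("reference shape not broadcastable to cube shape")
  denom <- w - dk
  rc <- (s - dk) / denom
  rc[denom <= eps] <- NA_real_
  rc[!is.na(rc) & rc < 0] <- 0
  HyperCube(rc, wavelengths(raw), calibrated = TRUE)
}

#' Segment the sample region of interest by Otsu thresholding
#'
#' Thresholds the band-averaged reflectance image with Otsu's method
#' (via \pkg{EBImage}). By default the foreground is the class with the
#' lower mean reflectance (dark beans on a bright stage); set
#' `invert = TRUE` for bright samples on a dark background.
#'
#' @param cube a calibrated [HyperCube-class].
#' @param invert take the brighter class as foreground.
#' @return Logical H x W matrix, `TRUE` on the sample, with the Otsu
#'   threshold attached as attribute `"threshold"`.
#' @export
segmentROI <- function(cube, invert = FALSE) {
  stopifnot(is(cube, "HyperCube"))
  if (!cube@calibrated) stop("cube must be calibrated first")
  img <- apply(cubeData(cube), c(1, 2), mean, na.rm = TRUE)
  rng <- range(img, finite = TRUE)
  if (diff(rng) < 1e-12)
    stop("uniform image: no bimodality to threshold")
  thr <- EBImage::otsu(img, range = rng)
  mask <- img < thr
  if (invert) mask <- !mask
  if (!any(mask)) stop("empty foreground after thresholding")
  attr(mask, "threshold") <- thr
  mask
}

#' Median spectral profile over a region of interest
#'
#' Per-band median over the masked pixels; masked-out and invalid (NA)
#' pixels are excluded, never zero-filled.
#'
#' @param cube a [HyperCube-class].
#' @param mask logical H x W matrix, `TRUE` on pixels to include.
#' @param sampleId sample label for the profile.
#' @param metadata named list carried on the profile.
#' @return A [SpectralProfile-class] (kind `"reflectance"`).
#' @export
medianProfile <- function(cube, mask, sampleId = "s1", metadata = list()) {
  stopifnot(is(cube, "HyperCube"), is.logical(mask))
  dat <- cubeData(cube)
  if (!all(dim(mask) == dim(dat)[1:2])) stop("mask shape mismatch")
  if (!any(mask)) stop("empty mask")
  flat <- matrix(dat, nrow = prod(dim(dat)[1:2]))
  med <- apply(flat[as.vector(mask), , drop = FALSE], 2,
               stats::median, na.rm = TRUE)
  SpectralProfile(wavelengths(cube), med, kind = "reflectance",
                  sampleId = sampleId, metadata = metadata)
}

#' Convert a reflectance profile to absorbance
#'
#' A = -log10(R), the Beer-Lambert absorbance convention. Zero
#' reflectances are floored at `floorR` with a warning; a natural-log
#' variant is available since downstream centered regression is
#' equivariant to the log base.
#'
#' @param profile a reflectance [SpectralProfile-class].
#' @param base log base, `10` (default) or `exp(1)`.
#' @param floorR floor applied to non-positive reflectance (default
#'   1e-6).
#' @return An absorbance [SpectralProfile-class].
#' @export
toAbsorbance <- function(profile, base = 10, floorR = 1e-6) {
  stopifnot(is(profile, "SpectralProfile"))
  if (profileKind(profile) != "reflectance")
    stop("profile must be reflectance")
  r <- profileValues(profile)
  if (all(r <= 0)) stop("all-zero reflectance profile")
  if (any(r <= 0)) {
    warning(sprintf("floored %d non-positive reflectance value(s) at %g",
                    sum(r <= 0), floorR))
    r[r <= 0] <- floorR
  }
  SpectralProfile(wavelengths(profile), -log(r, base = base),
                  kind = "absorbance", sampleId = profile@sampleId,
                  metadata = profile@metadata)
}

## central least-squares polynomial value over a (possibly truncated)
## window; offsets are relative to the evaluation point
.polyCenter <- function(y, offsets, degree) {
  X <- outer(offsets, 0:degree, "^")
  qr.solve(X, y)[1]
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the value at that point of the least-squares
#' polynomial of degree N fitted to the 2M+1 surrounding points. Near
#' the ends, the window is truncated to the available points and the
#' polynomial refitted, which preserves exactness on polynomials of
#' degree <= N everywhere (including the edges). Any polynomial signal
#' of degree <= N passes through unchanged.
#'
#' @param x a numeric vector or a [SpectralProfile-class].
#' @param config an [SGConfig-class]; the defaults (window 23, degree
#'   2) match common Vis-NIR practice on a ~5.4 nm band grid.
#' @param ... unused.
#' @return Smoothed object of the same class as `x`.
#' @export
setGeneric("sgSmooth", function(x, config = SGConfig(), ...)
  standardGeneric("sgSmooth"))

#' @rdname sgSmooth
#' @export
setMethod("sgSmooth", "numeric", function(x, config = SGConfig(), ...) {
  n <- length(x)
  m <- (config@window - 1L) %/% 2L
  deg <- config@degree
  if (config@window > n) stop("window exceeds signal length")
  out <- numeric(n)
  ## interior: one shared coefficient vector (convolution weights)
  offs <- -m:m
  X <- outer(offs, 0:deg, "^")
  w <- solve(crossprod(X), t(X))[1, ]          # center row of the projector
  interior <- (m + 1L):(n - m)
  for (i in interior) out[i] <- sum(w * x[(i - m):(i + m)])
  ## edges: truncated-window refit
  for (i in seq_len(m)) {
    j <- 1:min(n, i + m)
    out[i] <- .polyCenter(x[j], j - i, min(deg, length(j) - 1L))
    j2 <- max(1, n - i - m + 1L):n
    out[n - i + 1L] <- .polyCenter(x[j2], j2 - (n - i + 1L),
                                   min(deg, length(j2) - 1L))
  }
  out
})

#' @rdname sgSmooth
#' @export
setMethod("sgSmooth", "SpectralProfile",
  function(x, config = SGConfig(), ...) {
    SpectralProfile(wavelengths(x),
                    sgSmooth(profileValues(x), config),
                    kind = profileKind(x), sampleId = x@sampleId,
                    metadata = x@metadata)
  })

#' Preprocess a raw cube to a smoothed absorbance profile
#'
#' Convenience chain: reflectance correction, ROI segmentation, median
#' profile, absorbance conversion, Savitzky-Golay smoothing.
#'
#' @param raw raw [HyperCube-class].
#' @param refs [ReferenceFrames-class].
#' @param config [SGConfig-class].
#' @param sampleId sample label.
#' @param metadata named list carried on the profile.
#' @param invert see [segmentROI()].
#' @return Smoothed absorbance [SpectralProfile-class].
#' @export
preprocessCube <- function(raw, refs, config = SGConfig(),
                           sampleId = "s1", metadata = list(),
                           invert = FALSE) {
  rc <- correctReflectance(raw, refs)
  mask <- segmentROI(rc, invert = invert)
  prof <- medianProfile(rc, mask, sampleId = sampleId, metadata = metadata)
  sgSmooth(toAbsorbance(prof), config)
}
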