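#' @import methods
NULL

#' Thin-layer drying curve at one drying-air temperature
#'
#' Container for a moisture-vs-time series recorded during convective
#' drying of a single replicate at a constant drying-air temperature.
#' Moisture may be stored on a wet or a dry basis; see
#' [convertBasis()].
#'
#' @slot temperature drying-air temperature (degrees C).
#' @slot times sampling times in hours, non-negative and strictly
#'   increasing.
#' @slot moisture moisture content (%) at each time, on the basis given
#'   by `basis`.
#' @slot basis `"wet"` or `"dry"`.
#' @slot replicateId replicate label.
#'
#' @seealso [DryingCurve()], [estimateTransport()]
#' @exportClass DryingCurve
setClass("DryingCurve",
  representation(
    temperature = "numeric",
    times       = "numeric",
    moisture    = "numeric",
    basis       = "character",
    replicateId = "character"
  )
)

setValidity("DryingCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@moisture))
    msg <- c(msg, "times and moisture must have equal length")
  if (length(object@times) > 0) {
    if (any(object@times < 0)) msg <- c(msg, "times must be non-negative")
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
  }
  if (!(length(object@basis) == 1L && object@basis %in% c("wet", "dry")))
    msg <- c(msg, "basis must be 'wet' or 'dry'")
  else if (object@basis == "wet") {
    if (any(object@moisture <= 0 | object@moisture >= 100))
      msg <- c(msg, "wet-basis moisture must lie in (0, 100)")
  } else if (any(object@moisture <= 0)) {
    msg <- c(msg, "dry-basis moisture must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DryingCurve
#'
#' @param temperature drying-air temperature (degrees C).
#' @param times sampling times (h), strictly increasing.
#' @param moisture moisture content (%) at each time.
#' @param basis moisture basis, `"wet"` or `"dry"`.
#' @param replicateId replicate label.
#' @return A [DryingCurve-class] object.
#' @examples
#' DryingCurve(30, c(0, 2, 4), c(81.8, 60, 45), basis = "dry")
#' @export
DryingCurve <- function(temperature, times, moisture, basis = c("wet", "dry"),
                        replicateId = "r1") {
  basis <- match.arg(basis)
  new("DryingCurve", temperature = as.numeric(temperature),
      times = as.numeric(times), moisture = as.numeric(moisture),
      basis = basis, replicateId = as.character(replicateId))
}

#' Log moisture-ratio series derived from a drying curve
#'
#' Holds ln((M - Meq)/(M0 - Meq)) against time in seconds, the
#' linearized form of the first-term sphere solution.
#'
#' @slot timesS times in seconds.
#' @slot logRatio natural log of the dimensionless moisture ratio.
#' @slot m0 initial moisture (dry basis, %).
#' @slot meq equilibrium moisture (dry basis, %).
#' @slot nDropped number of points dropped because M <= Meq.
#' @seealso [moistureRatio()], [linearizedFit()]
#' @exportClass MoistureRatioSeries
setClass("MoistureRatioSeries",
  representation(timesS = "numeric", logRatio = "numeric",
                 m0 = "numeric", meq = "numeric", nDropped = "integer")
)

setValidity("MoistureRatioSeries", function(object) {
  if (length(object@timesS) != length(object@logRatio))
    return("timesS and logRatio must have equal length")
  if (object@m0 <= object@meq) return("m0 must exceed meq")
  TRUE
})

#' Linearized drying-line fit
#'
#' Ordinary least-squares fit of the log moisture ratio on time:
#' slope a = -mu^2 D / L^2 (1/s) and intercept b, the log of the
#' surface shape factor of the first eigenfunction.
#'
#' @slot slope slope a (1/s), negative for a drying curve.
#' @slot intercept intercept b (dimensionless).
#' @slot mse mean squared error of the residuals.
#' @slot n number of points fitted.
#' @seealso [linearizedFit()], [solveMuFromIntercept()]
#' @exportClass KineticFit
setClass("KineticFit",
  representation(slope = "numeric", intercept = "numeric",
                 mse = "numeric", n = "integer"))

#' Moisture-transport parameters at one temperature
#'
#' First eigenvalue mu, mass-transfer Biot number, effective moisture
#' diffusivity and convective mass-transfer coefficient for a sphere of
#' characteristic radius `radiusL`, as recovered from the linearized
#' first-term drying line.
#'
#' @slot mu first positive eigenvalue, in (0, pi).
#' @slot biot mass-transfer Biot number, `1 - mu * cot(mu)`.
#' @slot dEff effective moisture diffusivity (m^2/s).
#' @slot hM convective mass-transfer coefficient (m/s).
#' @slot radiusL characteristic length L (m).
#' @slot temperature drying-air temperature (degrees C).
#' @slot fitMse mean squared error of the underlying linear fit
#'   (NA when constructed directly from coefficients).
#' @seealso [estimateTransport()], [transportFromCoefficients()]
#' @exportClass TransportParams
setClass("TransportParams",
  representation(mu = "numeric", biot = "numeric", dEff = "numeric",
                 hM = "numeric", radiusL = "numeric",
                 temperature = "numeric", fitMse = "numeric"))

setValidity("TransportParams", function(object) {
  msg <- character()
  if (!(object@mu > 0 && object@mu < pi))
    msg <- c(msg, "mu must lie in (0, pi)")
  if (abs(1 - object@mu / tan(object@mu) - object@biot) > 1e-6)
    msg <- c(msg, "biot inconsistent with 1 - mu*cot(mu)")
  if (object@dEff <= 0) msg <- c(msg, "dEff must be positive")
  if (abs(object@hM * object@radiusL - object@biot * object@dEff) >
      1e-12 * abs(object@biot * object@dEff))
    msg <- c(msg, "hM * L must equal biot * dEff")
  if (length(msg)) msg else TRUE
})

#' Eigenvalue set of the sphere boundary condition
#'
#' First k positive roots of `1 - mu * cot(mu) = Biot`; root n lies in
#' ((n-1) pi, n pi).
#'
#' @slot biot mass-transfer Biot number.
#' @slot roots strictly increasing positive roots.
#' @seealso [rootsForBiot()]
#' @exportClass RootSet
setClass("RootSet", representation(biot = "numeric", roots = "numeric"))

setValidity("RootSet", function(object) {
  k <- length(object@roots)
  if (k == 0) return("at least one root required")
  lo <- (seq_len(k) - 1) * pi
  if (any(object@roots <= lo) || any(object@roots >= lo + pi))
    return("root n must lie in ((n-1)*pi, n*pi)")
  if (k > 1 && any(diff(object@roots) <= 0))
    return("roots must be strictly increasing")
  TRUE
})

#' Arrhenius fit of a transport coefficient
#'
#' Linear regression of ln(coefficient) on 1/(T + 273.15); the slope
#' carries the activation energy (Ea = -slope * R) and the intercept
#' the pre-exponential factor.
#'
#' @slot slope regression slope (K).
#' @slot intercept regression intercept (log of the pre-factor).
#' @slot preFactor pre-exponential factor, `exp(intercept)`.
#' @slot activationEnergy activation energy Ea (kJ/mol).
#' @slot r2 coefficient of determination.
#' @slot gasConstant gas constant used (J/mol/K).
#' @slot n number of temperatures fitted.
#' @seealso [fitArrhenius()], [predict,ArrheniusFit-method]
#' @exportClass ArrheniusFit
setClass("ArrheniusFit",
  representation(slope = "numeric", intercept = "numeric",
                 preFactor = "numeric", activationEnergy = "numeric",
                 r2 = "numeric", gasConstant = "numeric", n = "integer"))

setValidity("ArrheniusFit", function(object) {
  msg <- character()
  if (abs(object@preFactor - exp(object@intercept)) >
      1e-9 * object@preFactor)
    msg <- c(msg, "preFactor must equal exp(intercept)")
  if (object@r2 < -1e-9 || object@r2 > 1 + 1e-9)
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Hyperspectral cube
#'
#' A height x width x bands array of raw signal or corrected
#' reflectance, with the wavelength (nm) of each band.
#'
#' @slot data numeric array H x W x B; corrected cubes may carry NA for
#'   masked (invalid) pixels.
#' @slot wavelengths strictly increasing band wavelengths (nm).
#' @slot calibrated TRUE after white/dark reflectance correction.
#' @seealso [HyperCube()], [correctReflectance()], [segmentROI()]
#' @exportClass HyperCube
setClass("HyperCube",
  representation(data = "array", wavelengths = "numeric",
                 calibrated = "logical"))

setValidity("HyperCube", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3)
    msg <- c(msg, "data must be a 3-D array (H x W x B)")
  else if (dim(object@data)[3] != length(object@wavelengths))
    msg <- c(msg, "third extent of data must match length(wavelengths)")
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (isTRUE(object@calibrated) &&
      any(object@data < 0, na.rm = TRUE))
    msg <- c(msg, "corrected reflectance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a HyperCube
#'
#' @param data numeric H x W x B array.
#' @param wavelengths band wavelengths (nm), strictly increasing.
#' @param calibrated logical; TRUE if `data` is corrected reflectance.
#' @return A [HyperCube-class] object.
#' @export
HyperCube <- function(data, wavelengths, calibrated = FALSE) {
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      calibrated = calibrated)
}

#' White and dark reference frames
#'
#' References for reflectance correction. Either full frames with the
#' same H x W x B shape as the sample cube or single-line (1 x W x B)
#' references, as acquired by push-broom line scanners that calibrate
#' per column.
#'
#' @slot white white-reference array.
#' @slot dark dark-reference array, same shape as `white`.
#' @seealso [correctReflectance()]
#' @exportClass ReferenceFrames
setClass("ReferenceFrames", representation(white = "array", dark = "array"))

setValidity("ReferenceFrames", function(object) {
  if (!identical(dim(object@white), dim(object@dark)))
    return("white and dark must have identical dimensions")
  if (length(dim(object@white)) != 3)
    return("references must be 3-D arrays (H x W x B or 1 x W x B)")
  TRUE
})

#' @rdname ReferenceFrames-class
#' @param white,dark reference arrays (H x W x B or 1 x W x B).
#' @return A [ReferenceFrames-class] object.
#' @export
ReferenceFrames <- function(white, dark) {
  new("ReferenceFrames", white = white, dark = dark)
}

#' Single spectral profile
#'
#' A wavelength-indexed reflectance or absorbance vector for one
#' sample, typically the median spectrum over a segmented region of
#' interest.
#'
#' @slot wavelengths wavelengths (nm), strictly increasing.
#' @slot values reflectance or absorbance per band.
#' @slot kind `"reflectance"` or `"absorbance"`.
#' @slot sampleId sample label.
#' @slot metadata named list (e.g. temperature, replicate).
#' @seealso [medianProfile()], [toAbsorbance()], [sgSmooth()]
#' @exportClass SpectralProfile
setClass("SpectralProfile",
  representation(wavelengths = "numeric", values = "numeric",
                 kind = "character", sampleId = "character",
                 metadata = "list"))

setValidity("SpectralProfile", function(object) {
  msg <- character()
  if (length(object@wavelengths) != length(object@values))
    msg <- c(msg, "wavelengths and values must have equal length")
  if (!(length(object@kind) == 1L &&
        object@kind %in% c("reflectance", "absorbance")))
    msg <- c(msg, "kind must be 'reflectance' or 'absorbance'")
  else if (object@kind == "reflectance" &&
           any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "reflectance values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralProfile
#'
#' @param wavelengths wavelengths (nm).
#' @param values per-band values.
#' @param kind `"reflectance"` or `"absorbance"`.
#' @param sampleId sample label.
#' @param metadata named list of sample metadata.
#' @return A [SpectralProfile-class] object.
#' @export
SpectralProfile <- function(wavelengths, values,
                            kind = c("reflectance", "absorbance"),
                            sampleId = "s1", metadata = list()) {
  kind <- match.arg(kind)
  new("SpectralProfile", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values), kind = kind,
      sampleId = as.character(sampleId), metadata = metadata)
}

#' Savitzky-Golay filter configuration
#'
#' @slot window odd window length 2M+1 (points).
#' @slot degree polynomial degree N, with N < window.
#' @seealso [sgSmooth()]
#' @exportClass SGConfig
setClass("SGConfig", representation(window = "integer", degree = "integer"))

setValidity("SGConfig", function(object) {
  msg <- character()
  if (object@window < 3 || object@window %% 2L == 0L)
    msg <- c(msg, "window must be an odd integer >= 3")
  if (object@degree < 0 || object@degree >= object@window)
    msg <- c(msg, "degree must satisfy 0 <= degree < window")
  if (length(msg)) msg else TRUE
})

#' @rdname SGConfig-class
#' @param window odd window length (default 23).
#' @param degree polynomial degree (default 2).
#' @return An [SGConfig-class] object.
#' @export
SGConfig <- function(window = 23L, degree = 2L) {
  new("SGConfig", window = as.integer(window), degree = as.integer(degree))
}

#' NIPALS partial least squares regression model
#'
#' Mean-centered NIPALS decomposition relating an absorbance matrix to
#' cup score, with per-component weights, loadings and scores and the
#' assembled regression coefficient vector on the original (centered)
#' wavelength axes.
#'
#' @slot nLV number of latent variables.
#' @slot xMean per-wavelength training means.
#' @slot yMean training response mean.
#' @slot weights p x k X-weight matrix (unit columns).
#' @slot xLoadings p x k X-loading matrix.
#' @slot yLoadings length-k y-loading vector.
#' @slot scores n x k training score matrix.
#' @slot coef length-p regression coefficient vector (centered scale).
#' @slot fitted fitted training responses.
#' @slot wavelengths wavelength (nm) of each predictor column.
#' @seealso [fitPLSR()], [predict,PLSRModel-method], [vipScores()]
#' @exportClass PLSRModel
setClass("PLSRModel",
  representation(nLV = "integer", xMean = "numeric", yMean = "numeric",
                 weights = "matrix", xLoadings = "matrix",
                 yLoadings = "numeric", scores = "matrix",
                 coef = "numeric", fitted = "numeric",
                 wavelengths = "numeric"))

setValidity("PLSRModel", function(object) {
  p <- length(object@xMean)
  if (!all(dim(object@weights) == c(p, object@nLV)))
    return("weights must be p x nLV")
  if (!all(dim(object@xLoadings) == c(p, object@nLV)))
    return("xLoadings must be p x nLV")
  if (length(object@yLoadings) != object@nLV)
    return("yLoadings must have length nLV")
  if (length(object@coef) != p)
    return("coef must have length p")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "DryingCurve", function(object) {
  cat(sprintf("DryingCurve: %d points, %.0f degC, %s basis, replicate %s\n",
              length(object@times), object@temperature, object@basis,
              object@replicateId))
  cat(sprintf("  t = %.1f..%.1f h, M = %.2f..%.2f %%\n",
              min(object@times), max(object@times),
              min(object@moisture), max(object@moisture)))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit: a = %.8e 1/s, b = %.8f, MSE = %.4g (n = %d)\n",
              object@slope, object@intercept, object@mse, object@n))
})

setMethod("show", "TransportParams", function(object) {
  cat(sprintf(paste0("TransportParams @ %.0f degC (L = %.4g m)\n",
                     "  mu = %.6f  Biot = %.6f\n",
                     "  D_eff = %.6e m^2/s  h_m = %.6e m/s\n"),
              object@temperature, object@radiusL, object@mu, object@biot,
              object@dEff, object@hM))
})

setMethod("show", "RootSet", function(object) {
  cat(sprintf("RootSet: Biot = %.4f, %d roots\n  %s\n", object@biot,
              length(object@roots),
              paste(sprintf("%.4f", object@roots), collapse = "  ")))
})

setMethod("show", "ArrheniusFit", function(object) {
  cat(sprintf(paste0("ArrheniusFit: ln(v) = %.4f + %.2f/(T+273.15)\n",
                     "  pre-factor = %.4g, Ea = %.3f kJ/mol, r2 = %.4f\n"),
              object@intercept, object@slope, object@preFactor,
              object@activationEnergy, object@r2))
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube: %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths),
              if (object@calibrated) "calibrated" else "raw"))
})

setMethod("show", "SpectralProfile", function(object) {
  cat(sprintf("SpectralProfile '%s': %d bands (%.1f-%.1f nm), %s\n",
              object@sampleId, length(object@values),
              min(object@wavelengths), max(object@wavelengths),
              object@kind))
})

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf("PLSRModel: %d latent variables, %d wavelengths, %d samples\n",
              object@nLV, length(object@xMean), nrow(object@scores)))
})

## ---- accessors ----------------------------------------------------------

#' @title Accessors for beandry S4 classes
#' @description Small read-only accessors; slots are never accessed
#'   directly by user code.
#' @param object a beandry S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dryingTimes", function(object) standardGeneric("dryingTimes"))
#' @rdname accessors
#' @export
setMethod("dryingTimes", "DryingCurve", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("moisture", function(object) standardGeneric("moisture"))
#' @rdname accessors
#' @export
setMethod("moisture", "DryingCurve", function(object) object@moisture)

#' @rdname accessors
#' @export
setGeneric("moistureBasis", function(object) standardGeneric("moistureBasis"))
#' @rdname accessors
#' @export
setMethod("moistureBasis", "DryingCurve", function(object) object@basis)

#' @rdname accessors
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))
#' @rdname accessors
#' @export
setMethod("temperature", "DryingCurve", function(object) object@temperature)
#' @rdname accessors
#' @export
setMethod("temperature", "TransportParams",
          function(object) object@temperature)

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setMethod("wavelengths", "HyperCube", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralProfile",
          function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "PLSRModel", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setMethod("profileValues", "SpectralProfile", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("profileKind", function(object) standardGeneric("profileKind"))
#' @rdname accessors
#' @export
setMethod("profileKind", "SpectralProfile", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("cubeData", function(object) standardGeneric("cubeData"))
#' @rdname accessors
#' @export
setMethod("cubeData", "HyperCube", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("eigenRoots", function(object) standardGeneric("eigenRoots"))
#' @rdname accessors
#' @export
setMethod("eigenRoots", "RootSet", function(object) object@roots)

#' @rdname accessors
#' @export
setGeneric("biotNumber", function(object) standardGeneric("biotNumber"))
#' @rdname accessors
#' @export
setMethod("biotNumber", "TransportParams", function(object) object@biot)
#' @rdname accessors
#' @export
setMethod("biotNumber", "RootSet", function(object) object@biot)

#' @rdname accessors
#' @export
setGeneric("effectiveDiffusivity",
           function(object) standardGeneric("effectiveDiffusivity"))
#' @rdname accessors
#' @export
setMethod("effectiveDiffusivity", "TransportParams",
          function(object) object@dEff)

#' @rdname accessors
#' @export
setGeneric("massTransferCoef",
           function(object) standardGeneric("massTransferCoef"))
#' @rdname accessors
#' @export
setMethod("massTransferCoef", "TransportParams", function(object) object@hM)

#' @rdname accessors
#' @export
setGeneric("firstEigenvalue",
           function(object) standardGeneric("firstEigenvalue"))
#' @rdname accessors
#' @export
setMethod("firstEigenvalue", "TransportParams", function(object) object@mu)

#' @rdname accessors
#' @export
setGeneric("activationEnergy",
           function(object) standardGeneric("activationEnergy"))
#' @rdname accessors
#' @export
setMethod("activationEnergy", "ArrheniusFit",
          function(object) object@activationEnergy)

#' @rdname accessors
#' @export
setGeneric("preFactor", function(object) standardGeneric("preFactor"))
#' @rdname accessors
#' @export
setMethod("preFactor", "ArrheniusFit", function(object) object@preFactor)

#' @rdname accessors
#' @export
setGeneric("nLatent", function(object) standardGeneric("nLatent"))
#' @rdname accessors
#' @export
setMethod("nLatent", "PLSRModel", function(object) object@nLV)

#' @rdname accessors
#' @export
setGeneric("plsrScores", function(object) standardGeneric("plsrScores"))
#' @rdname accessors
#' @export
setMethod("plsrScores", "PLSRModel", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("plsrLoadings", function(object) standardGeneric("plsrLoadings"))
#' @rdname accessors
#' @export
setMethod("plsrLoadings", "PLSRModel", function(object) object@xLoadings)

#' @rdname accessors
#' @param ... ignored.
#' @export
setMethod("coef", "PLSRModel", function(object, ...) object@coef)

#' @rdname accessors
#' @export
setMethod("coef", "KineticFit", function(object, ...)
  c(slope = object@slope, intercept = object@intercept))

#' @rdname accessors
#' @export
setMethod("coef", "ArrheniusFit", function(object, ...)
  c(slope = object@slope, intercept = object@intercept))
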