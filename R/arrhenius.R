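## Arrhenius temperature dependence of the moisture-transport
## coefficients: ln(v) is linear in 1/(T + 273.15), the slope carrying
## the activation energy and the intercept the pre-exponential factor.

#' Gas constant (J mol^-1 K^-1) used throughout
#' @keywords internal
.GAS_CONSTANT <- 8.31446

#' Fit the Arrhenius temperature dependence of a transport coefficient
#'
#' Ordinary least squares of ln(value) on 1/(T + 273.15). The
#' activation energy is Ea = -slope * R / 1000 (kJ/mol) and the
#' pre-exponential factor exp(intercept).
#'
#' @param tempsC drying-air temperatures (degrees C), at least two
#'   distinct values.
#' @param values positive coefficient values (e.g. effective
#'   diffusivities in m^2/s), one per temperature.
#' @return An [ArrheniusFit-class].
#' @examples
#' deff <- c(4.538592, 5.817569, 9.245937, 11.821655) * 1e-13
#' fitArrhenius(c(30, 40, 50, 60), deff)
#' @export
fitArrhenius <- function(tempsC, values) {
  if (length(tempsC) != length(values))
    stop("tempsC and values must have equal length")
  if (any(values <= 0)) stop("values must be positive")
  if (length(unique(tempsC)) < 2)
    stop("at least 2 distinct temperatures required")
  x <- 1 / (tempsC + 273.15)
  y <- log(values)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  r2 <- if (stats::var(y) == 0) 1 else
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  new("ArrheniusFit", slope = slope, intercept = intercept,
      preFactor = exp(intercept),
      activationEnergy = -slope * .GAS_CONSTANT / 1000,
      r2 = r2, gasConstant = .GAS_CONSTANT, n = length(y))
}

#' Predict a transport coefficient at new temperatures
#'
#' Evaluates exp(intercept + slope / (T + 273.15)) from a fitted
#' Arrhenius line.
#'
#' @param object an [ArrheniusFit-class].
#' @param tempsC temperature(s) in degrees C.
#' @param ... ignored.
#' @return Predicted coefficient value(s).
#' @examples
#' fit <- fitArrhenius(c(30, 40, 50, 60),
#'                     c(4.538592, 5.817569, 9.245937, 11.821655) * 1e-13)
#' predict(fit, tempsC = 25)
#' @export
setMethod("predict", "ArrheniusFit", function(object, tempsC, ...) {
  exp(object@intercept + object@slope / (tempsC + 273.15))
})
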