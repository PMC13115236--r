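## NIPALS partial least squares regression of cup score on absorbance
## spectra, with cross-validated latent-variable selection, VIP and
## loading-based wavelength identification, and calibration/validation
## protocol utilities.

#' Fit a PLSR model by NIPALS
#'
#' Mean-centers X and y (no scaling) and extracts `nLV` latent
#' variables by NIPALS with deflation of both X and y. The regression
#' coefficient vector on the centered wavelengths is assembled as
#' beta = W (P'W)^-1 q. With `nLV = rank(X)` the fit coincides with
#' ordinary least squares.
#'
#' @param X numeric samples x wavelengths matrix (absorbance).
#' @param y numeric response (cup score), one value per row of X.
#' @param nLV number of latent variables, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param wl wavelength (nm) of each column; defaults to column index.
#' @return A [PLSRModel-class].
#' @export
fitPLSR <- function(X, y, nLV, wl = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values not supported")
  if (stats::var(y) == 0) stop("constant response")
  if (nLV > min(n - 1, p))
    stop("nLV exceeds min(nrow(X) - 1, ncol(X))")
  if (is.null(wl)) wl <- seq_len(p)
  xMean <- colMeans(X); yMean <- mean(y)
  E <- sweep(X, 2, xMean); f <- y - yMean
  W <- P <- matrix(0, p, nLV)
  Tm <- matrix(0, n, nLV)
  q <- numeric(nLV)
  for (k in seq_len(nLV)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { nLV <- k - 1L; break }
    w <- w / nw
    tk <- drop(E %*% w)
    tt <- sum(tk^2)
    pk <- drop(crossprod(E, tk)) / tt
    qk <- sum(f * tk) / tt
    E <- E - tcrossprod(tk, pk)
    f <- f - tk * qk
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tk; q[k] <- qk
  }
  if (nLV == 0L) stop("no informative component could be extracted")
  W <- W[, seq_len(nLV), drop = FALSE]
  P <- P[, seq_len(nLV), drop = FALSE]
  Tm <- Tm[, seq_len(nLV), drop = FALSE]
  q <- q[seq_len(nLV)]
  beta <- drop(W %*% solve(crossprod(P, W), q))
  model <- new("PLSRModel", nLV = as.integer(nLV), xMean = xMean,
               yMean = yMean, weights = W, xLoadings = P, yLoadings = q,
               scores = Tm, coef = beta,
               fitted = yMean + drop(sweep(X, 2, xMean) %*% beta),
               wavelengths = as.numeric(wl))
  model
}

#' Predict cup scores from a fitted PLSR model
#'
#' y_hat = y_mean + (X - x_mean) beta. The wavelength grid of `newdata`
#' must match the training grid.
#'
#' @param object a [PLSRModel-class].
#' @param newdata samples x wavelengths matrix.
#' @param wl wavelengths of `newdata` columns; checked against the
#'   training grid when given.
#' @param ... ignored.
#' @return Predicted responses.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, wl = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@xMean))
    stop("wavelength grid mismatch: expected ",
         length(object@xMean), " columns")
  if (!is.null(wl) && !isTRUE(all.equal(as.numeric(wl),
                                        object@wavelengths)))
    stop("wavelength grid mismatch with training grid")
  object@yMean + drop(sweep(newdata, 2, object@xMean) %*% object@coef)
})

#' Select the number of latent variables by cross-validated Q2
#'
#' K-fold cross-validation: Q2(k) = 1 - PRESS(k)/TSS with TSS taken on
#' the full training response. Returns the smallest component count
#' attaining the maximum Q2; curve values within `q2Tol` of the
#' maximum are treated as ties, so hairline noise-driven improvements
#' never inflate the selected dimension. The fold partition is drawn
#' once from `seed`.
#'
#' @param X samples x wavelengths matrix.
#' @param y response.
#' @param maxLV largest component count to examine.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold partition.
#' @param q2Tol tie tolerance on the Q2 curve (default 1e-3).
#' @return List with `nLV` (0 when no component predicts better than
#'   the mean, with a warning), `q2` (the Q2 curve) and `folds` (the
#'   fold assignment used).
#' @export
selectNLV <- function(X, y, maxLV, folds = 5L, seed = 1L, q2Tol = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) stop("fewer samples than folds")
  maxLV <- min(maxLV, ncol(X), n - ceiling(n / folds) - 1)
  fold <- withSeed(seed, sample(rep(seq_len(folds), length.out = n)))
  press <- numeric(maxLV)
  for (f in seq_len(folds)) {
    hold <- fold == f
    for (k in seq_len(maxLV)) {
      m <- fitPLSR(X[!hold, , drop = FALSE], y[!hold], k)
      press[k] <- press[k] +
        sum((y[hold] - predict(m, X[hold, , drop = FALSE]))^2)
    }
  }
  tss <- sum((y - mean(y))^2)
  q2 <- 1 - press / tss
  if (max(q2) <= 0) {
    warning("no component predicts better than the mean (max Q2 <= 0)")
    nBest <- 0L
  } else {
    nBest <- which(q2 >= max(q2) - q2Tol)[1]   # smallest k within a tie
  }
  list(nLV = as.integer(nBest), q2 = q2, folds = fold)
}

#' Variable importance in projection
#'
#' Wold VIP: VIP_j = sqrt( p * sum_k SS_k w_jk^2 / sum_k SS_k ) with
#' SS_k = q_k^2 t_k't_k, the response variance explained by component
#' k (weights are unit-norm). The mean of the squared VIPs is 1, so
#' wavelengths with VIP > 1 contribute more than average.
#'
#' @param model a [PLSRModel-class].
#' @return Named numeric vector of per-wavelength VIP scores.
#' @export
vipScores <- function(model) {
  stopifnot(is(model, "PLSRModel"))
  ss <- model@yLoadings^2 * colSums(model@scores^2)
  p <- length(model@xMean)
  vip <- sqrt(p * drop(model@weights^2 %*% ss) / sum(ss))
  names(vip) <- model@wavelengths
  vip
}

#' Wavelengths with influential loadings
#'
#' Wavelengths whose absolute X-loading exceeds `threshold` in any of
#' the first `components` latent variables.
#'
#' @param model a [PLSRModel-class].
#' @param threshold absolute loading threshold (default 0.1).
#' @param components how many leading components to inspect (default 2).
#' @return Wavelengths (nm) passing the threshold.
#' @export
influentialLoadings <- function(model, threshold = 0.1, components = 2L) {
  stopifnot(is(model, "PLSRModel"))
  components <- min(components, nLatent(model))
  hit <- apply(abs(model@xLoadings[, seq_len(components), drop = FALSE]),
               1, max) > threshold
  model@wavelengths[hit]
}

#' Residual predictive deviation
#'
#' RPD = SD / RMSE, the ratio of the reference standard deviation to
#' the prediction RMSE; values above ~2 indicate a usable calibration.
#'
#' @param referenceSD standard deviation of the reference values.
#' @param rmsePred prediction root mean square error, positive.
#' @return RPD.
#' @export
rpd <- function(referenceSD, rmsePred) {
  if (any(rmsePred <= 0)) stop("rmsePred must be positive")
  referenceSD / rmsePred
}

#' Stratified calibration/validation split
#'
#' Splits sample indices into calibration and validation subsets
#' stratum by stratum (e.g. by drying temperature), assigning
#' round-half-up(`calFraction` * n) samples per stratum to calibration
#' (capped at n - 1 so every stratum validates). Deterministic given
#' `seed`.
#'
#' @param strata stratum label per sample; every stratum needs at
#'   least 2 samples.
#' @param calFraction calibration fraction (default 0.7).
#' @param seed integer seed.
#' @return List with integer index vectors `cal` and `val`.
#' @export
stratifiedSplit <- function(strata, calFraction = 0.7, seed = 1L) {
  strata <- as.factor(strata)
  if (any(table(strata) < 2))
    stop("every stratum needs at least 2 samples")
  idx <- split(seq_along(strata), strata)
  withSeed(seed, {
    cal <- integer(0)
    for (ix in idx) {
      nCal <- min(floor(length(ix) * calFraction + 0.5), length(ix) - 1L)
      nCal <- max(nCal, 1L)
      cal <- c(cal, sample(ix, nCal))
    }
    cal <- sort(cal)
    list(cal = cal, val = setdiff(seq_along(strata), cal))
  })
}

#' Calibration/validation performance metrics
#'
#' r2 = 1 - SSE/SST, RMSE, and RPD when a reference standard deviation
#' is supplied.
#'
#' @param yTrue observed responses (non-constant, length >= 2).
#' @param yPred predicted responses.
#' @param referenceSD optional reference SD for RPD.
#' @param label set label, e.g. `"calibration"` or `"validation"`.
#' @return One-row data.frame with `set`, `n`, `r2`, `rmse`, `rpd`.
#' @export
modelMetrics <- function(yTrue, yPred, referenceSD = NULL,
                         label = "calibration") {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2) stop("at least 2 observations required")
  sst <- sum((yTrue - mean(yTrue))^2)
  if (sst == 0) stop("zero-variance reference: r2 undefined")
  sse <- sum((yTrue - yPred)^2)
  rmse <- sqrt(mean((yTrue - yPred)^2))
  data.frame(set = label, n = length(yTrue), r2 = 1 - sse / sst,
             rmse = rmse,
             rpd = if (is.null(referenceSD)) NA_real_ else
               rpd(referenceSD, rmse))
}

## fixed coefficients of the published two-component cup-score model
.SCORE_COEF <- list(
  intercept = 83.14,
  comp = c(0.38, -0.21),
  comp1 = c(abs480 = 0.15, abs600 = 0.09, abs720 = -0.12, abs940 = 0.07),
  comp2 = c(abs480 = -0.08, abs600 = 0.13, abs720 = 0.05, abs940 = -0.04))

#' Fixed-coefficient cup-score model
#'
#' Evaluates the published two-component linear model linking cup
#' score to absorbance at 480, 600, 720 and 940 nm:
#' Y = 83.14 + 0.38 Comp1 - 0.21 Comp2 with
#' Comp1 = 0.15 A480 + 0.09 A600 - 0.12 A720 + 0.07 A940 and
#' Comp2 = -0.08 A480 + 0.13 A600 + 0.05 A720 - 0.04 A940.
#' The model is affine in the four absorbances.
#'
#' @param abs480,abs600,abs720,abs940 absorbance values (vectorized).
#' @return Predicted cup score(s).
#' @examples
#' cupScoreModel(0, 0, 0, 0)   # 83.14
#' @export
cupScoreModel <- function(abs480, abs600, abs720, abs940) {
  A <- cbind(abs480, abs600, abs720, abs940)
  comp1 <- drop(A %*% .SCORE_COEF$comp1)
  comp2 <- drop(A %*% .SCORE_COEF$comp2)
  .SCORE_COEF$intercept + .SCORE_COEF$comp[1] * comp1 +
    .SCORE_COEF$comp[2] * comp2
}

## gradient of cupScoreModel w.r.t. the four absorbances
.scoreGradient <- function() {
  unname(.SCORE_COEF$comp[1] * .SCORE_COEF$comp1 +
           .SCORE_COEF$comp[2] * .SCORE_COEF$comp2)
}

#' One-way ANOVA of sensory scores across drying temperatures
#'
#' Classic between/within decomposition with the p-value from the F
#' distribution (delegated to [stats::oneway.test()] with equal
#' variances). Degenerate input where every observation is identical
#' is reported as F = 0, p = 1.
#'
#' @param groups named list of numeric vectors, one per temperature
#'   (>= 2 groups, >= 2 observations each).
#' @return List with `F`, `p`, `dfBetween`, `dfWithin`.
#' @examples
#' anovaOneWay(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # F = 13.5
#' @export
anovaOneWay <- function(groups) {
  if (length(groups) < 2) stop("at least 2 groups required")
  if (any(lengths(groups) < 2))
    stop("at least 2 observations per group required")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  dfB <- nlevels(g) - 1L
  dfW <- length(y) - nlevels(g)
  if (stats::var(y) == 0)
    return(list(F = 0, p = 1, dfBetween = dfB, dfWithin = dfW))
  tst <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(tst$statistic), p = unname(tst$p.value),
       dfBetween = dfB, dfWithin = dfW)
}
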