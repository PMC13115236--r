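## End-to-end workflows wiring the modules together with one-file
## (YAML or list) configuration, explicit seeds and deterministic
## CSV/JSON outputs.

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

.requireFields <- function(config, fields, where) {
  miss <- setdiff(fields, names(config))
  if (length(miss))
    stop(where, ": missing config field(s): ", paste(miss, collapse = ", "))
}

#' Kinetics workflow: drying curves to transport and Arrhenius tables
#'
#' From either raw drying curves (`curves`: CSV path, see
#' [readDryingCurves()]) or already-fitted drying-line coefficients
#' (`coefficients`: CSV with columns `temperature_C, slope_per_s,
#' intercept` and optional `mse`), estimates per-temperature transport
#' parameters, fits the Arrhenius temperature dependence of both the
#' diffusivity and the mass-transfer coefficient, and predicts both at
#' requested temperatures. Deterministic: rerunning a config
#' reproduces the outputs byte for byte.
#'
#' @param config list or YAML path with fields: `curves` or
#'   `coefficients` (input CSV), `radius_m` (characteristic length L),
#'   optional `meq` (fixed equilibrium moisture, dry basis %; default:
#'   per-curve series minimum), optional `predict_temps_C` (default
#'   `c(25, 35, 45, 55, 65, 70)`), optional `out_dir` (when given,
#'   writes `transport.csv`, `arrhenius.csv`, `predictions.csv`).
#' @return List with data.frames `transport`, `arrhenius`,
#'   `predictions`.
#' @export
runKineticsWorkflow <- function(config) {
  config <- .loadConfig(config)
  .requireFields(config, "radius_m", "kinetics workflow")
  L <- config$radius_m
  predictTemps <- config$predict_temps_C %||% c(25, 35, 45, 55, 65, 70)
  if (!is.null(config$coefficients)) {
    cf <- utils::read.csv(config$coefficients)
    .requireFields(cf, c("temperature_C", "slope_per_s", "intercept"),
                   "coefficients table")
    if (nrow(cf) == 0) stop("empty coefficients table")
    params <- lapply(seq_len(nrow(cf)), function(i)
      transportFromCoefficients(cf$slope_per_s[i], cf$intercept[i], L,
                                temperature = cf$temperature_C[i],
                                fitMse = (cf$mse %||% NA_real_)[i]))
  } else if (!is.null(config$curves)) {
    curves <- readDryingCurves(config$curves)
    if (length(curves) == 0) stop("empty curves input")
    params <- lapply(curves, function(cu)
      estimateTransport(cu, meq = config$meq, radiusL = L,
                        m0 = config$m0))
  } else stop("kinetics workflow: supply 'curves' or 'coefficients'")
  transport <- do.call(rbind, lapply(params, function(p)
    data.frame(temperature_C = temperature(p), mu = firstEigenvalue(p),
               d_eff_m2_s = effectiveDiffusivity(p), biot = biotNumber(p),
               h_m_m_s = massTransferCoef(p), fit_mse = p@fitMse)))
  rownames(transport) <- NULL
  transport <- transport[order(transport$temperature_C), ]
  if (length(unique(transport$temperature_C)) >= 2) {
    fitD <- fitArrhenius(transport$temperature_C, transport$d_eff_m2_s)
    fitH <- fitArrhenius(transport$temperature_C, transport$h_m_m_s)
    arr <- data.frame(
      coefficient = c("d_eff", "h_m"),
      slope_K = c(fitD@slope, fitH@slope),
      intercept = c(fitD@intercept, fitH@intercept),
      pre_factor = c(preFactor(fitD), preFactor(fitH)),
      activation_energy_kJ_mol = c(activationEnergy(fitD),
                                   activationEnergy(fitH)),
      r2 = c(fitD@r2, fitH@r2))
    pred <- data.frame(temperature_C = predictTemps,
                       d_eff_m2_s = predict(fitD, tempsC = predictTemps),
                       h_m_m_s = predict(fitH, tempsC = predictTemps))
  } else {
    ## a single temperature cannot constrain the temperature dependence
    arr <- NULL
    pred <- NULL
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(transport, file.path(config$out_dir, "transport.csv"),
                     row.names = FALSE)
    if (!is.null(arr)) {
      utils::write.csv(arr, file.path(config$out_dir, "arrhenius.csv"),
                       row.names = FALSE)
      utils::write.csv(pred, file.path(config$out_dir, "predictions.csv"),
                       row.names = FALSE)
    }
  }
  list(transport = transport, arrhenius = arr, predictions = pred)
}

#' Chemometrics workflow: spectra to a validated cup-score model
#'
#' Smooths absorbance spectra (Savitzky-Golay), splits samples into
#' calibration and validation stratified by temperature, selects the
#' latent-variable count by 5-fold cross-validated Q2 (capped at
#' `max_lv`), fits the NIPALS PLSR model, and reports calibration and
#' validation metrics plus VIP and loading-selected wavelengths.
#'
#' @param config list or YAML path with fields: `spectra` (spectra
#'   matrix CSV path, see [readSpectraMatrix()]) or `X` (matrix) plus
#'   `scores` (CSV path or data.frame with `sample_id, temperature,
#'   cup_score`), optional `sg_window` (23), `sg_degree` (2),
#'   `max_lv` (10), `folds` (5), `cal_fraction` (0.7), `seed` (1),
#'   `out_dir` (when given, writes `model.json`, `metrics.csv`,
#'   `vip.csv`).
#' @return List with `model` ([PLSRModel-class]), `nLV`, `q2`,
#'   `metrics` (two-row data.frame), `vip` (named vector),
#'   `vipSelected` and `loadingSelected` wavelengths, `split`.
#' @export
runChemometricsWorkflow <- function(config) {
  config <- .loadConfig(config)
  if (!is.null(config$spectra)) {
    sp <- readSpectraMatrix(config$spectra)
    X <- sp$X; wl <- sp$wavelengths
  } else if (!is.null(config$X)) {
    X <- as.matrix(config$X)
    wl <- as.numeric(colnames(X))
  } else stop("chemometrics workflow: supply 'spectra' or 'X'")
  scores <- config$scores
  if (is.character(scores)) scores <- utils::read.csv(scores)
  .requireFields(scores, c("sample_id", "temperature", "cup_score"),
                 "scores table")
  missing <- setdiff(rownames(X), scores$sample_id)
  extra <- setdiff(scores$sample_id, rownames(X))
  if (length(missing) || length(extra))
    stop("sample id mismatch between spectra and scores; ",
         "spectra-only: [", paste(missing, collapse = ", "),
         "], scores-only: [", paste(extra, collapse = ", "), "]")
  scores <- scores[match(rownames(X), scores$sample_id), ]
  cfg <- SGConfig(config$sg_window %||% 23L, config$sg_degree %||% 2L)
  Xs <- t(apply(X, 1, sgSmooth, config = cfg))
  seed <- config$seed %||% 1L
  split <- stratifiedSplit(scores$temperature,
                           calFraction = config$cal_fraction %||% 0.7,
                           seed = seed)
  sel <- selectNLV(Xs[split$cal, , drop = FALSE],
                   scores$cup_score[split$cal],
                   maxLV = config$max_lv %||% 10L,
                   folds = config$folds %||% 5L, seed = seed)
  nLV <- max(sel$nLV, 1L)
  model <- fitPLSR(Xs[split$cal, , drop = FALSE],
                   scores$cup_score[split$cal], nLV, wl = wl)
  sdRef <- stats::sd(scores$cup_score[split$cal])
  metrics <- rbind(
    modelMetrics(scores$cup_score[split$cal],
                 predict(model, Xs[split$cal, , drop = FALSE]),
                 referenceSD = sdRef, label = "calibration"),
    modelMetrics(scores$cup_score[split$val],
                 predict(model, Xs[split$val, , drop = FALSE]),
                 referenceSD = sdRef, label = "validation"))
  vip <- vipScores(model)
  out <- list(model = model, nLV = nLV, q2 = sel$q2, metrics = metrics,
              vip = vip,
              vipSelected = model@wavelengths[vip > 1],
              loadingSelected = influentialLoadings(model),
              split = split)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writePLSRModel(model, file.path(config$out_dir, "model.json"))
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(wavelength_nm = model@wavelengths, vip = unname(vip)),
      file.path(config$out_dir, "vip.csv"), row.names = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
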