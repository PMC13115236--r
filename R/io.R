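## File formats: tidy CSV for drying curves, transport tables and
## spectra matrices; ENVI header + binary raster pairs for cubes; JSON
## for portable PLSR models.

#' Read drying curves from CSV
#'
#' Expects columns `temperature_C, replicate, time_h, moisture_pct,
#' basis` (basis `wet` or `dry`), UTF-8 with header. One
#' [DryingCurve-class] is built per temperature x replicate.
#'
#' @param path CSV path.
#' @return Named list of [DryingCurve-class] objects
#'   (`"<temp>C_<replicate>"`).
#' @export
readDryingCurves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "replicate", "time_h", "moisture_pct", "basis")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  parts <- split(df, interaction(df$temperature_C, df$replicate, drop = TRUE))
  out <- lapply(parts, function(p) {
    p <- p[order(p$time_h), ]
    basis <- unique(p$basis)
    if (length(basis) != 1) stop("mixed basis within one curve")
    DryingCurve(p$temperature_C[1], p$time_h, p$moisture_pct,
                basis = basis, replicateId = as.character(p$replicate[1]))
  })
  names(out) <- vapply(parts, function(p)
    sprintf("%gC_%s", p$temperature_C[1], p$replicate[1]), character(1))
  out
}

#' Write transport parameters as a tidy CSV
#'
#' Columns `temperature_C, mu, d_eff_m2_s, biot, h_m_m_s, fit_mse`.
#'
#' @param params list of [TransportParams-class] (or a single one).
#' @param path output CSV path.
#' @return The data.frame written, invisibly.
#' @export
writeTransportTable <- function(params, path) {
  if (is(params, "TransportParams")) params <- list(params)
  df <- do.call(rbind, lapply(params, function(p)
    data.frame(temperature_C = temperature(p), mu = firstEigenvalue(p),
               d_eff_m2_s = effectiveDiffusivity(p), biot = biotNumber(p),
               h_m_m_s = massTransferCoef(p), fit_mse = p@fitMse)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read/write a spectra matrix CSV
#'
#' First column `sample_id`, remaining columns one per wavelength with
#' numeric headers in nm.
#'
#' @param path CSV path.
#' @return For the reader: list with `X` (samples x wavelengths
#'   matrix, rows named by sample id) and `wavelengths`.
#' @export
readSpectraMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop("first column must be 'sample_id'")
  wl <- as.numeric(names(df)[-1])
  if (anyNA(wl)) stop("wavelength headers must be numeric (nm)")
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$sample_id
  list(X = X, wavelengths = wl)
}

#' @rdname readSpectraMatrix
#' @param X samples x wavelengths matrix, rows named by sample id.
#' @param wavelengths column wavelengths (nm).
#' @export
writeSpectraMatrix <- function(X, wavelengths, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  names(df)[-1] <- as.character(wavelengths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

## ENVI data type codes <-> R read/write modes
.enviTypes <- list(`4` = list(what = "numeric", size = 4),
                   `5` = list(what = "numeric", size = 8))

#' Read an ENVI cube (header + binary pair)
#'
#' Supports BIL, BIP and BSQ interleaves and IEEE float (type 4) or
#' double (type 5) data; wavelengths are parsed from the `wavelength`
#' header field when present.
#'
#' @param hdrPath path to the `.hdr` header; the binary is the same
#'   path without the extension (or with `.dat`/`.raw`).
#' @return A [HyperCube-class] (raw; mark calibrated yourself if the
#'   file already holds corrected reflectance).
#' @export
readENVI <- function(hdrPath) {
  lines <- readLines(hdrPath, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  field <- function(name) {
    m <- regmatches(txt, regexpr(
      paste0("(?mi)^", name, "\\s*=\\s*([^\\{\\n]+)$"), txt, perl = TRUE))
    if (!length(m)) return(NA_character_)
    trimws(sub(".*=", "", m))
  }
  block <- function(name) {
    m <- regmatches(txt, regexpr(
      paste0("(?si)", name, "\\s*=\\s*\\{([^}]*)\\}"), txt, perl = TRUE))
    if (!length(m)) return(NULL)
    as.numeric(strsplit(gsub(".*\\{|\\}", "", m), ",")[[1]])
  }
  samples <- as.integer(field("samples"))   # width (columns)
  nlines <- as.integer(field("lines"))      # height (rows)
  bands <- as.integer(field("bands"))
  dtype <- as.character(as.integer(field("data type")))
  interleave <- tolower(field("interleave"))
  byteOrder <- as.integer(field("byte order"))
  if (is.na(byteOrder)) byteOrder <- 0L
  if (!dtype %in% names(.enviTypes))
    stop("unsupported ENVI data type ", dtype)
  spec <- .enviTypes[[dtype]]
  base <- sub("\\.hdr$", "", hdrPath, ignore.case = TRUE)
  binPath <- c(base, paste0(base, ".dat"), paste0(base, ".raw"))
  binPath <- binPath[file.exists(binPath)][1]
  if (is.na(binPath)) stop("binary file for ", hdrPath, " not found")
  n <- samples * nlines * bands
  vals <- readBin(binPath, what = spec$what, n = n, size = spec$size,
                  endian = if (byteOrder == 0) "little" else "big")
  if (length(vals) < n) stop("binary file shorter than header implies")
  ## ENVI stores row-major per line; map into H x W x B
  arr <- switch(interleave,
    bsq = aperm(array(vals, dim = c(samples, nlines, bands)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(samples, bands, nlines)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(bands, samples, nlines)), c(3, 2, 1)),
    stop("unsupported interleave ", interleave))
  wl <- block("wavelength")
  if (is.null(wl)) wl <- seq_len(bands)
  HyperCube(arr, wl)
}

#' @rdname readENVI
#' @param cube a [HyperCube-class].
#' @param basePath output path without extension; writes
#'   `<basePath>.hdr` and `<basePath>.dat`.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @export
writeENVI <- function(cube, basePath, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  dat <- cubeData(cube)
  d <- dim(dat)                              # H, W, B
  vals <- switch(interleave,
    bsq = as.vector(aperm(dat, c(2, 1, 3))),
    bil = as.vector(aperm(dat, c(2, 3, 1))),
    bip = as.vector(aperm(dat, c(3, 2, 1))))
  writeBin(vals, paste0(basePath, ".dat"), size = 8, endian = "little")
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("wavelength = {",
                  paste(format(wavelengths(cube), trim = TRUE),
                        collapse = ", "), "}"))
  writeLines(hdr, paste0(basePath, ".hdr"))
  invisible(basePath)
}

#' Serialize / restore a PLSR model as portable JSON
#'
#' Stores means, weights, loadings, scores-free regression vector,
#' component count and the wavelength grid.
#'
#' @param model a [PLSRModel-class].
#' @param path JSON path.
#' @return `readPLSRModel` returns the restored [PLSRModel-class];
#'   `writePLSRModel` the path, invisibly.
#' @export
writePLSRModel <- function(model, path) {
  stopifnot(is(model, "PLSRModel"))
  obj <- list(nLV = model@nLV, xMean = model@xMean, yMean = model@yMean,
              weights = model@weights, xLoadings = model@xLoadings,
              yLoadings = model@yLoadings, coef = model@coef,
              wavelengths = model@wavelengths)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePLSRModel
#' @export
readPLSRModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- as.integer(obj$nLV)
  p <- length(obj$xMean)
  new("PLSRModel", nLV = k, xMean = as.numeric(obj$xMean),
      yMean = as.numeric(obj$yMean),
      weights = matrix(as.numeric(obj$weights), p, k),
      xLoadings = matrix(as.numeric(obj$xLoadings), p, k),
      yLoadings = as.numeric(obj$yLoadings),
      scores = matrix(numeric(0), 0, k),
      coef = as.numeric(obj$coef), fitted = numeric(0),
      wavelengths = as.numeric(obj$wavelengths))
}
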