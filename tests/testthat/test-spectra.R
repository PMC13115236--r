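makeCube <- function(arr, wl = seq(400, 1000, length.out = dim(arr)[3]))
  HyperCube(arr, wl)

test_that("reflectance correction satisfies its fixed points and bounds", {
  d <- c(4, 5, 3)
  W <- array(0.9, d); D <- array(0.1, d)
  refs <- ReferenceFrames(W, D)
  expect_equal(unname(cubeData(correctReflectance(makeCube(W), refs))[1, 1, ]),
               rep(1, 3))
  expect_true(all(cubeData(correctReflectance(makeCube(D), refs)) == 0))
  expect_true(all(abs(cubeData(correctReflectance(
    makeCube((W + D) / 2), refs)) - 0.5) < 1e-12))
  ## any S between D and W lands in [0, 1]
  set.seed(42)
  S <- array(runif(prod(d), 0.1, 0.9), d)
  rc <- cubeData(correctReflectance(makeCube(S), refs))
  expect_true(all(rc >= 0 & rc <= 1))
  ## values below dark are clipped at zero, degenerate pixels masked
  S2 <- W; S2[1, 1, 1] <- 0.05
  W2 <- W; W2[2, 2, ] <- D[2, 2, ]
  rc2 <- cubeData(correctReflectance(makeCube(S2), ReferenceFrames(W2, D)))
  expect_equal(rc2[1, 1, 1], 0)
  expect_true(all(is.na(rc2[2, 2, ])))
})

test_that("line references broadcast across rows", {
  d <- c(6, 5, 4)
  refs <- ReferenceFrames(array(0.8, c(1, 5, 4)), array(0.2, c(1, 5, 4)))
  S <- array(0.5, d)
  rc <- correctReflectance(makeCube(S), refs)
  expect_true(all(abs(cubeData(rc) - 0.5) < 1e-12))
  bad <- ReferenceFrames(array(0.8, c(2, 5, 4)), array(0.2, c(2, 5, 4)))
  expect_error(correctReflectance(makeCube(S), bad), "broadcastable")
})

test_that("ROI segmentation recovers planted geometry via Otsu", {
  h <- 40; w <- 40; b <- 4
  disk <- outer((1:h - 20)^2, (1:w - 20)^2, "+") <= 8^2
  refl <- array(0.9, c(h, w, b))
  refl[array(disk, c(h, w, b))] <- 0.2
  cube <- HyperCube(refl, 1:b, calibrated = TRUE)
  mask <- segmentROI(cube)
  expect_equal(mask, disk, ignore_attr = TRUE)
  ## exact foreground fraction on a perfectly separable image
  m2 <- matrix(0.8, 10, 10); m2[1:30] <- 0.1
  cube2 <- HyperCube(array(m2, c(10, 10, 2)), 1:2, calibrated = TRUE)
  expect_equal(sum(segmentROI(cube2)), 30L)
  expect_equal(sum(segmentROI(cube2, invert = TRUE)), 70L)
  uni <- HyperCube(array(0.5, c(5, 5, 2)), 1:2, calibrated = TRUE)
  expect_error(segmentROI(uni), "uniform")
  raw <- HyperCube(array(0.5, c(5, 5, 2)), 1:2)
  expect_error(segmentROI(raw), "calibrated")
})

test_that("median profile matches a sort oracle and resists outliers", {
  arr <- array(0.5, c(3, 1, 2))
  arr[, 1, 1] <- c(0.1, 0.5, 0.9)
  cube <- HyperCube(arr, 1:2, calibrated = TRUE)
  mask <- matrix(TRUE, 3, 1)
  expect_equal(profileValues(medianProfile(cube, mask)), c(0.5, 0.5))
  ## one 10x outlier among 99 identical pixels changes nothing
  arr2 <- array(0.3, c(10, 10, 2)); arr2[1, 1, ] <- 3
  cube2 <- HyperCube(arr2, 1:2, calibrated = TRUE)
  expect_equal(profileValues(medianProfile(cube2, matrix(TRUE, 10, 10))),
               c(0.3, 0.3))
  ## brute-force per-band sort-and-middle on a random 5x5x4 cube
  set.seed(7)
  arr3 <- array(runif(100), c(5, 5, 4))
  mask3 <- matrix(sample(c(TRUE, FALSE), 25, replace = TRUE, c(0.6, 0.4)),
                  5, 5)
  cube3 <- HyperCube(arr3, 1:4, calibrated = TRUE)
  oracle <- sapply(1:4, function(k) {
    v <- sort(arr3[, , k][mask3])
    n <- length(v)
    if (n %% 2) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
  })
  expect_equal(profileValues(medianProfile(cube3, mask3)), oracle)
  ## permutation invariance over pixels (same multiset per band)
  perm <- sample(sum(mask3))
  arr4 <- arr3
  for (k in 1:4) {
    v <- arr3[, , k][mask3]
    tmp <- arr4[, , k]; tmp[mask3] <- v[perm]; arr4[, , k] <- tmp
  }
  expect_equal(profileValues(medianProfile(
    HyperCube(arr4, 1:4, calibrated = TRUE), mask3)), oracle)
  expect_error(medianProfile(cube3, matrix(FALSE, 5, 5)), "empty")
})

test_that("absorbance conversion is -log10 and inverts exactly", {
  p <- SpectralProfile(1:3, c(1, 0.1, 0.01), "reflectance")
  a <- toAbsorbance(p)
  expect_equal(profileValues(a), c(0, 1, 2))
  expect_equal(profileKind(a), "absorbance")
  set.seed(3)
  r <- runif(50, 1e-4, 1)
  back <- 10^(-profileValues(toAbsorbance(SpectralProfile(1:50, r,
                                                          "reflectance"))))
  expect_equal(back, r, tolerance = 1e-12)
  expect_warning(toAbsorbance(SpectralProfile(1:2, c(0, 0.5),
                                              "reflectance")), "floored")
  expect_error(toAbsorbance(SpectralProfile(1:2, c(0, 0), "reflectance")),
               "all-zero")
})

test_that("SG smoothing is exact on low-degree polynomials everywhere", {
  x <- seq_len(60)
  for (cfg in list(SGConfig(23, 2), SGConfig(11, 3))) {
    deg <- cfg@degree
    y <- 2 - 0.3 * x + 0.01 * x^2 + if (deg >= 3) 1e-4 * x^3 else 0
    expect_equal(sgSmooth(y, cfg), y, tolerance = 1e-9)
  }
  expect_equal(sgSmooth(rep(5, 30)), rep(5, 30))
  expect_error(sgSmooth(rnorm(10), SGConfig(23, 2)), "window exceeds")
})

test_that("SG interior agrees with the reference filter and a per-window fit", {
  skip_if_not_installed("signal")
  set.seed(9)
  y <- sin(seq(0, 6, length.out = 120)) + rnorm(120, 0, 0.1)
  ours <- sgSmooth(y, SGConfig(23, 2))
  ref <- signal::sgolayfilt(y, p = 2, n = 23)
  interior <- 12:(120 - 11)
  expect_equal(ours[interior], ref[interior], tolerance = 1e-10)
  ## direct least-squares oracle at a few points
  for (i in c(12, 40, 77, 109)) {
    j <- (i - 11):(i + 11)
    fit <- lm(y[j] ~ poly(j - i, 2, raw = TRUE))
    expect_equal(ours[i], unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("SG noise attenuation matches the projector variance factor", {
  cfg <- SGConfig(23, 2)
  ## theoretical factor: squared center row of the least-squares
  ## projector onto quadratics over the 23-point window
  X <- outer(-11:11, 0:2, "^")
  cc <- (X %*% solve(crossprod(X)) %*% t(X))[12, ]
  factor <- sum(cc^2)
  expect_lt(factor, 1)
  set.seed(123)
  n <- 1001
  vals <- replicate(200, {
    s <- sgSmooth(rnorm(n), cfg)
    s[12:(n - 11)]
  })
  expect_equal(mean(vals^2), factor, tolerance = 0.05)
})
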