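## Independent oracles used across test files.

## brute-force OLS by grid search over (slope, intercept)
gridOLS <- function(x, y, slopeRange, interceptRange, n = 201) {
  a <- seq(slopeRange[1], slopeRange[2], length.out = n)
  b <- seq(interceptRange[1], interceptRange[2], length.out = n)
  sse <- outer(a, b, Vectorize(function(ai, bi) sum((ai * x + bi - y)^2)))
  best <- arrayInd(which.min(sse), dim(sse))
  list(slope = a[best[1]], intercept = b[best[2]], sse = min(sse),
       stepA = diff(a[1:2]), stepB = diff(b[1:2]))
}

## printed drying-line coefficients per temperature (regression fixture)
tableCoefficients <- function() {
  read.csv(system.file("extdata", "drying_line_coefficients.csv",
                       package = "beandry"))
}

## printed transport parameters the coefficients should reproduce
tableTransport <- function() {
  data.frame(
    temperature_C = c(30, 40, 50, 60),
    mu = c(2.256442, 2.333156, 2.058683, 2.127121),
    d_eff = c(4.538592, 5.817569, 9.245937, 11.821655) * 1e-13,
    biot = c(2.845864, 3.228052, 2.092496, 2.322733),
    h_m = c(3.255095, 4.732716, 4.875778, 6.919997) * 1e-9)
}

## printed eigenvalue table: first six roots per Biot number
tableRoots <- function() {
  list(`2.8459` = c(2.2564, 5.0621, 8.0786, 11.1595, 14.2659, 17.3845),
       `3.2281` = c(2.3332, 5.1227, 8.1217, 11.1921, 14.2918, 17.4061),
       `2.0925` = c(2.0587, 4.9304, 7.9899, 11.0937, 14.2139, 17.3417),
       `2.3227` = c(2.1271, 4.9724, 8.0175, 11.1140, 14.2299, 17.3548))
}

## characteristic bean radius (m) reproducing the transport tables
RADIUS_L <- 3.968e-4
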