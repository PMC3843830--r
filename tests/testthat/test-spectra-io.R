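test_that("Spectrum validity rejects malformed inputs", {
  expect_error(Spectrum(c(300, 300, 301), c(1, 1, 1)), "strictly increasing")
  expect_error(Spectrum(300:302, c(1, -1, 1)), "non-negative")
  expect_error(Spectrum(300:302, c(1, 1)), "equal length")
  expect_error(Spectrum(300:301, c(1, 1), kind = "bogus"), "kind")
})

test_that("wide and long spectra files round-trip", {
  w <- 300:320
  vals <- data.frame(a = seq(0, 1, length.out = 21),
                     b = seq(1, 0, length.out = 21),
                     c = rep(0.5, 21))
  tf <- tempfile(fileext = ".csv")
  write.csv(cbind(wavelength_nm = w, vals), tf, row.names = FALSE)
  sp <- readSpectraTable(tf, layout = "wide")
  expect_length(sp, 3L)
  expect_named(sp, c("a", "b", "c"))
  expect_equal(intensities(sp$a), vals$a)
  expect_equal(wavelengths(sp$b), as.numeric(w))

  # two-column file -> single spectrum of matching length
  tf2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = w, t = vals$a), tf2, row.names = FALSE)
  expect_length(readSpectraTable(tf2, layout = "wide"), 1L)
  expect_length(readSpectraTable(tf2, layout = "wide")[[1]], 21L)

  tf3 <- tempfile(fileext = ".csv")
  long <- data.frame(series = rep(c("x", "y"), each = 21),
                     wavelength_nm = rep(w, 2),
                     value = c(vals$a, vals$b))
  write.csv(long, tf3, row.names = FALSE)
  sp3 <- readSpectraTable(tf3, layout = "long")
  expect_named(sp3, c("x", "y"))
  expect_equal(intensities(sp3$y), vals$b)
})

test_that("descending-wavelength files are reordered consistently", {
  w <- 300:320
  v <- seq(0, 1, length.out = 21)
  up <- tempfile(fileext = ".csv")
  down <- tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = w, t = v), up, row.names = FALSE)
  write.csv(data.frame(wavelength_nm = rev(w), t = rev(v)), down,
            row.names = FALSE)
  expect_equal(readSpectraTable(down)[[1]], readSpectraTable(up)[[1]])
})

test_that("readSpectraTable flags bad cells and duplicates", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,t", "300,0.1", "301,oops", "302,0.3"), tf)
  expect_error(readSpectraTable(tf), "row")
  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,t", "300,0.1", "300,0.2"), tf2)
  expect_error(readSpectraTable(tf2), "duplicate")
  expect_error(readSpectraTable(tempfile()), "not found")
})

test_that("percent input switch divides by 100", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = 300:302, t = c(10, 50, 90)), tf,
            row.names = FALSE)
  expect_equal(intensities(readSpectraTable(tf, percent = TRUE)[[1]]),
               c(0.1, 0.5, 0.9))
})

test_that("linear resampling matches a pointwise two-point oracle", {
  s <- Spectrum(c(300, 400), c(0, 1))
  expect_equal(intensities(resampleLinear(s, 350)), 0.5)
  expect_equal(resampleLinear(s, c(300, 400)), s)   # endpoints preserved

  set.seed(11)
  knots <- sort(runif(12, 300, 700))
  knots[1] <- 300; knots[12] <- 700
  sp <- Spectrum(knots, runif(12))
  grid <- sort(runif(200, 300, 700))
  got <- intensities(resampleLinear(sp, grid))
  oracle <- vapply(grid, function(g) {
    i <- max(which(knots <= g))
    if (i == length(knots)) return(intensities(sp)[i])
    x0 <- knots[i]; x1 <- knots[i + 1]
    y0 <- intensities(sp)[i]; y1 <- intensities(sp)[i + 1]
    y0 + (y1 - y0) * (g - x0) / (x1 - x0)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(resampleLinear(s, c(299, 350)), "extrapolate")
})

test_that("running average matches a brute-force windowed mean", {
  const <- Spectrum(300:400, rep(0.7, 101))
  expect_equal(smoothRunningAverage(const, 11), const)

  imp <- Spectrum(300:400, c(rep(0, 50), 1, rep(0, 50)))
  sm <- intensities(smoothRunningAverage(imp, 11))
  expect_equal(sm[46:56], rep(1 / 11, 11))
  expect_equal(sum(sm[46:56] > 0), 11L)

  set.seed(7)
  s <- randomSpectrum(81)
  v <- intensities(s)
  n <- length(v)
  for (window in c(1L, 5L, 11L)) {
    half <- (window - 1L) %/% 2L
    oracle <- vapply(seq_len(n), function(i) {
      r <- min(half, i - 1L, n - i)
      mean(v[(i - r):(i + r)])
    }, numeric(1))
    expect_equal(intensities(smoothRunningAverage(s, window)), oracle)
  }
  expect_error(smoothRunningAverage(s, 10), "odd")
  expect_error(smoothRunningAverage(s, 1001), "larger")
})

test_that("range normalisation scales the in-range maximum to 1", {
  s <- Spectrum(300:700, 0.8 * exp(-(300:700 - 650)^2 / 5000))
  ns <- normalizeToRangeMax(s)
  expect_equal(intensities(ns)[wavelengths(ns) == 650], 1)
  expect_equal(normalizeToRangeMax(ns), ns)   # idempotent

  # in-range max scaled to 1 even when the global max lies outside the range
  w <- 250:700
  v <- ifelse(w < 300, 2, 1 + (w - 300) / 400)   # global max 2 at 250-299
  s2 <- Spectrum(w, v)
  n2 <- normalizeToRangeMax(s2)
  expect_equal(max(intensities(n2)[w >= 300 & w <= 700]), 1)
  expect_equal(intensities(n2), v / 2)
  expect_true(any(intensities(n2)[w < 300] > 0.999))

  expect_error(normalizeToRangeMax(Spectrum(300:310, rep(0, 11))), "positive")
})

test_that("group averaging matches a per-wavelength loop oracle", {
  one <- randomSpectrum(31)
  avg1 <- averageSpectra(list(one))
  expect_equal(avg1$mean, one)
  expect_equal(intensities(avg1$sd), rep(0, 31))

  a <- Spectrum(300:310, rep(0.2, 11))
  b <- Spectrum(300:310, rep(0.4, 11))
  avg <- averageSpectra(list(a, b))
  expect_equal(intensities(avg$mean), rep(0.3, 11))
  expect_equal(intensities(avg$sd), rep(sd(c(0.2, 0.4)), 11))

  set.seed(21)
  grp <- replicate(5, randomSpectrum(41), simplify = FALSE)
  avg5 <- averageSpectra(grp)
  for (i in c(1, 20, 41)) {
    vals <- vapply(grp, function(s) intensities(s)[i], numeric(1))
    expect_equal(intensities(avg5$mean)[i], mean(vals))
    expect_equal(intensities(avg5$sd)[i], sd(vals))
  }
  expect_error(averageSpectra(list(a, randomSpectrum(41))), "grid")
})

test_that("wavelengthAtLevel finds interpolated crossings from the maximum", {
  ramp <- Spectrum(300:400, (0:100) / 100)
  expect_equal(wavelengthAtLevel(ramp, 0.5), 350)

  lgs <- logisticOmt(350, 5)
  expect_equal(wavelengthAtLevel(normalizeToRangeMax(lgs), 0.5), 350,
               tolerance = 0.01)

  # noisy sigmoid after smooth + normalise, against the dense-grid oracle
  set.seed(5)
  noisy <- Spectrum(300:700,
                    pmax(1 / (1 + exp(-(300:700 - 340) / 6)) +
                           rnorm(401, 0, 0.01), 0))
  proc <- normalizeToRangeMax(smoothRunningAverage(noisy, 11))
  expect_equal(wavelengthAtLevel(proc, 0.5),
               denseCrossingOracle(proc, 0.5), tolerance = 0.1)

  expect_error(wavelengthAtLevel(ramp, 1.5), "level")
  expect_error(wavelengthAtLevel(Spectrum(300:310, rep(1, 11)), 0.5),
               "not attained")
})

test_that("crossing metrics are invariant under uniform scaling of raw values", {
  set.seed(9)
  raw <- Spectrum(300:700,
                  pmax(0.8 / (1 + exp(-(300:700 - 355) / 7)) +
                         rnorm(401, 0, 0.005), 0))
  pipeline <- function(s) {
    wavelengthAtLevel(normalizeToRangeMax(smoothRunningAverage(s, 11)), 0.5)
  }
  scaled <- Spectrum(wavelengths(raw), intensities(raw) * 37.5)
  expect_equal(pipeline(raw), pipeline(scaled), tolerance = 1e-9)
})

test_that("wavelengthAtLevel is monotone in level for monotone spectra", {
  lgs <- normalizeToRangeMax(logisticOmt(360, 8))
  lv <- seq(0.1, 0.9, by = 0.1)
  xs <- vapply(lv, function(l) wavelengthAtLevel(lgs, l), numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("cutoff slopes: ramp, interval count, and integration-back", {
  ramp <- Spectrum(300:400, (0:100) / 100)
  cs <- cutoffSlopes(ramp)
  expect_equal(nrow(cs), 20L)
  expect_equal(cs$slope, rep(0.01, 20), tolerance = 1e-9)

  lgs <- normalizeToRangeMax(logisticOmt(350, 8))
  cl <- cutoffSlopes(lgs)
  # slope maximal in the interval containing the 50% crossing (logistic
  # derivative peaks at the midpoint)
  mid <- which(cl$level_lo <= 0.5 & cl$level_hi > 0.5)
  # the logistic derivative peaks at the midpoint, so the steepest interval
  # is the one containing the 50% crossing or its mirror-symmetric neighbour
  expect_true(which.max(cl$slope) %in% c(mid - 1L, mid))
  # analytic check: max logistic slope is plateau/(4 s); interval average
  # slightly below (unattained bottom levels are NA by design)
  expect_lt(max(cl$slope, na.rm = TRUE), 1 / (4 * 8))
  expect_gt(max(cl$slope, na.rm = TRUE), 0.9 / (4 * 8))

  # integration-back where all levels attained
  attained <- is.finite(cs$slope)
  expect_equal(sum(0.05 / cs$slope[attained]),
               max(cs$lambda_hi, na.rm = TRUE) - min(cs$lambda_lo, na.rm = TRUE))

  expect_error(cutoffSlopes(logisticOmt(350, 8, plateau = 0.8)), "normalised")
})

test_that("retinal UV fraction: bounds, fine-grid oracle, monotonicity", {
  grid <- 300:700
  flat <- Spectrum(grid, rep(1, 401), kind = "illuminant-photon")
  expect_equal(retinalUvFraction(Spectrum(grid, rep(1, 401)), flat), 1)

  opaque <- Spectrum(grid, ifelse(grid <= 400, 0, 1))
  expect_equal(retinalUvFraction(opaque, flat), 0)

  lgs <- logisticOmt(350, 5)
  got <- retinalUvFraction(lgs, flat)
  fine <- seq(300, 400, by = 0.01)
  oracle <- pracma::trapz(fine, 1 / (1 + exp(-(fine - 350) / 5))) /
    pracma::trapz(fine, rep(1, length(fine)))
  expect_equal(got, oracle, tolerance = 1e-6)

  d65 <- standardIlluminantD65(grid)
  fr <- vapply(seq(320, 400, by = 10), function(l50) {
    retinalUvFraction(logisticOmt(l50, 6), d65)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_error(retinalUvFraction(lgs, standardIlluminantD65(300:500)), "grid")
})
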