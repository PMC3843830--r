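#' @include AllClasses.R
NULL

#' Read spectra from a delimited text file
#'
#' Reads transmittance (or other) spectra from CSV/TSV files in either a wide
#' layout (first column the wavelength in nm, one value column per spectrum)
#' or a long layout (columns `series`, `wavelength_nm`, `value`).
#'
#' @param path path to a delimited text file. The delimiter is taken from the
#'   extension (`.tsv`/`.txt` tab, otherwise comma).
#' @param layout `"wide"` or `"long"`.
#' @param kind spectral kind assigned to the result, see [Spectrum-class].
#' @param percent if `TRUE`, values are percentages and are divided by 100 on
#'   input.
#' @return A named list of [Spectrum-class] objects, wavelengths ascending.
#' @details Duplicate wavelengths within one series are an error, as are
#'   non-numeric wavelength or value cells (reported with their row number).
#'   Files stored with descending wavelengths are reordered ascending.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(wavelength_nm = 300:310, a = runif(11), b = runif(11)),
#'           tf, row.names = FALSE)
#' sp <- readSpectraTable(tf, layout = "wide")
#' names(sp)
#' @export
readSpectraTable <- function(path, layout = c("wide", "long"),
                             kind = "transmittance", percent = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("need at least two columns", call. = FALSE)

  asNum <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & trimws(as.character(x)) != "")
    bad <- c(bad, which(is.na(x)))
    if (length(bad)) {
      stop(sprintf("non-numeric %s in row(s) %s", what,
                   paste(sort(unique(bad))[1:min(5, length(bad))],
                         collapse = ", ")), call. = FALSE)
    }
    out
  }

  buildOne <- function(w, v, nm) {
    if (anyDuplicated(w)) {
      stop("duplicate wavelengths in series '", nm, "'", call. = FALSE)
    }
    o <- order(w)
    Spectrum(w[o], if (percent) v[o] / 100 else v[o], kind = kind)
  }

  if (layout == "wide") {
    w <- asNum(raw[[1]], "wavelength cell")
    out <- lapply(seq.int(2L, ncol(raw)), function(j) {
      buildOne(w, asNum(raw[[j]], paste0("value cell in column '",
                                         names(raw)[j], "'")),
               names(raw)[j])
    })
    names(out) <- names(raw)[-1]
  } else {
    need <- c("series", "wavelength_nm", "value")
    cols <- if (all(need %in% names(raw))) raw[need] else raw[, 1:3]
    w <- asNum(cols[[2]], "wavelength cell")
    v <- asNum(cols[[3]], "value cell")
    keys <- as.character(cols[[1]])
    out <- lapply(split(seq_along(keys), keys),
                  function(idx) buildOne(w[idx], v[idx], keys[idx[1]]))
  }
  out
}

#' Linearly resample a spectrum onto a new grid
#'
#' @param s a [Spectrum-class].
#' @param grid target wavelengths (nm), strictly increasing, within the span
#'   of `s` (no extrapolation).
#' @return A [Spectrum-class] on `grid`.
#' @examples
#' s <- Spectrum(c(300, 400), c(0, 1))
#' intensities(resampleLinear(s, 350))   # 0.5
#' @export
resampleLinear <- function(s, grid) {
  w <- wavelengths(s)
  grid <- as.numeric(grid)
  if (min(grid) < min(w) - 1e-9 || max(grid) > max(w) + 1e-9) {
    stop("grid extends beyond the span of the spectrum; refusing to extrapolate",
         call. = FALSE)
  }
  v <- approx(w, intensities(s), xout = grid, method = "linear",
              ties = "ordered")$y
  Spectrum(grid, v, kind = spectrumKind(s))
}

#' Centred running-average smoothing
#'
#' Smooths a spectrum with a centred moving mean of odd width (default 11
#' samples, i.e. 11 nm on a 1 nm grid). Near the edges the window shrinks
#' symmetrically so the output has the same length as the input and endpoint
#' values are approximately preserved.
#'
#' @param s a [Spectrum-class].
#' @param window odd window width in samples, `>= 1`, `<=` length of `s`.
#' @return A smoothed [Spectrum-class].
#' @export
smoothRunningAverage <- function(s, window = 11L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  v <- intensities(s)
  n <- length(v)
  if (window > n) stop("window larger than spectrum", call. = FALSE)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  out <- vapply(seq_len(n), function(i) {
    r <- min(half, i - 1L, n - i)
    (cs[i + r + 1L] - cs[i - r]) / (2L * r + 1L)
  }, numeric(1))
  Spectrum(wavelengths(s), out, kind = spectrumKind(s))
}

#' Normalise a spectrum to its maximum within a wavelength range
#'
#' Divides all values by the maximum attained within `[lo, hi]` (default
#' 300–700 nm), so the in-range maximum becomes exactly 1. Values outside the
#' range may exceed 1 if the global maximum lies outside it.
#'
#' @param s a [Spectrum-class].
#' @param lo,hi normalisation range in nm.
#' @return A [Spectrum-class] with in-range maximum 1.
#' @export
normalizeToRangeMax <- function(s, lo = 300, hi = 700) {
  w <- wavelengths(s)
  inr <- w >= lo & w <= hi
  if (!any(inr)) stop("no samples within the normalisation range", call. = FALSE)
  m <- max(intensities(s)[inr])
  if (m <= 0) stop("maximum within range is not positive", call. = FALSE)
  Spectrum(w, intensities(s) / m, kind = spectrumKind(s))
}

#' Pointwise mean and standard deviation of a group of spectra
#'
#' @param group a list of [Spectrum-class] objects on identical grids.
#' @return A list with elements `mean` and `sd`, both [Spectrum-class]
#'   objects. The sd uses the sample (n-1) denominator and is a zero spectrum
#'   when `group` has a single member.
#' @export
averageSpectra <- function(group) {
  if (!length(group)) stop("need at least one spectrum", call. = FALSE)
  ref <- group[[1]]
  for (s in group[-1]) .stopIfGridMismatch(ref, s)
  mat <- vapply(group, intensities, numeric(length(ref)))
  mat <- matrix(mat, nrow = length(ref))
  mu <- rowMeans(mat)
  sdv <- if (ncol(mat) == 1L) rep(0, nrow(mat)) else apply(mat, 1L, sd)
  list(mean = Spectrum(wavelengths(ref), mu, kind = spectrumKind(ref)),
       sd = Spectrum(wavelengths(ref), sdv, kind = spectrumKind(ref)))
}

# downward scan from the in-range maximum for the first crossing of `level`;
# returns the linearly interpolated wavelength, or NA when the level is never
# attained. `level` may be 0 or 1 (used by cutoffSlopes); exported wrapper
# restricts to (0, 1).
.crossingFromMax <- function(w, v, level, lo, hi) {
  inr <- which(w >= lo & w <= hi)
  imax <- inr[which.max(v[inr])]
  if (level >= v[imax]) {
    # the maximum itself is the only point attaining the top level
    return(if (abs(level - v[imax]) <= 1e-12) w[imax] else NA_real_)
  }
  if (imax == 1L) return(NA_real_)
  for (j in seq.int(imax - 1L, 1L)) {
    if (v[j] <= level) {
      if (v[j] == level) return(w[j])
      # crossing between j and j+1 (v[j] < level <= v[j+1])
      return(w[j] + (level - v[j]) / (v[j + 1L] - v[j]) * (w[j + 1L] - w[j]))
    }
  }
  NA_real_
}

#' Wavelength at which a spectrum crosses a transmittance level
#'
#' Scanning downward in wavelength from the in-range maximum, returns the
#' linearly interpolated wavelength of the first crossing of `level`. For a
#' normalised ocular media transmittance curve,
#' `wavelengthAtLevel(s, 0.5)` is the UV-transparency indicator
#' \eqn{\lambda_{T0.5}}: the wavelength at which half of the light incident
#' on the cornea reaches the retina.
#'
#' @param s a [Spectrum-class], normally smoothed and normalised first.
#' @param level level in (0, 1).
#' @param lo,hi range (nm) within which the maximum is located.
#' @return Wavelength in nm.
#' @examples
#' ramp <- Spectrum(300:400, (0:100) / 100)
#' wavelengthAtLevel(ramp, 0.5)   # 350
#' @export
wavelengthAtLevel <- function(s, level = 0.5, lo = 300, hi = 700) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  out <- .crossingFromMax(wavelengths(s), intensities(s), level, lo, hi)
  if (is.na(out)) stop("level not attained", call. = FALSE)
  out
}

#' Cut-off slopes per 5% transmittance interval
#'
#' Characterises the steepness of a normalised transmittance cut-off by the
#' average slope within each of the 20 intervals `[k*5%, (k+1)*5%)` between 0
#' and 100% transmittance: `0.05 / (lambda(hi) - lambda(lo))`, in
#' transmittance fraction per nm. Crossing wavelengths are obtained by the
#' same downward scan as [wavelengthAtLevel()]; intervals with an unattained
#' bounding level are `NA`.
#'
#' @param s a normalised [Spectrum-class] (in-range maximum 1).
#' @param lo,hi range (nm) within which the maximum is located.
#' @return A data.frame with 20 rows: `level_lo`, `level_hi`, `lambda_lo`,
#'   `lambda_hi` (nm) and `slope` (fraction per nm).
#' @examples
#' ramp <- Spectrum(300:400, (0:100) / 100)
#' all.equal(cutoffSlopes(ramp)$slope, rep(0.01, 20))
#' @export
cutoffSlopes <- function(s, lo = 300, hi = 700) {
  w <- wavelengths(s)
  v <- intensities(s)
  inr <- w >= lo & w <= hi
  if (abs(max(v[inr]) - 1) > 1e-6) {
    stop("spectrum must be normalised (in-range maximum 1); see normalizeToRangeMax()",
         call. = FALSE)
  }
  levels <- seq(0, 1, by = 0.05)
  lam <- vapply(levels, function(lv) .crossingFromMax(w, v, lv, lo, hi),
                numeric(1))
  k <- seq_len(20L)
  data.frame(level_lo = levels[k], level_hi = levels[k + 1L],
             lambda_lo = lam[k], lambda_hi = lam[k + 1L],
             slope = 0.05 / (lam[k + 1L] - lam[k]))
}

#' Fraction of UV photons transmitted to the retina
#'
#' The number of 300–400 nm photons reaching the retina under a given
#' illuminant, relative to the number incident on the cornea:
#' \deqn{\int_{300}^{400} I(\lambda) T(\lambda)\,d\lambda \Big/
#'       \int_{300}^{400} I(\lambda)\,d\lambda}
#' with trapezoid integration on the shared grid. For a D65 daylight photon
#' spectrum this is the retinal UV irradiance metric that decreases with
#' increasing \eqn{\lambda_{T0.5}}.
#'
#' @param omt normalised transmittance [Spectrum-class].
#' @param illum illuminant [Spectrum-class] in photon units, same grid.
#' @param lo,hi integration bounds in nm (default 300–400).
#' @return Fraction in `[0, 1]`.
#' @export
retinalUvFraction <- function(omt, illum, lo = 300, hi = 400) {
  .stopIfGridMismatch(omt, illum)
  w <- wavelengths(omt)
  sel <- w >= lo & w <= hi
  if (sum(sel) < 2L) stop("need at least two samples in the UV band", call. = FALSE)
  num <- .trapz(w[sel], intensities(omt)[sel] * intensities(illum)[sel])
  den <- .trapz(w[sel], intensities(illum)[sel])
  num / den
}
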