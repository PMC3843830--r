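#' @include visual-system.R
NULL

#' Quantum catches of a visual system
#'
#' Photon signal of each receptor channel for a reflecting surface under an
#' illuminant:
#' \deqn{q_i = \int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, d\lambda}
#' with trapezoid integration on the shared grid (300–700 nm by default
#' construction). A channel with zero catch is an error: its log-contrast is
#' undefined and the channel is effectively blind to the stimulus.
#'
#' @param system a [VisualSystem-class].
#' @param reflectance reflectance [Spectrum-class].
#' @param illum illuminant [Spectrum-class] in photon units.
#' @return Named numeric vector of positive catches, one per channel.
#' @export
quantumCatches <- function(system, reflectance, illum) {
  .stopIfGridMismatch(reflectance, illum)
  w <- wavelengths(reflectance)
  ri <- intensities(reflectance) * intensities(illum)
  sens <- channelSensitivities(system)
  q <- vapply(sens, function(s) {
    .stopIfGridMismatch(s, reflectance, "sensitivity and stimulus spectra")
    .trapz(w, ri * intensities(s))
  }, numeric(1))
  names(q) <- channelNames(system)
  if (any(q <= 0)) {
    stop("channel blind to stimulus: zero quantum catch in ",
         paste(names(q)[q <= 0], collapse = ", "), call. = FALSE)
  }
  q
}

#' Receptor-noise-limited colour distance
#'
#' Chromatic distance (in just-noticeable differences, JND) between two
#' quantum-catch vectors under the receptor-noise-limited model. With
#' log-contrasts \eqn{\Delta f_i = \ln(q_i^a / q_i^b)} and channel noise
#' \eqn{e_i},
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\Delta f_i - \Delta f_j)^2
#'       \prod_{k \notin \{i,j\}} e_k^2}{\sum_i \prod_{k \ne i} e_k^2},}
#' the general-n form that reduces to the familiar di-, tri- and
#' tetrachromatic expressions. \eqn{\Delta S = 1} is the discrimination
#' threshold.
#'
#' @param system a [VisualSystem-class], or directly a numeric vector of
#'   per-channel noise values \eqn{e_i}.
#' @param catchesA,catchesB positive quantum-catch vectors, one value per
#'   channel.
#' @return Distance in JND units.
#' @examples
#' deltaS(c(0.1, 0.1), c(1.1, 1), c(1, 1))   # ~0.674
#' @export
deltaS <- function(system, catchesA, catchesB) {
  e <- if (is.numeric(system)) system else channelNoise(system)
  n <- length(e)
  if (n < 2L) stop("need at least two channels", call. = FALSE)
  if (length(catchesA) != n || length(catchesB) != n) {
    stop("catch vectors must have one value per channel", call. = FALSE)
  }
  if (any(catchesA <= 0) || any(catchesB <= 0)) {
    stop("quantum catches must be positive", call. = FALSE)
  }
  df <- log(catchesA) - log(catchesB)
  e2 <- e^2
  num <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      num <- num + (df[i] - df[j])^2 * prod(e2[-c(i, j)])
    }
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e2[-i]), numeric(1)))
  sqrt(num / den)
}

#' Build a double-Gaussian reflectance spectrum
#'
#' Realises a [StimulusSpec-class] on a wavelength grid:
#' \deqn{R(\lambda) = b + A_{uv}\, g(\lambda; \mu_{uv}, w_{uv}) +
#'       A_{long}\, g(\lambda; \mu_{long}, w_{long}),}
#' where `g` is a unit-height Gaussian parameterised by its full width at
#' half maximum.
#'
#' @param spec a [StimulusSpec-class].
#' @param grid wavelength grid in nm.
#' @return A reflectance [Spectrum-class].
#' @export
makeStimulus <- function(spec, grid = 300:700) {
  grid <- as.numeric(grid)
  if (spec@uvPeak < min(grid) || spec@uvPeak > max(grid) ||
      spec@longPeak < min(grid) || spec@longPeak > max(grid)) {
    stop("stimulus peaks must lie within the grid", call. = FALSE)
  }
  g <- function(mu, fwhm) {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-(grid - mu)^2 / (2 * sigma^2))
  }
  v <- spec@baseline + spec@uvAmplitude * g(spec@uvPeak, spec@uvFwhm) +
    spec@longAmplitude * g(spec@longPeak, spec@longFwhm)
  Spectrum(grid, v, kind = "reflectance")
}

#' Discrimination threshold for reducing a UV peak
#'
#' Decreases the amplitude of the stimulus UV peak in 1% steps and returns
#' the smallest reduction (in percent) at which the colour contrast between
#' the original and the reduced stimulus exceeds 1 JND. A threshold that
#' would require removing the whole peak (100%) is taken to mark the limit of
#' no discrimination and is reported as such.
#'
#' Quantum catches are linear in the UV amplitude, so catches for each
#' reduction step are obtained exactly by interpolating between the full
#' stimulus and the peak-free stimulus.
#'
#' @param system a [VisualSystem-class].
#' @param spec a [StimulusSpec-class].
#' @param illum illuminant [Spectrum-class] in photon units; its grid is the
#'   computation grid.
#' @return Integer threshold percent in `1..100`, or `NA` when even full
#'   removal stays below 1 JND. Use [discriminationLimit()] / the
#'   `discriminable` column of [thresholdSweep()] for the "100% = no
#'   discrimination" convention.
#' @export
discriminationThreshold <- function(system, spec, illum) {
  grid <- wavelengths(illum)
  qFull <- quantumCatches(system, makeStimulus(spec, grid), illum)
  spec0 <- spec
  spec0@uvAmplitude <- 0
  q0 <- quantumCatches(system, makeStimulus(spec0, grid), illum)
  for (k in seq_len(100L)) {
    qk <- q0 + (1 - k / 100) * (qFull - q0)
    if (deltaS(system, qFull, qk) > 1) return(k)
  }
  NA_integer_
}

#' Threshold sweep across UV peak positions
#'
#' Runs [discriminationThreshold()] for UV peaks at each nanometre of
#' `uvRange`, shifting the long-wavelength peak along with the UV peak at a
#' fixed offset (200 nm by default, anchored at the 320/520 nm initial pair).
#'
#' @param system a [VisualSystem-class].
#' @param baseSpec a [StimulusSpec-class]; its peak positions are overridden
#'   per sweep point, all other parameters are kept.
#' @param illum illuminant [Spectrum-class] in photon units.
#' @param uvRange UV peak positions in nm (default `320:420`).
#' @param longOffset offset of the long-wavelength peak from the UV peak, nm.
#' @return A threshold-curve data.frame with columns `uv_peak_nm`,
#'   `threshold_percent` (`NA` when nothing is discriminable) and
#'   `discriminable` (`TRUE` when the threshold exists and is below 100%).
#' @export
thresholdSweep <- function(system, baseSpec = stimulusSpec(), illum,
                           uvRange = 320:420, longOffset = 200) {
  th <- vapply(uvRange, function(p) {
    sp <- baseSpec
    sp@uvPeak <- p
    sp@longPeak <- p + longOffset
    discriminationThreshold(system, sp, illum)
  }, integer(1))
  data.frame(uv_peak_nm = as.numeric(uvRange), threshold_percent = th,
             discriminable = !is.na(th) & th < 100L)
}

#' Short-wavelength discrimination limit of a threshold curve
#'
#' @param curve a threshold-curve data.frame from [thresholdSweep()].
#' @return The smallest `uv_peak_nm` at which amplitude differences are
#'   discriminable (threshold below 100%), or `NA` when none is.
#' @export
discriminationLimit <- function(curve) {
  if (!nrow(curve)) stop("empty threshold curve", call. = FALSE)
  ok <- curve$uv_peak_nm[curve$discriminable]
  if (!length(ok)) NA_real_ else min(ok)
}
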