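#' @include utils.R
NULL

.SPECTRUM_KINDS <- c("transmittance", "reflectance", "sensitivity",
                     "illuminant-photon", "illuminant-energy")

#' Spectrum: a sampled function of wavelength
#'
#' Container for any 1-D spectral quantity used in the package: ocular media
#' transmittance, reflectance, receptor sensitivity, or an illuminant in
#' photon or energy units. Wavelengths are in nanometres and must be strictly
#' increasing; values are unitless, finite and non-negative.
#'
#' @slot wavelength numeric, strictly increasing, nm.
#' @slot value numeric, same length as `wavelength`, finite and `>= 0`.
#' @slot kind one of `"transmittance"`, `"reflectance"`, `"sensitivity"`,
#'   `"illuminant-photon"`, `"illuminant-energy"`.
#'
#' @seealso [Spectrum()] for the user constructor, [wavelengths()],
#'   [intensities()], [spectrumKind()] for accessors.
#' @name Spectrum-class
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  slots = c(wavelength = "numeric", value = "numeric", kind = "character"),
  prototype = prototype(wavelength = numeric(), value = numeric(),
                        kind = "transmittance"))

setValidity("Spectrum", function(object) {
  w <- object@wavelength
  v <- object@value
  msgs <- character()
  if (length(w) != length(v)) {
    msgs <- c(msgs, "wavelength and value must have equal length")
  }
  if (length(w) && any(!is.finite(w))) {
    msgs <- c(msgs, "wavelengths must be finite")
  }
  if (length(w) > 1 && any(diff(w) <= 0)) {
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  }
  if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
    msgs <- c(msgs, "values must be finite and non-negative")
  }
  if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS) {
    msgs <- c(msgs, paste0("kind must be one of: ",
                           paste(.SPECTRUM_KINDS, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Spectrum
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly increasing.
#' @param value numeric vector of non-negative values, same length.
#' @param kind spectral kind, see [Spectrum-class].
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(300:700, rep(1, 401), "transmittance")
#' wavelengths(s)[1:3]
#' @export
Spectrum <- function(wavelength, value, kind = "transmittance") {
  new("Spectrum", wavelength = as.numeric(wavelength),
      value = as.numeric(value), kind = kind)
}

#' Accessors for Spectrum objects
#'
#' `wavelengths()` returns the wavelength grid (nm), `intensities()` the
#' sampled values, `spectrumKind()` the spectral kind.
#'
#' @param x a [Spectrum-class].
#' @return numeric vector (or character scalar for `spectrumKind`).
#' @name Spectrum-accessors
#' @aliases wavelengths intensities spectrumKind
NULL

#' @rdname Spectrum-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("spectrumKind", function(x) standardGeneric("spectrumKind"))

#' @rdname Spectrum-accessors
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)

#' @rdname Spectrum-accessors
setMethod("intensities", "Spectrum", function(x) x@value)

#' @rdname Spectrum-accessors
setMethod("spectrumKind", "Spectrum", function(x) x@kind)

setMethod("show", "Spectrum", function(object) {
  w <- object@wavelength
  cat(sprintf("Spectrum (%s): %d samples", object@kind, length(w)))
  if (length(w)) {
    cat(sprintf(", %.6g-%.6g nm, value range [%.4g, %.4g]",
                min(w), max(w), min(object@value), max(object@value)))
  }
  cat("\n")
  invisible(NULL)
})

#' @export
setMethod("length", "Spectrum", function(x) length(x@wavelength))

#' ReceptorChannel: one cone class of a visual system
#'
#' A receptor channel couples a pigment peak wavelength with its relative
#' abundance in the retina and the effective (ocular-media screened)
#' sensitivity spectrum.
#'
#' @slot name channel label, e.g. `"sws1"`, `"sws2"`, `"mws"`, `"lws"`.
#' @slot lambdaMax pigment absorbance peak, nm.
#' @slot abundance relative channel abundance (eta), `> 0`.
#' @slot sensitivity a [Spectrum-class] of kind `"sensitivity"`.
#' @name ReceptorChannel-class
#' @exportClass ReceptorChannel
setClass("ReceptorChannel",
  slots = c(name = "character", lambdaMax = "numeric",
            abundance = "numeric", sensitivity = "Spectrum"))

setValidity("ReceptorChannel", function(object) {
  msgs <- character()
  if (length(object@abundance) != 1L || !is.finite(object@abundance) ||
      object@abundance <= 0) {
    msgs <- c(msgs, "abundance must be a single positive number")
  }
  if (length(object@lambdaMax) != 1L || !is.finite(object@lambdaMax)) {
    msgs <- c(msgs, "lambdaMax must be a single finite number")
  }
  if (length(msgs)) msgs else TRUE
})

#' VisualSystem: receptor channels plus receptor noise
#'
#' An ordered set of 2–4 receptor channels with per-channel noise for the
#' receptor-noise-limited (RNL) colour discrimination model. Channel noise is
#' tied to abundance by \eqn{e_i = \nu \sqrt{\eta_{ref}/\eta_i}}, where
#' \eqn{\eta_{ref}} is the largest abundance, so the most abundant channel has
#' noise equal to the Weber fraction \eqn{\nu}. This is the bright-light
#' (Weber) regime: noise is independent of intensity.
#'
#' @slot channels list of [ReceptorChannel-class] objects, in fixed order.
#' @slot weberFraction Weber fraction \eqn{\nu} of the most abundant channel.
#' @slot noise numeric vector of per-channel noise \eqn{e_i}, `> 0`.
#' @seealso [buildVisualSystem()], [deltaS()], [quantumCatches()].
#' @name VisualSystem-class
#' @exportClass VisualSystem
setClass("VisualSystem",
  slots = c(channels = "list", weberFraction = "numeric", noise = "numeric"))

setValidity("VisualSystem", function(object) {
  msgs <- character()
  nch <- length(object@channels)
  if (nch < 2L || nch > 4L) {
    msgs <- c(msgs, "a visual system needs 2-4 channels")
  }
  if (!all(vapply(object@channels, is, logical(1), class2 = "ReceptorChannel"))) {
    msgs <- c(msgs, "channels must all be ReceptorChannel objects")
  }
  if (length(object@noise) != nch || any(!is.finite(object@noise)) ||
      any(object@noise <= 0)) {
    msgs <- c(msgs, "noise must be positive, one value per channel")
  }
  if (length(object@weberFraction) != 1L || object@weberFraction <= 0) {
    msgs <- c(msgs, "weberFraction must be a single positive number")
  }
  if (nch >= 2L && !length(msgs)) {
    eta <- vapply(object@channels, function(ch) ch@abundance, numeric(1))
    expected <- object@weberFraction * sqrt(max(eta) / eta)
    if (any(abs(object@noise - expected) > 1e-8)) {
      msgs <- c(msgs, "noise must equal weberFraction * sqrt(eta_ref / eta)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "VisualSystem", function(object) {
  cat(sprintf("VisualSystem: %d channels, Weber fraction %.3g\n",
              length(object@channels), object@weberFraction))
  for (i in seq_along(object@channels)) {
    ch <- object@channels[[i]]
    cat(sprintf("  %-6s lambda_max %.0f nm  eta %.3g  e_i %.4g\n",
                ch@name, ch@lambdaMax, ch@abundance, object@noise[i]))
  }
  invisible(NULL)
})

#' Accessors for VisualSystem objects
#'
#' `channelNames()`, `channelNoise()` and `channelSensitivities()` return the
#' channel labels, the per-channel RNL noise values \eqn{e_i}, and the list of
#' screened sensitivity [Spectrum-class] objects.
#'
#' @param x a [VisualSystem-class].
#' @name VisualSystem-accessors
#' @aliases channelNames channelNoise channelSensitivities
NULL

#' @rdname VisualSystem-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname VisualSystem-accessors
#' @export
setGeneric("channelNoise", function(x) standardGeneric("channelNoise"))

#' @rdname VisualSystem-accessors
#' @export
setGeneric("channelSensitivities", function(x) standardGeneric("channelSensitivities"))

#' @rdname VisualSystem-accessors
setMethod("channelNames", "VisualSystem", function(x)
  vapply(x@channels, function(ch) ch@name, character(1)))

#' @rdname VisualSystem-accessors
setMethod("channelNoise", "VisualSystem", function(x) x@noise)

#' @rdname VisualSystem-accessors
setMethod("channelSensitivities", "VisualSystem", function(x)
  lapply(x@channels, function(ch) ch@sensitivity))

#' StimulusSpec: a double-Gaussian reflectance stimulus
#'
#' Parameters of the model reflectance spectra used in the discrimination
#' analysis: a constant baseline plus two unit-height-scaled Gaussian peaks,
#' one in the UV and one at longer wavelength. The default geometry (narrow
#' 36 nm-FWHM UV peak at 320 nm, broader peak at 520 nm) mimics a green
#' parrot breast patch with a strong UV component.
#'
#' @slot uvPeak,uvAmplitude,uvFwhm UV peak position (nm), amplitude
#'   (reflectance units) and full width at half maximum (nm).
#' @slot longPeak,longAmplitude,longFwhm the long-wavelength peak.
#' @slot baseline constant baseline reflectance, `> 0`.
#' @seealso [stimulusSpec()], [makeStimulus()].
#' @name StimulusSpec-class
#' @exportClass StimulusSpec
setClass("StimulusSpec",
  slots = c(uvPeak = "numeric", uvAmplitude = "numeric", uvFwhm = "numeric",
            longPeak = "numeric", longAmplitude = "numeric",
            longFwhm = "numeric", baseline = "numeric"))

setValidity("StimulusSpec", function(object) {
  msgs <- character()
  amps <- c(object@uvAmplitude, object@longAmplitude)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    msgs <- c(msgs, "amplitudes must be finite and >= 0")
  }
  if (object@uvFwhm <= 0 || object@longFwhm <= 0) {
    msgs <- c(msgs, "FWHM values must be > 0")
  }
  if (object@baseline <= 0) {
    msgs <- c(msgs, "baseline must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StimulusSpec
#'
#' @param uvPeak,uvAmplitude,uvFwhm UV Gaussian peak position (nm), amplitude
#'   and FWHM (nm).
#' @param longPeak,longAmplitude,longFwhm long-wavelength Gaussian peak.
#' @param baseline constant baseline reflectance (`> 0`).
#' @return A [StimulusSpec-class].
#' @examples
#' stimulusSpec(uvPeak = 320, uvFwhm = 36)
#' @export
stimulusSpec <- function(uvPeak = 320, uvAmplitude = 0.5, uvFwhm = 36,
                         longPeak = 520, longAmplitude = 0.5, longFwhm = 96,
                         baseline = 0.05) {
  new("StimulusSpec", uvPeak = uvPeak, uvAmplitude = uvAmplitude,
      uvFwhm = uvFwhm, longPeak = longPeak, longAmplitude = longAmplitude,
      longFwhm = longFwhm, baseline = baseline)
}

setMethod("show", "StimulusSpec", function(object) {
  cat(sprintf(paste0("StimulusSpec: UV peak %.0f nm (A=%.3g, FWHM %.0f nm), ",
                     "long peak %.0f nm (A=%.3g, FWHM %.0f nm), baseline %.3g\n"),
              object@uvPeak, object@uvAmplitude, object@uvFwhm,
              object@longPeak, object@longAmplitude, object@longFwhm,
              object@baseline))
  invisible(NULL)
})
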