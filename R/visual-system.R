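#' @include spectra-io.R
NULL

# Govardovskii et al. (2000) A1 visual pigment template constants, kept in one
# block so an alternative template family can be swapped in.
.A1_TEMPLATE <- list(
  A = 69.7, B = 28, C = -14.9, D = 0.674,
  b = 0.922, c = 1.104,
  a0 = 0.8795, a1 = 0.0459, a2 = 300, a3 = 11940,
  # beta band
  Abeta = 0.26,
  bm0 = 189, bm1 = 0.315,     # beta-band lambda_max
  bb0 = -40.5, bb1 = 0.195    # beta-band bandwidth
)

#' Visual pigment absorbance template
#'
#' Normalised absorbance spectrum of an A1 visual pigment from its peak
#' wavelength alone, using the Govardovskii A1 nomogram (alpha band plus beta
#' band). The returned spectrum has maximum value 1 near `lambdaMax`.
#'
#' @param lambdaMax pigment absorbance peak in nm, within `[330, 600]`.
#' @param grid wavelength grid in nm (default 300–700 at 1 nm).
#' @return A [Spectrum-class] of kind `"sensitivity"`.
#' @examples
#' tpl <- pigmentTemplate(371)
#' wavelengths(tpl)[which.max(intensities(tpl))]
#' @export
pigmentTemplate <- function(lambdaMax, grid = 300:700) {
  if (!is.numeric(lambdaMax) || length(lambdaMax) != 1L ||
      lambdaMax < 330 || lambdaMax > 600) {
    stop("lambdaMax must be a single value within [330, 600] nm", call. = FALSE)
  }
  p <- .A1_TEMPLATE
  lam <- as.numeric(grid)
  x <- lambdaMax / lam
  a <- p$a0 + p$a1 * exp(-(lambdaMax - p$a2)^2 / p$a3)
  alpha <- 1 / (exp(p$A * (a - x)) + exp(p$B * (p$b - x)) +
                  exp(p$C * (p$c - x)) + p$D)
  lmb <- p$bm0 + p$bm1 * lambdaMax
  bb <- p$bb0 + p$bb1 * lambdaMax
  beta <- p$Abeta * exp(-((lam - lmb) / bb)^2)
  v <- alpha + beta
  Spectrum(lam, v / max(v), kind = "sensitivity")
}

#' Screen a pigment by the ocular media
#'
#' Pointwise product of a pigment (or any sensitivity) spectrum with an
#' ocular media transmittance spectrum. The result is deliberately NOT
#' renormalised: screening reduces absolute sensitivity, shifts the
#' absorbance peak to longer wavelengths and truncates the visual range in
#' the UV, and all three effects must remain visible.
#'
#' @param pigment a sensitivity [Spectrum-class].
#' @param omt a transmittance [Spectrum-class] on the same grid.
#' @return A [Spectrum-class] of kind `"sensitivity"`.
#' @export
applyOcularMedia <- function(pigment, omt) {
  .stopIfGridMismatch(pigment, omt)
  Spectrum(wavelengths(pigment), intensities(pigment) * intensities(omt),
           kind = "sensitivity")
}

#' Effective peak wavelength of a sensitivity spectrum
#'
#' Wavelength of maximum sensitivity, refined by fitting a parabola through
#' the three samples around the grid argmax (sub-sample precision on a 1 nm
#' grid).
#'
#' @param sensitivity a [Spectrum-class].
#' @return Peak wavelength in nm.
#' @export
effectivePeak <- function(sensitivity) {
  v <- intensities(sensitivity)
  w <- wavelengths(sensitivity)
  if (max(v) <= 0) stop("spectrum is all zero; no peak", call. = FALSE)
  i <- which.max(v)
  if (i == 1L || i == length(v)) return(w[i])
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (denom >= 0) return(w[i])
  offset <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  w[i] + offset * (w[i + 1L] - w[i])
}

# long-pass cut-off used for optional oil-droplet filtering
.longPassFilter <- function(grid, cut, scale = 8) {
  Spectrum(grid, 1 / (1 + exp(-(grid - cut) / scale)), kind = "transmittance")
}

#' Surrogate receptor parameter sets
#'
#' Default cone channel parameters for the two avian model retinas used in
#' the discrimination analysis: the budgerigar as the UVS-pigment
#' representative and the domestic chicken as the VS-pigment representative.
#' The sws1 peaks (371 and 418 nm) follow published measurements; the
#' remaining peaks and the relative abundances (sws1 : sws2 : mws : lws =
#' 1 : 2 : 2 : 4) are surrogate defaults and can be overridden in
#' [buildVisualSystem()].
#'
#' @param species `"budgerigar"` (UVS) or `"chicken"` (VS).
#' @return A data.frame with columns `name`, `lambda_max`, `abundance`.
#' @export
receptorDefaults <- function(species = c("budgerigar", "chicken")) {
  species <- match.arg(species)
  lm <- switch(species,
               budgerigar = c(371, 440, 499, 566),
               chicken = c(418, 455, 508, 571))
  data.frame(name = c("sws1", "sws2", "mws", "lws"),
             lambda_max = lm, abundance = c(1, 2, 2, 4),
             stringsAsFactors = FALSE)
}

#' Parametric average ocular media transmittance curves
#'
#' Logistic surrogates for the three average OMT classes observed across
#' birds: `"uv"` (high UV transparency, parrots and UVS-passerines;
#' \eqn{\lambda_{T0.5}} 323 nm), `"v"` (medium transparency, owls, land fowls
#' and VS-passerines; 358 nm) and `"raptor"` (low transparency; 389 nm), plus
#' `"identity"` (perfectly transparent media). Slope scales default to a
#' steeper cut-off for the UV class, as seen in measured curves.
#'
#' @param class one of `"uv"`, `"v"`, `"raptor"`, `"identity"`.
#' @param grid wavelength grid in nm.
#' @param lambdaT50,slopeScale optional overrides of the logistic midpoint
#'   (nm) and scale (nm).
#' @return A normalised transmittance [Spectrum-class].
#' @export
averageOmt <- function(class = c("uv", "v", "raptor", "identity"),
                       grid = 300:700, lambdaT50 = NULL, slopeScale = NULL) {
  class <- match.arg(class)
  grid <- as.numeric(grid)
  if (class == "identity") {
    return(Spectrum(grid, rep(1, length(grid)), kind = "transmittance"))
  }
  preset <- switch(class,
                   uv = c(323, 6), v = c(358, 9), raptor = c(389, 8))
  l50 <- if (is.null(lambdaT50)) preset[1] else lambdaT50
  s <- if (is.null(slopeScale)) preset[2] else slopeScale
  v <- 1 / (1 + exp(-(grid - l50) / s))
  normalizeToRangeMax(Spectrum(grid, v, kind = "transmittance"))
}

#' Assemble a receptor-noise-limited visual system
#'
#' Builds each channel from its pigment template, screens it by the ocular
#' media, optionally applies a per-channel long-pass (oil-droplet style)
#' filter, and computes per-channel noise
#' \eqn{e_i = \nu \sqrt{\eta_{ref}/\eta_i}} from the relative abundances.
#' Oil-droplet filtering is off unless a `droplet_cut` column is supplied;
#' sws1 droplets are transparent, so UV channels are normally left unfiltered.
#'
#' @param channels a data.frame with columns `name`, `lambda_max`,
#'   `abundance` and optionally `droplet_cut` (nm, `NA` to skip), e.g. from
#'   [receptorDefaults()]; 2–4 rows.
#' @param omt ocular media transmittance [Spectrum-class]; its grid becomes
#'   the system grid.
#' @param weberFraction Weber fraction \eqn{\nu} of the most abundant channel.
#' @return A [VisualSystem-class].
#' @examples
#' vs <- buildVisualSystem(receptorDefaults("budgerigar"), averageOmt("uv"))
#' channelNoise(vs)
#' @export
buildVisualSystem <- function(channels, omt, weberFraction = 0.1) {
  if (missing(omt) || !is(omt, "Spectrum")) {
    stop("an ocular media transmittance Spectrum is required", call. = FALSE)
  }
  if (!is.data.frame(channels) ||
      !all(c("name", "lambda_max", "abundance") %in% names(channels))) {
    stop("channels must be a data.frame with name, lambda_max, abundance",
         call. = FALSE)
  }
  if (nrow(channels) < 2L || nrow(channels) > 4L) {
    stop("2-4 channels required", call. = FALSE)
  }
  if (any(is.na(channels$lambda_max))) {
    stop("every channel needs a lambda_max", call. = FALSE)
  }
  grid <- wavelengths(omt)
  chans <- lapply(seq_len(nrow(channels)), function(i) {
    sens <- applyOcularMedia(pigmentTemplate(channels$lambda_max[i], grid), omt)
    if ("droplet_cut" %in% names(channels) && !is.na(channels$droplet_cut[i])) {
      sens <- applyOcularMedia(sens, .longPassFilter(grid, channels$droplet_cut[i]))
    }
    new("ReceptorChannel", name = as.character(channels$name[i]),
        lambdaMax = channels$lambda_max[i],
        abundance = channels$abundance[i], sensitivity = sens)
  })
  eta <- channels$abundance
  noise <- weberFraction * sqrt(max(eta) / eta)
  new("VisualSystem", channels = chans, weberFraction = weberFraction,
      noise = noise)
}
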