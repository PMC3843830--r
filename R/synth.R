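#' @include spectra-io.R
NULL

#' Packaged 38-species table of ocular media transmittance indicators
#'
#' Loads the bundled species table: 38 bird species from 11 orders with sws1
#' pigment class (13 UVS, 25 VS), pigment \eqn{\lambda_{max}} where measured,
#' the published \eqn{\lambda_{T0.5}} of the ocular media, an analysis group
#' label (`parrot`, `UVS-passerine`, `VS-passerine`, `owl`, `landfowl`,
#' `raptor`, `other`), a flag for whether the transmittance is known at very
#' short wavelengths, and footnotes (owls' VS grouping is uncertain; some
#' pigment classes are inferred from phylogeny). Axial eye lengths were never
#' published as a table and are therefore `NA`; eye-size analyses use
#' [synthSpeciesTable()].
#'
#' @return A data.frame with 38 rows.
#' @examples
#' table(speciesTable1()$pigment_class)
#' @export
speciesTable1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "aviomt",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 38L,
            all(tab$pigment_class %in% c("UVS", "VS")),
            all(tab$lambda_t50 >= 300 & tab$lambda_t50 <= 700))
  tab
}

#' Synthetic sigmoidal ocular media transmittance spectrum
#'
#' Generates a logistic transmittance curve
#' \eqn{T(\lambda) = p / (1 + e^{-(\lambda - \lambda_{50})/s})} plus optional
#' Gaussian noise, sampled on the standard 300–700 nm, 1 nm grid and clipped
#' at zero. With plateau 1 and no noise, \eqn{\lambda_{T0.5}} of the
#' normalised curve equals \eqn{\lambda_{50}} (up to the negligible
#' normalisation at 700 nm), which anchors parameter-recovery tests.
#'
#' @param lambdaT50 logistic midpoint in nm, within (300, 450).
#' @param slopeScale logistic scale s in nm, `> 0`.
#' @param plateau asymptotic transmittance fraction.
#' @param noiseSd standard deviation of additive Gaussian noise, `>= 0`.
#' @param seed integer seed; the same seed always yields the same spectrum
#'   and the caller's RNG stream is left untouched.
#' @param grid wavelength grid in nm.
#' @return A transmittance [Spectrum-class].
#' @export
synthOmtSpectrum <- function(lambdaT50, slopeScale = 6, plateau = 1,
                             noiseSd = 0, seed, grid = 300:700) {
  if (lambdaT50 <= 300 || lambdaT50 >= 450) {
    stop("lambdaT50 must lie within (300, 450) nm", call. = FALSE)
  }
  if (slopeScale <= 0 || noiseSd < 0 || plateau <= 0) {
    stop("slopeScale and plateau must be > 0, noiseSd >= 0", call. = FALSE)
  }
  grid <- as.numeric(grid)
  v <- plateau / (1 + exp(-(grid - lambdaT50) / slopeScale))
  if (noiseSd > 0) {
    v <- .withSeed(seed, v + rnorm(length(grid), 0, noiseSd))
  } else {
    # still consume the seed argument for interface uniformity
    stopifnot(!missing(seed))
  }
  Spectrum(grid, pmax(v, 0), kind = "transmittance")
}

#' Synthetic species table with an eye-size trend
#'
#' Generates a species table emulating the structure of the packaged
#' 38-species table together with one synthetic transmittance spectrum per
#' species. Pigment peaks are drawn uniformly from the empirical class ranges
#' (UVS 359–373 nm, VS 404–421 nm); axial eye length is uniform over
#' `axialRange`; \eqn{\lambda_{T0.5}} follows the linear eye-size relation
#' `intercept + slope * axial_length` plus Gaussian noise (the positive
#' trend seen in real birds); each species gets a matching logistic
#' transmittance spectrum.
#'
#' @param nUvs,nVs species counts per pigment class (defaults mirror the
#'   published 13 + 25 composition).
#' @param axialRange axial eye length range in mm.
#' @param intercept,slope linear \eqn{\lambda_{T0.5}}–axial-length relation
#'   (nm, nm per mm).
#' @param noiseSd residual sd of \eqn{\lambda_{T0.5}} about the relation, nm.
#' @param slopeScales logistic OMT scale per class, nm (UVS cut-offs are
#'   steeper).
#' @param omtNoiseSd additive noise sd of the generated spectra.
#' @param seed integer seed.
#' @return A list with `table` (data.frame: `species`, `pigment_class`,
#'   `pigment_lambda_max`, `lambda_t50`, `axial_length`, `group_label`) and
#'   `spectra` (list of [Spectrum-class], one per row).
#' @export
synthSpeciesTable <- function(nUvs = 13L, nVs = 25L, axialRange = c(6, 34),
                              intercept = 310, slope = 2.5, noiseSd = 6,
                              slopeScales = c(UVS = 6, VS = 9),
                              omtNoiseSd = 0.01, seed) {
  n <- nUvs + nVs
  stopifnot(n >= 1L, noiseSd >= 0)
  ranges <- list(UVS = c(359, 373), VS = c(404, 421))
  .withSeed(seed, {
    cls <- c(rep("UVS", nUvs), rep("VS", nVs))
    lmax <- vapply(cls, function(cl) runif(1, ranges[[cl]][1], ranges[[cl]][2]),
                   numeric(1))
    axial <- runif(n, axialRange[1], axialRange[2])
    l50 <- intercept + slope * axial + rnorm(n, 0, noiseSd)
    l50 <- pmin(pmax(l50, 301), 449)
    grp <- character(n)
    if (nUvs > 0) {
      grp[seq_len(nUvs)] <- rep(c("parrot", "UVS-passerine"),
                                length.out = nUvs)
    }
    if (nVs > 0) {
      grp[nUvs + seq_len(nVs)] <-
        rep(c("VS-passerine", "owl", "landfowl", "raptor", "other"),
            length.out = nVs)
    }
    spectra <- lapply(seq_len(n), function(i) {
      synthOmtSpectrum(l50[i], slopeScale = unname(slopeScales[cls[i]]),
                       noiseSd = omtNoiseSd,
                       seed = sample.int(.Machine$integer.max, 1L))
    })
    list(table = data.frame(species = sprintf("synthetic_%s_%02d",
                                              tolower(cls), seq_len(n)),
                            pigment_class = cls, pigment_lambda_max = lmax,
                            lambda_t50 = l50, axial_length = axial,
                            group_label = grp, stringsAsFactors = FALSE),
         spectra = spectra)
  })
}

#' CIE standard illuminant D65
#'
#' The bundled CIE D65 relative spectral power table (300–700 nm at 5 nm)
#' interpolated to the requested grid. In `"energy"` units the tabulated
#' relative power is returned as is; in `"photon"` units it is converted to
#' relative photon flux (energy times wavelength) and renormalised so its
#' trapezoid integral over the grid is 1.
#'
#' @param grid wavelength grid in nm, within 300–700.
#' @param units `"photon"` or `"energy"`.
#' @return An illuminant [Spectrum-class].
#' @export
standardIlluminantD65 <- function(grid = 300:700,
                                  units = c("photon", "energy")) {
  units <- match.arg(units)
  path <- system.file("extdata", "cie_d65.csv", package = "aviomt",
                      mustWork = TRUE)
  tab <- read.csv(path)
  base <- Spectrum(tab$wavelength_nm, tab$relative_spectral_power,
                   kind = "illuminant-energy")
  s <- resampleLinear(base, grid)
  if (units == "energy") return(s)
  w <- wavelengths(s)
  v <- intensities(s) * w
  v <- v / .trapz(w, v)
  Spectrum(w, v, kind = "illuminant-photon")
}
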