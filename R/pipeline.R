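#' @include rnl.R stats.R synth.R
NULL

#' Configuration for the end-to-end analysis pipeline
#'
#' @param speciesTable path to a species CSV with the columns of
#'   [speciesTable1()], or `NULL` to use the packaged table.
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving every random component.
#' @param grid wavelength grid in nm.
#' @param smoothWindow running-average window (odd, samples).
#' @param omtSlopeScales named logistic scales (nm) for generating synthetic
#'   per-species transmittance spectra from tabulated
#'   \eqn{\lambda_{T0.5}} values.
#' @param omtNoiseSd additive noise sd of the generated spectra.
#' @param weberFraction Weber fraction of the RNL model.
#' @param fwhms UV-peak FWHM values to sweep (nm).
#' @param uvRange UV peak positions for the sweep (nm).
#' @param eyeSizeN number of synthetic species for the eye-size analysis.
#' @return A validated list of class `"RunConfig"`.
#' @export
pipelineConfig <- function(speciesTable = NULL, outDir = tempfile("aviomt-run-"),
                           seed = 1L, grid = 300:700, smoothWindow = 11L,
                           omtSlopeScales = c(UVS = 6, VS = 9),
                           omtNoiseSd = 0.01, weberFraction = 0.1,
                           fwhms = c(36, 96), uvRange = 320:420,
                           eyeSizeN = 23L) {
  if (!is.null(speciesTable) && !file.exists(speciesTable)) {
    stop("species table not found: ", speciesTable, call. = FALSE)
  }
  if (smoothWindow %% 2L == 0L) stop("smoothWindow must be odd", call. = FALSE)
  structure(list(speciesTable = speciesTable, outDir = outDir,
                 seed = as.integer(seed), grid = as.numeric(grid),
                 smoothWindow = as.integer(smoothWindow),
                 omtSlopeScales = omtSlopeScales, omtNoiseSd = omtNoiseSd,
                 weberFraction = weberFraction, fwhms = fwhms,
                 uvRange = uvRange, eyeSizeN = as.integer(eyeSizeN)),
            class = "RunConfig")
}

.stage <- function(name, verbose, code) {
  if (verbose) message(sprintf("[aviomt] stage %-18s ...", name))
  tryCatch(force(code), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the end-to-end analysis
#'
#' Orchestrates the whole analysis chain: load the species table, generate a
#' synthetic transmittance spectrum per species from its tabulated
#' \eqn{\lambda_{T0.5}} (the raw measured curves were never deposited),
#' process each spectrum (smooth, normalise, \eqn{\lambda_{T0.5}}, cut-off
#' slopes, retinal UV fraction), summarise and test the species groups,
#' average the three transmittance classes, correlate transmittance with
#' pigment tuning and retinal UV irradiance, run the eye-size analysis on a
#' synthetic table, and sweep discrimination thresholds for the four visual
#' systems (UVS/VS pigment crossed with UV-/V-class ocular media).
#'
#' All intermediates are plain CSV and the summary is JSON, so every stage is
#' independently inspectable; identical config and seed give byte-identical
#' outputs.
#'
#' @param config a `"RunConfig"` from [pipelineConfig()].
#' @param verbose print one progress line per stage.
#' @return (Invisibly) the summary list; files are written under
#'   `config$outDir`: `species_metrics.csv`, `group_summary.csv`,
#'   `average_omt.csv`, `threshold_curves.csv`, `summary.json`.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  grid <- config$grid
  illum <- standardIlluminantD65(grid, "photon")

  tab <- .stage("load-table", verbose, {
    if (is.null(config$speciesTable)) speciesTable1()
    else read.csv(config$speciesTable, stringsAsFactors = FALSE)
  })

  spectra <- .stage("synth-spectra", verbose, {
    lapply(seq_len(nrow(tab)), function(i) {
      synthOmtSpectrum(tab$lambda_t50[i],
                       slopeScale = unname(
                         config$omtSlopeScales[tab$pigment_class[i]]),
                       noiseSd = config$omtNoiseSd,
                       seed = (config$seed + 7919L * i) %% .Machine$integer.max,
                       grid = grid)
    })
  })

  processed <- .stage("process-spectra", verbose, {
    lapply(spectra, function(s) {
      normalizeToRangeMax(smoothRunningAverage(s, config$smoothWindow))
    })
  })

  metrics <- .stage("metrics", verbose, {
    l50 <- vapply(processed, wavelengthAtLevel, numeric(1), level = 0.5)
    uvf <- vapply(processed, retinalUvFraction, numeric(1), illum = illum)
    cbind(tab, lambda_t50_recovered = l50, retinal_uv_fraction = uvf)
  })
  slopes <- lapply(processed, cutoffSlopes)
  write.csv(metrics, file.path(config$outDir, "species_metrics.csv"),
            row.names = FALSE)

  groupSummary <- .stage("group-stats", verbose, {
    byPigment <- summarizeGroups(metrics, "pigment_class")
    testGroups <- c("parrot", "UVS-passerine", "VS-passerine", "owl",
                    "landfowl", "raptor")
    present <- intersect(testGroups, metrics$group_label)
    byLabel <- summarizeGroups(metrics, "group_label", groups = present)
    list(pigment = byPigment, label = byLabel)
  })
  write.csv(rbind(cbind(grouping = "pigment_class", groupSummary$pigment),
                  cbind(grouping = "group_label", groupSummary$label)),
            file.path(config$outDir, "group_summary.csv"), row.names = FALSE)

  tests <- .stage("group-tests", verbose, {
    uvs <- metrics$lambda_t50[metrics$pigment_class == "UVS"]
    vs <- metrics$lambda_t50[metrics$pigment_class == "VS"]
    main <- compareGroups(uvs, vs)
    # cut-off slope comparison per 5% interval, Dunn-Sidak family of 20
    slopeMat <- vapply(slopes, function(d) d$slope, numeric(20L))
    isUvs <- metrics$pigment_class == "UVS"
    perInterval <- lapply(seq_len(20L), function(k) {
      sa <- slopeMat[k, isUvs]; sb <- slopeMat[k, !isUvs]
      sa <- sa[is.finite(sa)]; sb <- sb[is.finite(sb)]
      if (length(sa) < 2L || length(sb) < 2L) return(NULL)
      cmp <- compareGroups(sa, sb, familySize = 20L)
      list(interval = k, level_lo = 0.05 * (k - 1), test = cmp$test,
           p_value = cmp$p_value, significant = cmp$significant)
    })
    list(lambda_t50_uvs_vs = main,
         slope_intervals = Filter(Negate(is.null), perInterval))
  })

  avgOmt <- .stage("average-omt", verbose, {
    classOf <- function(labels) which(metrics$group_label %in% labels)
    groups <- list(uv_omt = c("parrot", "UVS-passerine"),
                   v_omt = c("owl", "landfowl", "VS-passerine"),
                   raptor_omt = "raptor")
    out <- lapply(groups, function(labels) {
      idx <- classOf(labels)
      if (!length(idx)) return(NULL)
      averageSpectra(processed[idx])
    })
    Filter(Negate(is.null), out)
  })
  if (length(avgOmt)) {
    avgDf <- data.frame(wavelength_nm = grid)
    for (nm in names(avgOmt)) {
      avgDf[[paste0(nm, "_mean")]] <- intensities(avgOmt[[nm]]$mean)
      avgDf[[paste0(nm, "_sd")]] <- intensities(avgOmt[[nm]]$sd)
    }
    write.csv(avgDf, file.path(config$outDir, "average_omt.csv"),
              row.names = FALSE)
  }

  correlations <- .stage("correlations", verbose, {
    known <- if ("omt_uv_known" %in% names(metrics)) metrics$omt_uv_known else TRUE
    sub <- metrics[known, , drop = FALSE]
    uvIrr <- correlateSpearman(sub$lambda_t50, sub$retinal_uv_fraction)
    uvFit <- fitCurve(sub$lambda_t50, sub$retinal_uv_fraction, "poly2")
    pig <- sub[!is.na(sub$pigment_lambda_max), , drop = FALSE]
    pigCor <- if (nrow(pig) >= 4L) {
      correlateSpearman(pig$lambda_t50, pig$pigment_lambda_max)
    } else NULL
    pigFit <- if (nrow(pig) >= 4L) {
      fitCurve(pig$pigment_lambda_max, pig$lambda_t50, "linear")
    } else NULL
    list(retinal_uv = uvIrr, retinal_uv_poly2 = uvFit,
         pigment = pigCor, pigment_linear = pigFit)
  })

  eyeSize <- .stage("eye-size", verbose, {
    syn <- synthSpeciesTable(nUvs = ceiling(config$eyeSizeN / 3),
                             nVs = config$eyeSizeN - ceiling(config$eyeSizeN / 3),
                             seed = config$seed + 104729L)
    cor <- correlateSpearman(syn$table$axial_length, syn$table$lambda_t50)
    lin <- fitCurve(syn$table$axial_length, syn$table$lambda_t50, "linear")
    tte <- fitCurve(syn$table$axial_length, syn$table$lambda_t50,
                    "two_term_exponential")
    list(n = nrow(syn$table), spearman = cor, linear = lin,
         two_term_exponential = tte)
  })

  sweeps <- .stage("model-sweeps", verbose, {
    omts <- list(uv = if (!is.null(avgOmt$uv_omt))
                        normalizeToRangeMax(avgOmt$uv_omt$mean)
                      else averageOmt("uv", grid),
                 v = if (!is.null(avgOmt$v_omt))
                       normalizeToRangeMax(avgOmt$v_omt$mean)
                     else averageOmt("v", grid))
    systems <- list(
      vs_pigment_v_omt = list(rec = "chicken", omt = "v"),
      vs_pigment_uv_omt = list(rec = "chicken", omt = "uv"),
      uvs_pigment_v_omt = list(rec = "budgerigar", omt = "v"),
      uvs_pigment_uv_omt = list(rec = "budgerigar", omt = "uv"))
    rows <- list()
    limits <- list()
    for (nm in names(systems)) {
      sys <- buildVisualSystem(receptorDefaults(systems[[nm]]$rec),
                               omts[[systems[[nm]]$omt]],
                               weberFraction = config$weberFraction)
      for (fw in config$fwhms) {
        curve <- thresholdSweep(sys, stimulusSpec(uvFwhm = fw), illum,
                                uvRange = config$uvRange)
        rows[[length(rows) + 1L]] <- cbind(system = nm, uv_fwhm_nm = fw, curve)
        limits[[paste0(nm, "_fwhm", fw)]] <- discriminationLimit(curve)
      }
    }
    list(curves = do.call(rbind, rows), limits = limits)
  })
  write.csv(sweeps$curves, file.path(config$outDir, "threshold_curves.csv"),
            row.names = FALSE)

  summary <- .stage("summary", verbose, {
    list(
      seed = config$seed,
      n_species = nrow(metrics),
      group_means = list(
        pigment = groupSummary$pigment,
        label = groupSummary$label),
      lambda_t50_range = range(metrics$lambda_t50),
      tests = list(
        lambda_t50_uvs_vs = unclass(tests$lambda_t50_uvs_vs),
        slope_intervals = tests$slope_intervals),
      correlations = list(
        retinal_uv = correlations$retinal_uv,
        retinal_uv_poly2 = list(
          coefficients = as.list(correlations$retinal_uv_poly2$coefficients),
          rss = correlations$retinal_uv_poly2$rss),
        pigment = correlations$pigment,
        pigment_linear = if (!is.null(correlations$pigment_linear)) list(
          coefficients = as.list(correlations$pigment_linear$coefficients),
          rss = correlations$pigment_linear$rss) else NULL),
      eye_size = list(
        n = eyeSize$n, spearman = eyeSize$spearman,
        linear = as.list(eyeSize$linear$coefficients),
        two_term_exponential = as.list(
          eyeSize$two_term_exponential$coefficients)),
      discrimination_limits = sweeps$limits)
  })
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns", null = "null")
  invisible(summary)
}
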