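# internal numerical helpers

# trapezoid rule on an arbitrary (increasing) grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# run `code` under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.stopIfGridMismatch <- function(a, b, what = "spectra") {
  wa <- wavelengths(a)
  wb <- wavelengths(b)
  if (length(wa) != length(wb) || any(abs(wa - wb) > 1e-9)) {
    stop(what, " must share an identical wavelength grid", call. = FALSE)
  }
  invisible(TRUE)
}
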