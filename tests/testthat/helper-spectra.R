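# shared fixtures: all built in code, no files

# noiseless logistic transmittance on an arbitrary grid
logisticOmt <- function(l50, s, grid = 300:700, plateau = 1) {
  Spectrum(grid, plateau / (1 + exp(-(grid - l50) / s)),
           kind = "transmittance")
}

# independent dense-grid downward-crossing oracle: evaluates the sampled
# spectrum by linear interpolation on a very fine grid and scans from the
# maximum downward for the first crossing of `level`
denseCrossingOracle <- function(s, level, step = 0.001) {
  w <- wavelengths(s)
  fine <- seq(min(w), max(w), by = step)
  v <- approx(w, intensities(s), xout = fine)$y
  imax <- which.max(v)
  below <- which(v[seq_len(imax)] <= level)
  if (!length(below)) return(NA_real_)
  j <- max(below)
  if (v[j] == level) return(fine[j])
  fine[j] + (level - v[j]) / (v[j + 1] - v[j]) * (fine[j + 1] - fine[j])
}

# random wiggly non-negative spectrum for property tests
randomSpectrum <- function(n = 101, grid = seq(300, 700, length.out = n),
                           kind = "transmittance") {
  v <- abs(cumsum(rnorm(length(grid), 0, 0.1))) + 0.05
  Spectrum(grid, v, kind = kind)
}

# achromatic-projection oracle for the RNL distance: 1-D numeric minimisation
# of the noise-weighted distance to the achromatic (equal log-contrast) axis
rnlProjectionOracle <- function(df, e) {
  f <- function(c) sum(((df - c) / e)^2)
  opt <- optimize(f, range(df) + c(-1, 1), tol = 1e-12)
  sqrt(opt$objective)
}
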