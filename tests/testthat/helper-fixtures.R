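# Shared fixtures: everything is generated in code at test time.

# a noise-free Gaussian chromatogram on a regular grid
gaussian_chrom <- function(amplitude = 1000, center = 5, sigma = 0.05,
                           period = 0.05, span = c(0, 10), offset = 0) {
  rt <- seq(span[1], span[2], by = period)
  tibble::tibble(
    rt = rt,
    intensity = offset + amplitude * exp(-0.5 * ((rt - center) / sigma)^2)
  )
}

# scenario with response factors set to the reference calibration slopes
# (surrogate's slope for the compounds without their own standard)
reference_scenario <- function(contents = numeric(), noise_level = 0,
                               seed = 1, ...) {
  lib <- phenol_library()
  calref <- phenol_calibration_reference()
  rf <- setNames(calref$slope[match(lib$surrogate, calref$compound)],
                 lib$compound)
  ms_scenario(contents, response_factor = rf, noise_level = noise_level,
              seed = seed, ...)
}

# calibration models built directly from the reference table constants;
# with_intercept = FALSE gives the pure proportional response matching
# simulate_run()'s sample model (the printed intercepts are matrix
# background that only enters the calibration series)
reference_calibrations <- function(lod = 0.01, with_intercept = TRUE) {
  calref <- phenol_calibration_reference()
  levels <- c(2, 5, 10, 20, 50, 100)
  out <- lapply(seq_len(nrow(calref)), function(i) {
    b <- if (with_intercept) calref$intercept[i] else 0
    m <- fit_calibration(levels, calref$slope[i] * levels + b,
                         compound = calref$compound[i])
    m$lod <- lod
    m$loq <- 10 / 3 * lod
    m
  })
  setNames(out, calref$compound)
}
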