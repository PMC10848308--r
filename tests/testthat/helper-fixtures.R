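# Shared fixtures built in code: small spectral sets with known structure.

grid_2cm <- function() seq(800, 4000, by = 2)

# Raw set containing a single Gaussian band, optionally with baseline/noise.
single_band_set <- function(centre = 1744, amplitude = 1, sigma = 14,
                            baseline = 0, noise_sd = 0, n = 1, seed = 1) {
  set.seed(seed)
  wn <- grid_2cm()
  vals <- vapply(seq_len(n), function(i) {
    amplitude * exp(-(wn - centre)^2 / (2 * sigma^2)) + baseline +
      stats::rnorm(length(wn), 0, noise_sd)
  }, numeric(length(wn)))
  ftir_set(wn, vals)
}

# Small, fast generator configuration used where the full study design is
# not the thing under test.
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, cells_per_site = c(2L, 3L),
                   points_per_cell = c(2L, 2L), ...)
}

# Response models with a single non-zero band, for clean forward-model tests.
one_band_models <- function(label = "lipid_ester", amplitude = 2) {
  m <- default_response_models()
  m$slope <- 0
  m$baseline <- ifelse(m$label == label, amplitude, 0)
  m
}

no_background <- function()
  data.frame(centre = numeric(0), amplitude = numeric(0),
             width_sd = numeric(0))
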