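#' Default taxon-specific light-response models
#'
#' One row per (taxon, band): baseline amplitude (arbitrary absorbance at 0%
#' incoming PAR), slope per percent incoming PAR, and an optional saturation
#' threshold above which the response plateaus
#' (`amplitude(L) = baseline + slope * min(L, saturation)`).
#'
#' The default structure encodes the observed field response: photosynthate
#' bands (lipids, fatty acids, carbohydrates) double between ~1.5% and ~10%
#' incoming PAR and saturate at 15%, except for Navicula spp. which keeps
#' accumulating; protein (amide II) is flat; carboxylated molecules decline
#' with light; phosphorylated molecules decline in four of five taxa; silica
#' increases with light (plateauing at 15% for Nitzschia frigida only).
#'
#' @param lipid_doubling_light Percent PAR at which photosynthate amplitude
#'   is twice its value at `lipid_ref_light`; defaults give
#'   `slope = baseline / 7` so amp(10%) / amp(1.5%) = 2 exactly.
#' @param lipid_ref_light Reference (low-light) percent PAR for the doubling.
#' @param saturation_pct Saturation threshold, percent incoming PAR.
#' @param silica_direction `+1` (default) for silica increasing with light,
#'   `-1` for the opposite sign.
#' @return Data frame with columns `taxon`, `label`, `baseline`, `slope`,
#'   `saturation` (NA = no plateau).
#' @export
default_response_models <- function(lipid_doubling_light = 10,
                                    lipid_ref_light = 1.5,
                                    saturation_pct = 15,
                                    silica_direction = 1) {
  taxa <- c("Nitzschia frigida", "Navicula spp.", "Haslea spp.",
            "Pleurosigma spp.", "Entomoneis spp.")
  taxon_scale <- c(1.0, 0.8, 0.9, 1.15, 1.1)  # taxon-specific amplitude levels
  reg <- default_band_registry()
  # baseline amplitude at 0% PAR per band, arbitrary absorbance units
  # arbitrary absorbance units; an order of magnitude below the amide I /
  # O-H background complex, as in real hydrated-cell spectra where the
  # quantified marker bands are minor features of the total absorbance
  base <- c(unsat_fa = 0.05, methyl_lipid_protein = 0.13,
            sat_lipid_2921 = 0.17, sat_lipid_2852 = 0.12, lipid_ester = 0.20,
            protein_amide2 = 0.27, carboxylate = 0.15, lipid_ch2 = 0.10,
            phosphoryl = 0.13, carbohydrate = 0.17, silica = 0.23)
  # slope/baseline = 1/7 makes amp(10)/amp(1.5) = (1 + 10/7)/(1 + 1.5/7) = 2
  rise <- 1 / (lipid_doubling_light - 2 * lipid_ref_light)
  photosynthate <- c("unsat_fa", "sat_lipid_2921", "sat_lipid_2852",
                     "lipid_ester", "lipid_ch2", "carbohydrate")
  out <- do.call(rbind, lapply(seq_along(taxa), function(i) {
    tx <- taxa[i]
    b <- base[reg$label] * taxon_scale[i]
    slope <- numeric(length(b))
    sat <- rep(NA_real_, length(b))
    ph <- reg$label %in% photosynthate
    slope[ph] <- b[ph] * rise
    sat[ph] <- if (tx == "Navicula spp.") NA_real_ else saturation_pct
    mx <- reg$label == "methyl_lipid_protein"      # mixed band: milder rise
    slope[mx] <- b[mx] * rise / 2
    sat[mx] <- if (tx == "Navicula spp.") NA_real_ else saturation_pct
    slope[reg$label == "carboxylate"] <- -b[reg$label == "carboxylate"] / 100
    if (tx != "Nitzschia frigida")
      slope[reg$label == "phosphoryl"] <- -b[reg$label == "phosphoryl"] / 100
    si <- reg$label == "silica"
    slope[si] <- silica_direction * b[si] / 50
    if (tx == "Nitzschia frigida") sat[si] <- saturation_pct
    data.frame(taxon = tx, label = reg$label, baseline = unname(b),
               slope = unname(slope), saturation = sat,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expected (noise-free) band amplitude under a response model
#'
#' @param models Response-model data frame (rows of
#'   [default_response_models()]).
#' @param light_pct Percent incoming PAR (scalar).
#' @return `models` with an `amplitude` column appended.
#' @export
response_amplitude <- function(models, light_pct) {
  if (any(light_pct < 0)) stop("light_pct must be >= 0")
  eff <- ifelse(is.na(models$saturation), light_pct,
                pmin(light_pct, models$saturation))
  models$amplitude <- models$baseline + models$slope * eff
  models
}

#' Configuration for the synthetic single-cell spectrum generator
#'
#' Defaults emulate the field study design: six landfast-ice sites spanning
#' ~1.3-23.2% transmitted PAR (snow/ice from the site table shipped with the
#' package, surface PAR 640 umol m^-2 s^-1), five taxa, 1-20 cells per taxon
#' per site each measured at 3-6 points, a 4000-800 cm^-1 grid at 2 cm^-1
#' digitization, multiplicative lognormal cell-to-cell (sigma 0.25) and
#' point-to-point (sigma 0.10) variability, a degree-2 polynomial baseline
#' plus one broad background hump (sd 200 cm^-1), and additive Gaussian noise
#' (sd 0.005 absorbance).
#'
#' @param seed Integer RNG seed.
#' @param sites Data frame with `station_id`, `snow_depth` (cm),
#'   `ice_thickness` (cm), `surface_par`; default mirrors the shipped site
#'   table.
#' @param models Response-model data frame; default
#'   [default_response_models()].
#' @param cells_per_site Integer range (min, max) of cells per taxon per site.
#' @param points_per_cell Integer range of measured points per cell.
#' @param cell_sigma,point_sigma Lognormal sigmas of the mean-one
#'   multiplicative cell and point factors.
#' @param noise_sd Additive noise sd, absorbance units.
#' @param baseline_coef_max Max |coefficient| of the degree-2 baseline
#'   polynomial (in a [-1, 1] scaled wavenumber coordinate).
#' @param hump_amp_max Max amplitude of the broad background hump.
#' @param hump_sd Sd of the background hump, cm^-1.
#' @param band_width_sd Per-band Gaussian sd, cm^-1 (length 11).
#' @param background_bands Light-invariant spectral features present in
#'   every cell regardless of light regime: data frame `centre`,
#'   `amplitude`, `width_sd`. Defaults model the two dominant features of
#'   hydrated single-cell spectra, the amide I / water-bending complex
#'   (~1655 cm^-1) and the amide A / O-H stretch (~3290 cm^-1). Because
#'   these strong flat features dominate the per-spectrum variance, they
#'   keep the SNV denominator from tracking the light-responsive bands (as
#'   in real spectra), limiting normalization-induced closure between
#'   bands.
#' @param grid_start,grid_end,grid_step Wavenumber grid, cm^-1.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             sites = default_synthetic_sites(),
                             models = default_response_models(),
                             cells_per_site = c(1L, 20L),
                             points_per_cell = c(3L, 6L),
                             cell_sigma = 0.25,
                             point_sigma = 0.10,
                             noise_sd = 0.005,
                             baseline_coef_max = 0.02,
                             hump_amp_max = 0.05,
                             hump_sd = 200,
                             band_width_sd = NULL,
                             background_bands = NULL,
                             grid_start = 4000, grid_end = 800,
                             grid_step = 2) {
  if (is.null(band_width_sd))
    band_width_sd <- c(10, 12, 11, 11, 14, 18, 16, 10, 16, 20, 18)
  if (is.null(background_bands))
    background_bands <- data.frame(centre = c(3290, 1655),
                                   amplitude = c(2.0, 5.0),
                                   width_sd = c(45, 18))
  cfg <- list(seed = as.integer(seed), sites = sites, models = models,
              cells_per_site = as.integer(cells_per_site),
              points_per_cell = as.integer(points_per_cell),
              cell_sigma = cell_sigma, point_sigma = point_sigma,
              noise_sd = noise_sd, baseline_coef_max = baseline_coef_max,
              hump_amp_max = hump_amp_max, hump_sd = hump_sd,
              band_width_sd = band_width_sd,
              background_bands = background_bands,
              grid_start = grid_start, grid_end = grid_end,
              grid_step = grid_step)
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @keywords internal
validate_synthetic_config <- function(cfg) {
  if (cfg$grid_step <= 0) stop("grid_step must be > 0")
  if (length(cfg$cells_per_site) != 2 || cfg$cells_per_site[1] < 1 ||
      diff(cfg$cells_per_site) < 0)
    stop("cells_per_site must be an increasing range with min >= 1")
  if (length(cfg$points_per_cell) != 2 || cfg$points_per_cell[1] < 1 ||
      diff(cfg$points_per_cell) < 0)
    stop("points_per_cell must be an increasing range with min >= 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$cell_sigma < 0 || cfg$point_sigma < 0)
    stop("variability sigmas must be >= 0")
  nbands <- length(unique(cfg$models$label))
  if (length(cfg$band_width_sd) != nbands)
    stop("band_width_sd must have one entry per band (", nbands, ")")
  invisible(cfg)
}

#' Default synthetic site design (snow, ice, surface PAR)
#'
#' Six sites spanning the observed gradient of snow depth and ice thickness,
#' with surface PAR fixed at the observed site-average 640 umol m^-2 s^-1,
#' plus the bottom-ice temperature and bulk salinity used for brine-state
#' derivation.
#'
#' @return Data frame of site physical inputs (depths in cm).
#' @export
default_synthetic_sites <- function() {
  data.frame(
    station_id = c("VM-1", "VM-2", "VM-3", "VM-4", "VM-5", "TF-2"),
    snow_depth = c(14.3, 15.8, 10.0, 7.0, 4.8, 3.4),
    ice_thickness = c(92, 78, 74, 50, 52, 38),
    surface_par = 640,
    ice_temperature = c(-2.1, -2.2, -2.2, -2.1, -2.2, -2.7),
    bulk_salinity = c(6.5, 10.7, 10.4, 3.7, 5.6, 9.2),
    stringsAsFactors = FALSE
  )
}

# Gaussian band-shape matrix: one column per band on the given grid.
#' @keywords internal
band_shape_matrix <- function(wn, centres, width_sd) {
  vapply(seq_along(centres),
         function(j) exp(-(wn - centres[j])^2 / (2 * width_sd[j]^2)),
         numeric(length(wn)))
}

# mean-one lognormal factors
rlnorm1 <- function(n, sigma) exp(stats::rnorm(n, -sigma^2 / 2, sigma))

# Shared forward model: absorbance matrix from per-point band amplitudes.
# amps: nbands x npts; returns n_wn x npts.
#' @keywords internal
synth_values <- function(amps, wn, shapes, cfg) {
  npts <- ncol(amps)
  vals <- shapes %*% amps
  u <- 2 * (wn - min(wn)) / diff(range(wn)) - 1
  coefs <- matrix(stats::runif(3 * npts, -cfg$baseline_coef_max,
                               cfg$baseline_coef_max), 3, npts)
  vals <- vals + cbind(1, u, u^2) %*% coefs
  hamp <- stats::runif(npts, 0, cfg$hump_amp_max)
  hcen <- stats::runif(npts, min(wn) + 200, max(wn) - 200)
  hump <- exp(-sweep(matrix(wn, length(wn), npts), 2, hcen)^2 /
                (2 * cfg$hump_sd^2))
  vals <- vals + sweep(hump, 2, hamp, `*`)
  if (cfg$noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, cfg$noise_sd),
                          nrow(vals))
  vals
}

#' Generate one synthetic single-point spectrum
#'
#' Forward model: sum of Gaussian bands at the registry centres with
#' amplitudes set by the taxon's light response, plus a smooth polynomial
#' baseline, a broad background hump, and additive noise. Uses the current
#' RNG state; seed externally (or via [synth_dataset()]) for reproducibility.
#'
#' @param taxon Taxon name present in `config$models`.
#' @param light_pct Percent incoming PAR at the site.
#' @param config A [synthetic_config()].
#' @return An `ftir_set` with a single raw spectrum.
#' @export
synth_spectrum <- function(taxon, light_pct, config = synthetic_config()) {
  models <- config$models[config$models$taxon == taxon, , drop = FALSE]
  if (!nrow(models)) stop("unknown taxon: ", taxon)
  wn <- seq(min(config$grid_start, config$grid_end),
            max(config$grid_start, config$grid_end), by = config$grid_step)
  reg <- default_band_registry()
  models <- models[match(reg$label, models$label), ]
  bg <- config$background_bands
  shapes <- band_shape_matrix(wn, c(reg$centre, bg$centre),
                              c(config$band_width_sd, bg$width_sd))
  amp <- c(response_amplitude(models, light_pct)$amplitude, bg$amplitude)
  amp <- amp * rlnorm1(length(amp), config$cell_sigma) *
    rlnorm1(length(amp), config$point_sigma)
  vals <- synth_values(matrix(amp, ncol = 1), wn, shapes, config)
  ftir_set(wn, vals, data.frame(point_id = "pt1", taxon = taxon,
                                light_pct = light_pct,
                                stringsAsFactors = FALSE))
}

#' Generate a complete synthetic field dataset
#'
#' Produces pipeline-ready inputs mirroring the study design: a derived site
#' table (light and brine state appended), a set of raw single-point spectra
#' with point/cell/taxon/site metadata, and the ground-truth table of
#' per-cell expected band amplitudes used for parameter-recovery tests.
#'
#' @param config A [synthetic_config()]; `config$seed` determines the output
#'   byte-for-byte.
#' @return List with elements `spectra` (`ftir_set`), `sites` (derived site
#'   table), `truth` (one row per cell x band: `cell_id`, `taxon`,
#'   `station_id`, `light_pct`, `label`, `true_amplitude`).
#' @export
synth_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  sites <- derive_site_environment(config$sites, depth_unit = "cm")
  reg <- default_band_registry()
  taxa <- unique(config$models$taxon)
  wn <- seq(min(config$grid_start, config$grid_end),
            max(config$grid_start, config$grid_end), by = config$grid_step)
  bg <- config$background_bands
  shapes <- band_shape_matrix(wn, c(reg$centre, bg$centre),
                              c(config$band_width_sd, bg$width_sd))
  nb <- nrow(reg)
  nbg <- nrow(bg)

  meta_l <- list(); truth_l <- list(); amp_l <- list()
  cell_n <- 0L
  for (s in seq_len(nrow(sites))) {
    L <- sites$light_pct[s]
    for (tx in taxa) {
      m <- config$models[config$models$taxon == tx, ]
      m <- m[match(reg$label, m$label), ]
      mean_amp <- response_amplitude(m, L)$amplitude
      ncells <- sample(seq(config$cells_per_site[1], config$cells_per_site[2]), 1)
      for (ci in seq_len(ncells)) {
        cell_n <- cell_n + 1L
        cell_id <- sprintf("cell%04d", cell_n)
        true_amp <- mean_amp * rlnorm1(nb, config$cell_sigma)
        bg_amp <- bg$amplitude * rlnorm1(nbg, config$cell_sigma)
        npts <- sample(seq(config$points_per_cell[1],
                           config$points_per_cell[2]), 1)
        pf <- matrix(rlnorm1((nb + nbg) * npts, config$point_sigma),
                     nb + nbg, npts)
        amp_l[[cell_n]] <- c(true_amp, bg_amp) * pf
        meta_l[[cell_n]] <- data.frame(
          point_id = sprintf("%s_p%d", cell_id, seq_len(npts)),
          cell_id = cell_id, taxon = tx,
          station_id = sites$station_id[s], light_pct = L,
          stringsAsFactors = FALSE)
        truth_l[[cell_n]] <- data.frame(
          cell_id = cell_id, taxon = tx, station_id = sites$station_id[s],
          light_pct = L, label = reg$label, true_amplitude = true_amp,
          stringsAsFactors = FALSE)
      }
    }
  }
  amps <- do.call(cbind, amp_l)
  meta <- do.call(rbind, meta_l)
  truth <- do.call(rbind, truth_l)
  rownames(meta) <- rownames(truth) <- NULL
  vals <- synth_values(amps, wn, shapes, config)
  list(spectra = ftir_set(wn, vals, meta),
       sites = sites, truth = truth)
}
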