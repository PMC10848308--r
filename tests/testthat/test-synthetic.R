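test_that("default response models encode the field effect structure", {
  m <- default_response_models()
  for (tx in unique(m$taxon)) {
    a10 <- response_amplitude(m[m$taxon == tx & m$label == "lipid_ester", ], 10)$amplitude
    a1.5 <- response_amplitude(m[m$taxon == tx & m$label == "lipid_ester", ], 1.5)$amplitude
    expect_equal(a10 / a1.5, 2)  # doubling between low- and high-light regimes
    expect_equal(m$slope[m$taxon == tx & m$label == "protein_amide2"], 0)
  }
  # saturation at 15% for all photosynthate bands except Navicula spp.
  nav <- m[m$taxon == "Navicula spp." & m$label == "lipid_ester", ]
  sat <- m[m$taxon == "Haslea spp." & m$label == "lipid_ester", ]
  expect_gt(response_amplitude(nav, 23)$amplitude,
            response_amplitude(nav, 15)$amplitude)
  expect_equal(response_amplitude(sat, 23)$amplitude,
               response_amplitude(sat, 15)$amplitude)
  # carboxylated molecules decline with light in every taxon
  expect_true(all(m$slope[m$label == "carboxylate"] < 0))
  # phosphorylated molecules decline in four of five taxa
  expect_equal(sum(m$slope[m$label == "phosphoryl"] < 0), 4)
  # silica direction is configurable
  m2 <- default_response_models(silica_direction = -1)
  expect_true(all(m2$slope[m2$label == "silica"] < 0))
})

test_that("forward model places a lone band at its centre with its amplitude", {
  cfg <- synthetic_config(noise_sd = 0, baseline_coef_max = 0,
                          hump_amp_max = 0, cell_sigma = 0, point_sigma = 0,
                          models = one_band_models("lipid_ester", 2),
                          background_bands = no_background())
  s <- synth_spectrum("Haslea spp.", 5, cfg)
  expect_equal(max(s$values), 2, tolerance = 1e-9)
  expect_equal(s$wavenumbers[which.max(s$values[, 1])], 1744)
})

test_that("generation is deterministic for a fixed seed", {
  s1 <- withr::with_seed(99, synth_spectrum("Haslea spp.", 5))
  s2 <- withr::with_seed(99, synth_spectrum("Haslea spp.", 5))
  expect_identical(s1$values, s2$values)
  d1 <- synth_dataset(small_config(seed = 11))
  d2 <- synth_dataset(small_config(seed = 11))
  expect_identical(d1$spectra$values, d2$spectra$values)
  expect_identical(d1$truth, d2$truth)
  d3 <- synth_dataset(small_config(seed = 12))
  expect_false(identical(d1$spectra$values, d3$spectra$values))
})

test_that("dataset mirrors the study design and finiteness invariants", {
  ds <- synth_dataset(small_config(seed = 5))
  expect_equal(nrow(ds$sites), 6)
  expect_equal(length(unique(ds$spectra$meta$taxon)), 5)
  counts <- table(ds$spectra$meta$station_id, ds$spectra$meta$taxon)
  expect_true(all(counts > 0))
  cell_counts <- tapply(ds$truth$cell_id[ds$truth$label == "lipid_ester"],
                        paste(ds$truth$station_id, ds$truth$taxon)[ds$truth$label == "lipid_ester"],
                        function(x) length(unique(x)))
  expect_true(all(cell_counts >= 1 & cell_counts <= 20))
  expect_true(all(is.finite(ds$spectra$values)))
  expect_true(all(ds$truth$true_amplitude > 0))
  # light gradient spans ~1.3-23.2% transmittance
  expect_equal(round(range(ds$sites$light_pct), 1), c(1.3, 23.2))
})

test_that("unsatisfiable generator ranges are rejected", {
  expect_error(synthetic_config(cells_per_site = c(0, 0)), "min >= 1")
  expect_error(synthetic_config(cells_per_site = c(5, 2)), "increasing")
  expect_error(synthetic_config(grid_step = 0), "grid_step")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})

test_that("realized cell amplitudes match the configured response on average", {
  # many cells at one site: sample mean of the lognormal cell amplitudes
  # stays within 3 standard errors of the analytic response
  one_site <- data.frame(station_id = "S1", snow_depth = 7, ice_thickness = 50,
                         surface_par = 640, ice_temperature = -2.1,
                         bulk_salinity = 6.5)
  cfg <- synthetic_config(seed = 21, sites = one_site,
                          cells_per_site = c(60L, 60L),
                          points_per_cell = c(2L, 2L))
  ds <- synth_dataset(cfg)
  L <- ds$sites$light_pct[1]
  m <- default_response_models()
  for (lab in c("lipid_ester", "protein_amide2", "carbohydrate")) {
    tr <- ds$truth[ds$truth$label == lab & ds$truth$taxon == "Haslea spp.", ]
    expected <- response_amplitude(
      m[m$taxon == "Haslea spp." & m$label == lab, ], L)$amplitude
    se <- expected * sqrt(exp(cfg$cell_sigma^2) - 1) / sqrt(nrow(tr))
    expect_lt(abs(mean(tr$true_amplitude) - expected), 3 * se)
  }
})

test_that("the configured low- to high-light lipid ratio is 2x analytically", {
  m <- default_response_models()
  r <- response_amplitude(m[m$label == "lipid_ester", ], 10)$amplitude /
    response_amplitude(m[m$label == "lipid_ester", ], 1.5)$amplitude
  expect_equal(unname(r), rep(2, 5))
})

test_that("the full pipeline round trip recovers the configured light response", {
  # one well-populated replicate: simulate -> preprocess -> quantify -> fit
  cfg <- synthetic_config(seed = 202, cells_per_site = c(40L, 40L),
                          points_per_cell = c(2L, 2L))
  ds <- synth_dataset(cfg)
  prof <- profile_cells(preprocess_set(ds$spectra)$spectra)$profiles

  # significant positive lipid-light slope below saturation, flat protein
  for (tx in unique(prof$taxon)) {
    fl <- light_response_fit(prof, "lipid_ester", taxon = tx,
                             max_light = 15.5)
    expect_gt(fl$slope, 0)
    expect_lt(fl$p, 0.05)
    fp <- light_response_fit(prof, "protein_amide2", taxon = tx)
    expect_gt(fp$p, 0.05)
  }

  # the non-plateauing taxon keeps accumulating lipid above the threshold
  ratio <- vapply(unique(prof$taxon), function(tx) {
    mean(prof$lipid_ester[prof$taxon == tx & prof$station_id == "TF-2"]) /
      mean(prof$lipid_ester[prof$taxon == tx & prof$station_id == "VM-5"])
  }, 0)
  expect_equal(names(which.max(ratio)), "Navicula spp.")
  expect_gt(ratio[["Navicula spp."]], 1.1)

  # the lipid shift between light regimes improves the split pair model
  ff <- fixed_factor_fit(prof, "lipid_ester", "carbohydrate")
  expect_true(ff$improvement$significant)
})
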