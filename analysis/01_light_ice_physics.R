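#!/usr/bin/env Rscript

# Under-ice light and brine state of the sampled sites.
#
# Derives, from the measured snow depth, ice thickness, surface PAR, bulk
# salinity and ice temperature of the six landfast-ice sites, the modelled
# transmittance, transmitted PAR, light class (LLT/HLT), brine salinity and
# brine volume; writes the derived table under results/.

suppressPackageStartupMessages(library(iceftir))

sites <- read.delim(system.file("extdata", "site_table.tsv",
                                package = "iceftir"))
validate_table(sites, "sites")
derived <- derive_site_environment(sites, depth_unit = "cm")

dir.create("results", showWarnings = FALSE)
write.table(derived, "results/sites_derived.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Derived light and brine state for", nrow(derived), "sites\n\n")
print(derived[, c("station_id", "snow_depth", "ice_thickness", "light_pct",
                  "transmitted_par", "light_class", "brine_salinity",
                  "brine_volume_pct")], digits = 4)

cat("\nTransmitted PAR spans",
    paste(round(range(derived$transmitted_par)), collapse = "-"),
    "umol m^-2 s^-1 across the gradient;",
    sum(derived$light_class == "LLT"), "LLT and",
    sum(derived$light_class == "HLT"), "HLT sites.\n")
cat("All brine volumes exceed the 5% habitability threshold:",
    all(derived$brine_volume_pct > 5), "\n")

# carbon-isotope contrast between the light regimes (printed summaries:
# -17.42 +/- 3.2 at HLT vs -24.85 +/- 0.5 at LLT, n = 3 per group)
w <- welch_t_summary(-17.42, 3.2, 3, -24.85, 0.5, 3)
cat(sprintf("delta13C HLT vs LLT: t(%d) = %.2f, p = %.3f\n",
            w$df_floor, w$t, w$p))
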