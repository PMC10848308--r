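# iceftir

Linking under-ice light to the single-cell biomolecular composition of
sea-ice diatoms.

Arctic landfast sea ice hosts diatom communities whose nutritional value to
the food web — lipids, fatty acids, carbohydrates, proteins — depends on how
much photosynthetically active radiation (PAR) penetrates the snow and ice
above them. `iceftir` is an R implementation of the full analysis chain used
to quantify that link from synchrotron FTIR microspectroscopy of individual
cells:

1. **Light & ice physics** — two-layer exponential attenuation
   $E_Z = E_0\,e^{-K_d Z}$ with $K_d$ = 20 m⁻¹ (snow), 5 m⁻¹ (top 10 cm of
   ice), 1 m⁻¹ (deeper ice); LLT/HLT site classification at 5% incoming
   PAR; equilibrium brine salinity $S_b = 1000(1-54.11/T)^{-1}$ and
   Frankenstein–Garner brine volume $V_b(\text{‰}) = S(49.185/|T|+0.532)$.
2. **Spectral preprocessing** — Savitzky–Golay smoothed second derivative
   (9-point window, 3rd-order polynomial) scaled to $d^2A/d\tilde\nu^2$,
   then Standard Normal Variate normalization per spectrum.
3. **Band quantification** — 11 assigned bands (3011…1080 cm⁻¹) integrated
   per measured point over zero-crossing-bounded windows of the negated
   second derivative; points averaged to per-cell relative contents.
4. **Statistics** — Spearman correlation structure, standardized PCA,
   per-taxon OLS of log₁₀(site-mean area) on % incoming PAR with 95% CI,
   fixed-factor (LLT vs HLT) biomolecule-pair regressions with a
   nested-model F-test, Shapiro–Wilk normality gating, Welch group
   comparison, Breusch–Pagan residual diagnostics.
5. **Synthetic campaign generator** — single-cell spectra with a
   configurable taxon × band light-response structure (2× lipid/fatty-acid
   rise saturating at 15% incoming PAR, one non-saturating taxon, flat
   protein, declining carboxylated signal), lognormal cell/point
   variability, polynomial baseline + background hump, additive noise —
   so the entire chain is testable end-to-end with known ground truth.

## Worked example

Derive the under-ice light climate and brine state of the six sampled
sites, then run the synthetic campaign through the whole chain:

```r
library(iceftir)

sites <- read.delim(system.file("extdata", "site_table.tsv", package = "iceftir"))
derive_site_environment(sites, depth_unit = "cm")[,
  c("station_id", "light_pct", "transmitted_par", "light_class",
    "brine_salinity", "brine_volume_pct")]
#>   station_id light_pct transmitted_par light_class brine_salinity brine_volume_pct
#> 1       VM-1     1.530           9.791         LLT          37.36           15.570
#> 2       VM-2     1.304           8.343         LLT          39.07           24.491
#> 3       VM-3     4.328          27.701         LLT          39.07           23.804
#> 4       VM-4    10.026          64.166         HLT          37.36            8.863
#> 5       VM-5    15.259          97.658         HLT          39.07           12.818
#> 6       TF-2    23.224         148.631         HLT          47.53           17.249
```

Snow, not ice, dominates the gradient: the deepest-snow site receives 1.5%
of surface PAR, the thinnest-snow site 23.2% — transmitted irradiances of
roughly 8–149 µmol m⁻² s⁻¹ under a 640 µmol m⁻² s⁻¹ surface. Brine volumes
all exceed the ~5% habitability threshold.

```r
ds   <- synth_dataset(synthetic_config(seed = 1))      # ~1400 point spectra, 312 cells
prep <- preprocess_set(ds$spectra)                     # SG 2nd derivative + SNV
prof <- profile_cells(prep$spectra)$profiles           # 312 cells x 11 bands
light_response_fit(prof, "lipid_ester", taxon = "Haslea spp.", max_light = 15.5)[
  c("slope", "F", "df", "p", "r_squared")]
#> $slope
#> [1] 0.02937
#> $F
#> [1] 111.1
#> $df
#> [1] 1 3
#> $p
#> [1] 0.001833
#> $r_squared
#> [1] 0.9737
```

The fitted below-saturation lipid (ester carbonyl, 1744 cm⁻¹) response is
strongly positive — the generator's configured doubling between low- and
high-light regimes — while the same fit for protein (amide II) is flat and
non-significant, and the lipid–carbohydrate pair regression improves
significantly when split into LLT and HLT groups.

The same workflow, as numbered scripts with narrative output, lives under
`analysis/` (`01_light_ice_physics.R` → `04_statistics.R`, writing tables
under `results/`), and `run_pipeline(pipeline_config(seed = 1))` executes
the whole chain into one output directory with a checksummed manifest.

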