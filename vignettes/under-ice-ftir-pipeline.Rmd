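---
title: "From under-ice light to single-cell biomolecular profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From under-ice light to single-cell biomolecular profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iceftir)
```

`iceftir` implements a complete analysis chain for studying how under-ice
light availability shapes the biomolecular composition of sea-ice diatoms
measured by single-cell synchrotron FTIR microspectroscopy. This vignette is
the package's own account of the models it implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open.

## The light model

Irradiance transmitted through snow and sea ice follows the exponential
attenuation law per layer, $E_Z = E_0 \exp(-K_d Z)$, applied with three
diffuse attenuation coefficients: $20\,\mathrm{m^{-1}}$ for snow,
$5\,\mathrm{m^{-1}}$ for the top 10 cm of ice (the most scattering, often
granular layer), and $1\,\mathrm{m^{-1}}$ for the ice below. Transmittance is
therefore

$$T(s, h) = e^{-20 s}\; e^{-5 \min(h, 0.1)}\; e^{-1 \max(h - 0.1, 0)},$$

with snow depth $s$ and ice thickness $h$ in metres. The model is
layer-separable and continuous in $h$: ice thinner than 10 cm is attenuated
with the top-layer coefficient over its actual thickness only. Sites are
classed by transmitted fraction at a 5% boundary — low light-transmissivity
(LLT) strictly below or at 5%, high (HLT) above; the boundary itself is
assigned to LLT because the low class is defined by a strict "< 5%"
inequality. Working units are SI metres internally; table readers accept the
centimetre columns of field core logs with an explicit unit declaration.
Percentages are reported to one decimal, matching field-table precision,
while internal values keep full precision.

The brine state of the bottom ice uses two standard relations:
equilibrium brine salinity $S_b = 1000\,(1 - 54.11/T)^{-1}$ ppt for ice
temperature $T$ in °C, and the Frankenstein–Garner brine volume
$V_b(\text{‰}) = S\,(49.185/|T| + 0.532)$ for bulk salinity $S$, reported as
percent of ice volume. Both are applied inside their validity range
($-22.9 \le T < 0$ °C) with a warning outside it. These specific forms were
selected because they reproduce the derived brine columns of the study's
site table exactly at printed precision.

Two reproducibility notes. First, recomputing transmittance from the
*rounded* snow/ice means gives 4.3%, 10.0% and 15.3% for three mid-gradient
sites against printed 4.2%, 10.3% and 15.2% — consistent with the original
derivation using unrounded means; the package does not force agreement for
those sites. Second, the transmitted-PAR range endpoint reproduces the
printed 148 µmol m⁻² s⁻¹ only when computed from the printed (rounded)
transmittance of 23.2%; full precision gives 149.

## The spectral conditioning chain

Raw single-point absorbance spectra on a uniform 4000–800 cm⁻¹ grid are
smoothed and differentiated in a single combined Savitzky–Golay pass:
9-point window (4 points either side), third-order polynomial, second
derivative. One pass rather than separate smoothing and differentiation is
the standard chemometric reading of that parameterization, and it is what
the band integrator assumes. The output is scaled by the inverse square of
the grid step so it approximates $d^2A/d\tilde\nu^2$ and is independent of
digitization density; relative band areas, the only quantity used
downstream, are unaffected by any common factor. The half-window of points
at each grid edge, where the filter is not a pure interior convolution, is
dropped — every assigned band sits more than 50 cm⁻¹ from the grid edges.
The second derivative is what suppresses smooth baselines and scatter humps:
a degree-2 polynomial background vanishes identically, and broad features are
attenuated roughly as the inverse square of their width.

Standard Normal Variate (SNV) normalization then centres each spectrum to
mean zero and scales it to unit standard deviation over the analysis range.
The population SD convention (divide by $n$) is used; the choice affects
only a constant factor common to all bands of a spectrum. Spectra that are
constant after differentiation cannot be normalized; they are rejected and
reported, never silently dropped. The wavenumber range over which the SNV
statistics are computed is not fixed by convention; the package defaults to
the full measured range and allows restriction (e.g. to
3050–2800 + 1770–1000 cm⁻¹) through `preprocess_params(analysis_range=)`.

State is tracked explicitly (`raw → second_derivative → normalized`), and
applying a transform to a spectrum in the wrong state is an error: no
double-processing can occur.

## Band quantification

Eleven assigned bands (3011, 2960, 2921, 2852, 1744, 1549, 1400, 1377,
1241, 1146 and 1080 cm⁻¹ — unsaturated fatty acids through silica) are
integrated per measured point. After the second derivative, absorbance
maxima appear as minima, so the integration window for a band is anchored on
the local minimum within ±8 cm⁻¹ of the nominal centre and bounded by the
flanking zero crossings of the signal, capped at a fixed half-width
(12 cm⁻¹ default). Zero-crossing bounds are the standard
derivative-spectroscopy choice and tolerate small centre shifts between
taxa. If no genuine dip exists near the centre, or the crossing-bounded
window is narrower than a physically plausible band (8 cm⁻¹), the spectrum
is treated as noise-like for that band: the fixed window is used and a QC
flag recorded. The signed trapezoid integral of the *negated* signal is
reported, so stronger absorbance gives larger positive relative content;
negative areas can occur under noise and are not clipped — downstream
log-transform steps exclude non-positive values with a logged count rather
than adding an arbitrary offset.

Because absorption coefficients differ between biomolecules, integrated
areas are relative quantities: comparable across cells and sites *within* a
band, never across bands. Measurement points are aggregated to cells by the
unweighted mean (the study counts cells, not points, and does not state the
rule; the per-point alternative is exposed via `aggregate = "point"`).
Whether integration was performed on the normalized derivative or on raw
absorbance is likewise not fully explicit in the field protocol; the stated
processing order implies the former, which is what the package does, and the
linearity of the whole chain is verified against known amplitudes with SNV
disabled.

## The synthetic campaign generator

The generator produces pipeline-ready raw spectra whose band amplitudes
follow a configurable taxon × band light-response structure, together with
the ground truth needed for parameter-recovery tests. Defaults emulate the
study design:

* six sites whose snow/ice geometry spans ~1.3–23.2% transmitted PAR, with
  surface PAR 640 µmol m⁻² s⁻¹;
* five taxa; 1–20 cells per taxon per site (uniform draw); 3–6 points per
  cell; a 2 cm⁻¹ grid over 4000–800 cm⁻¹ (instrument resolution is 4 cm⁻¹;
  digitization is typically finer);
* per-band response $a + b\,\min(L, L_{sat})$ with $L_{sat} = 15\%$ for the
  photosynthate bands (lipids, fatty acids, carbohydrates), parameterized so
  the amplitude at 10% PAR is exactly twice that at 1.5% ($b = a/7$);
  Navicula spp. is the non-saturating taxon; protein is flat; carboxylated
  molecules decline with light in all taxa, phosphorylated molecules in four
  of five; silica *increases* with light (the direction shown by the
  per-taxon silica regressions; the generator exposes the sign because the
  narrative elsewhere describes it in the opposite orientation);
* Gaussian band shapes (adequate for second-derivative separation at this
  sampling), fixed per-band widths of 10–20 cm⁻¹;
* mean-one lognormal multiplicative variability per band: cell-to-cell
  σ = 0.25 and point-to-point σ = 0.10 (points across one cell vary less
  than cells do — the reason multiple points per cell are measured);
* a degree-2 polynomial baseline with small random coefficients plus one
  broad background hump (σ ≈ 200 cm⁻¹), deliberately present so the
  derivative transform has something real to defeat; additive Gaussian
  noise of 0.005 absorbance units.

Two strong *light-invariant* background bands (amide I / water bending
complex near 1655 cm⁻¹ and amide A / O–H stretch near 3290 cm⁻¹) are part of
the forward model, an order of magnitude above the marker bands. This
mirrors real hydrated-cell spectra, where the marker bands are minor
features of the total absorbance, and it matters statistically: SNV divides
each spectrum by its own SD, so if the light-responsive bands dominated that
denominator, normalization would transfer part of their response onto every
other band (compositional closure). With realistic dominant background
features the closure bias on a flat band is small
(≈ −0.002 log₁₀ units per %PAR) — but not zero; see Limitations.

The generator does **not** emulate Mie or resonant scattering artefacts,
water-vapour rotational lines, aperture diffraction, or atmospheric
correction residues. Passing recovery tests therefore demonstrates the
statistical fidelity of the chain under controlled optics, not robustness
to every real-beamline artefact.

## The statistical layer

All analyses operate on per-cell profiles. A Shapiro–Wilk gate (α = 0.05)
decides raw versus log₁₀ scale; in practice lognormal cell variability sends
band areas down the log path, matching the field protocol. Correlation
structure uses Spearman's rank coefficient over all cells pooled. Ordination
is PCA on the standardized (correlation) matrix — band areas have
heterogeneous scales across biomolecules — with a deterministic sign
convention (the largest-magnitude loading of each component is positive).

Light-response fits are ordinary least squares of log₁₀(site-mean area) on
percent incoming PAR, one point per site, with a 95% confidence band.
Biomolecule-pair fits (lipid–carbohydrate, lipid–protein,
carbohydrate–protein) are cell-level, fitted separately for LLT and HLT
groups; the "fixed factor" claim — that splitting by light regime improves
the model — is made operational as a nested-model F-test of the two-line
model against the pooled single line. (An information-criterion comparison
would be the main alternative; the F-test was chosen because the original
inference is F-based throughout.) Only per-group fits whose own F-test is
significant are flagged reportable. The site-mean versus cell-level split
follows the granularity at which each analysis is displayed in the source
study (per-site means against light; cell scatter for pairs).

Confidence bands are truncated, not suppressed entirely, when a site
contributes fewer than three cells: the band stops at the last well-populated
light level (mirroring the study's decision to show no interval beyond 15.2%
incoming PAR where two taxa were sparse). The two-group isotope comparison
uses Welch's t with Welch–Satterthwaite degrees of freedom, floored for
reporting — consistent with the printed t(2) at n = 3 per group; the
closed-form summary version reproduces t ≈ 4.0 from the printed means and
SDs, with exact agreement not expected from rounded inputs. Residuals are
checked with a Breusch–Pagan score test, advisory only, with a low-power
flag below n = 10. The significance threshold is 0.05 throughout and no
multiple-testing correction is applied, matching the source protocol — a
documented limitation, not an endorsement.

## Numerical and reproducibility choices

* Uniform-grid enforcement at $10^{-6}$ relative tolerance; descending
  (instrument-convention) wavenumber columns are accepted and stored
  ascending.
* The SG + SNV + integration chain is linear/affine-equivariant where it
  should be, and these properties are tested as invariants rather than on
  single examples.
* One master seed drives everything; per-stage child seeds are derived by a
  fixed affine rule modulo $2^{31}-1$, so stages are individually
  re-runnable and a full pipeline run is byte-reproducible (verified by
  output checksums).
* Written tables are formatted to 12 significant digits to make checksums
  platform-stable.

## Problem sizes used in the shipped analyses

The demonstration pipeline and the recovery simulations run at the study's
own design (six sites, five taxa, 1–20 cells per taxon per site, 3–6 points
per cell, ~1400 point spectra per campaign). The end-to-end recovery
simulation uses 50 seeded replicates of that design; the null calibration of
the fixed-factor improvement test uses 500 replicates at the model level
(where the test's operating characteristics, not the optics, are in
question). Coverage and type-I checks of the regression layer use 100
direct-profile replicates.

## Known limitations

* **SNV closure.** Per-spectrum normalization makes band areas weakly
  compositional. With the default generator this leaves a residual trend of
  about −0.002 log₁₀ units per %PAR on a truly flat band — invisible to
  per-taxon site-mean regressions (5–6 points), but a test pooling all taxa
  and cells has enough power to flag it as a (spurious) decline roughly
  three times more often than the nominal 5%. Conclusions about flat
  responses should therefore rest on the per-taxon fits, which is how the
  package reports them.
* **Power at the study's own design.** With 1–20 cells per taxon per site
  and lognormal cell variability, a per-taxon site-mean regression on five
  below-saturation sites detects the 2× lipid effect in ~86% of
  (replicate, taxon) draws, not ~100%: single-cell sites are permitted by
  the design and do occur. The package reports this honestly rather than
  resizing the simulated campaign.
* The brine relations are inferred from exact agreement with the study's
  derived table, not stated in its methods; they are standard forms, but
  alternative parameterizations exist.
* No curve-fitting deconvolution of overlapping bands, no absolute
  concentration calibration, and no cross-band indices beyond explicitly
  dimensionless ones: relative-within-band semantics are enforced by
  design.
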