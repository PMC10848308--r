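#' Default infrared band registry for single-cell diatom spectra
#'
#' The eleven band assignments used to quantify relative biomolecular content
#' from second-derivative FTIR spectra: nominal band centres (cm^-1), the
#' biomolecule each reports on, and the window policy used to bound the
#' integrated area.
#'
#' @return Data frame with columns `centre` (cm^-1), `label` (short key used
#'   as profile column name), `biomolecule` (description), `window_policy`
#'   (`"zero_crossing"` or `"fixed_halfwidth"`), `half_width` (cm^-1 cap for
#'   the zero-crossing search / fallback width).
#' @export
default_band_registry <- function() {
  data.frame(
    centre = c(3011, 2960, 2921, 2852, 1744, 1549, 1400, 1377, 1241, 1146, 1080),
    label = c("unsat_fa", "methyl_lipid_protein", "sat_lipid_2921",
              "sat_lipid_2852", "lipid_ester", "protein_amide2",
              "carboxylate", "lipid_ch2", "phosphoryl", "carbohydrate",
              "silica"),
    biomolecule = c(
      "unsaturated fatty acids (cis C=CH stretch)",
      "methyl groups of lipids and proteins",
      "saturated lipids (CH2 asym. stretch)",
      "saturated lipids (CH2 sym. stretch)",
      "lipid ester carbonyl / fatty acids",
      "protein amide II",
      "carboxylated molecules (COO- sym. stretch)",
      "lipids/proteins CH bend (CH-stretch II family)",
      "phosphorylated molecules (PO2- asym. stretch)",
      "carbohydrates (C-O stretch)",
      "silica (Si-O stretch)"),
    window_policy = "zero_crossing",
    half_width = 12,
    stringsAsFactors = FALSE
  )
}

#' Read a band registry from TSV
#'
#' @param path TSV file with at least `centre` and `label` columns;
#'   `window_policy` and `half_width` default to zero-crossing / 12 cm^-1.
#' @return Validated band registry data frame.
#' @export
read_band_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(reg$window_policy)) reg$window_policy <- "zero_crossing"
  if (is.null(reg$half_width)) reg$half_width <- 12
  validate_band_registry(reg)
}

#' @keywords internal
validate_band_registry <- function(reg) {
  if (!all(c("centre", "label") %in% names(reg)))
    stop("band registry needs 'centre' and 'label' columns")
  if (anyDuplicated(reg$centre))
    stop("band centres must be unique")
  if (!all(reg$window_policy %in% c("zero_crossing", "fixed_halfwidth")))
    stop("window_policy must be 'zero_crossing' or 'fixed_halfwidth'")
  if (any(reg$half_width <= 0)) stop("half_width must be > 0")
  reg
}
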