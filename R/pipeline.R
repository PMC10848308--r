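# End-to-end pipeline binding: configuration, table validation, and the
# simulate -> preprocess -> quantify -> analyze driver with a run manifest.

#' Build a pipeline configuration
#'
#' One seed governs every source of randomness; per-stage child seeds are
#' derived from it by a fixed rule so stages are individually re-runnable.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if absent).
#' @param synthetic A [synthetic_config()] or NULL to use defaults (its seed
#'   is overridden by the derived stage seed).
#' @param preprocessing A [preprocess_params()].
#' @param bands Band registry data frame.
#' @param alpha Significance level for the statistical layer.
#' @param ci_level Confidence level for regression bands.
#' @param group_threshold_pct LLT/HLT boundary, percent incoming PAR.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("iceftir_run_"),
                            synthetic = NULL,
                            preprocessing = preprocess_params(),
                            bands = default_band_registry(),
                            alpha = 0.05, ci_level = 0.95,
                            group_threshold_pct = 5) {
  if (is.null(synthetic)) synthetic <- synthetic_config()
  stopifnot(inherits(synthetic, "synthetic_config"),
            inherits(preprocessing, "preprocess_params"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  bands <- validate_band_registry(bands)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synthetic = synthetic, preprocessing = preprocessing,
                 bands = bands, alpha = alpha, ci_level = ci_level,
                 group_threshold_pct = group_threshold_pct),
            class = "pipeline_config")
}

#' Derive a per-stage child seed from the master seed
#'
#' @param seed Master seed.
#' @param stage Stage index (1 = simulate, ...).
#' @return Integer child seed, stable across runs.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * stage) %% 2147483647)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `seed`, `out_dir`, `alpha`, `ci_level`,
#' `group_threshold_pct`, and under `synthetic`: `cells_per_site`,
#' `points_per_cell`, `noise_sd`, `cell_sigma`, `point_sigma`, `grid_step`.
#' Unspecified keys keep package defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic[intersect(names(y$synthetic),
                                    names(formals(synthetic_config)))]
  syn <- do.call(synthetic_config, syn_args %||% list())
  args <- y[intersect(names(y), c("seed", "out_dir", "alpha", "ci_level",
                                  "group_threshold_pct"))]
  do.call(pipeline_config, c(args, list(synthetic = syn)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a tabular input against a named schema
#'
#' Checks required columns, types and ranges for the pipeline's table
#' dialects, aggregating every violation into one error rather than failing
#' on the first.
#'
#' @param x Data frame or path to a TSV file.
#' @param schema One of `"sites"`, `"metadata"`, `"profiles"`.
#' @param reference For `"metadata"`: character vector of point ids present
#'   in the spectra file; metadata rows referencing absent points are
#'   reported as referential errors.
#' @return The validated data frame, invisibly; stops with the aggregated
#'   error list otherwise.
#' @export
validate_table <- function(x, schema = c("sites", "metadata", "profiles"),
                           reference = NULL) {
  schema <- match.arg(schema)
  if (is.character(x)) {
    if (!file.exists(x)) stop("cannot read table: ", x)
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  errs <- character()
  req <- switch(schema,
    sites = c("station_id", "snow_depth", "ice_thickness"),
    metadata = c("point_id", "cell_id", "taxon", "station_id"),
    profiles = c("cell_id", "taxon", "station_id", "light_pct"))
  miss <- setdiff(req, names(x))
  if (length(miss))
    errs <- c(errs, paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (schema == "sites") {
      for (col in c("snow_depth", "ice_thickness"))
        if (any(bad <- x[[col]] < 0))
          errs <- c(errs, paste0(col, " negative in row(s) ",
                                 paste(which(bad), collapse = ", ")))
      if (!is.null(x$ice_temperature) && any(bad <- x$ice_temperature >= 0))
        errs <- c(errs, paste0("ice_temperature must be < 0 degC in row(s) ",
                               paste(which(bad), collapse = ", ")))
      if (!is.null(x$bulk_salinity) && any(bad <- x$bulk_salinity < 0))
        errs <- c(errs, paste0("bulk_salinity negative in row(s) ",
                               paste(which(bad), collapse = ", ")))
    }
    if (schema == "metadata") {
      if (anyDuplicated(x$point_id))
        errs <- c(errs, "duplicate point_id values")
      if (!is.null(reference)) {
        orphan <- setdiff(x$point_id, reference)
        if (length(orphan))
          errs <- c(errs, paste0("metadata references absent point(s): ",
                                 paste(utils::head(orphan, 5), collapse = ", ")))
      }
    }
    if (schema == "profiles") {
      if (any(bad <- x$light_pct < 0))
        errs <- c(errs, paste0("light_pct negative in row(s) ",
                               paste(which(bad), collapse = ", ")))
    }
  }
  if (length(errs))
    stop("table failed '", schema, "' validation:\n  - ",
         paste(errs, collapse = "\n  - "))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Simulate (synthetic field dataset) -> preprocess (Savitzky-Golay second
#' derivative + SNV) -> quantify (band areas to cell profiles) -> analyze
#' (correlations, ordination, light-response and fixed-factor regressions).
#' All stage outputs are written under `config$out_dir` and summarized in a
#' run manifest whose checksums are identical for identical config + seed.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly; side effect: `sites.tsv`,
#'   `spectra.csv`, `metadata.tsv`, `truth.tsv`, `profiles.tsv`,
#'   `qc_report.tsv`, `correlations.tsv`, `pca_scores.tsv`,
#'   `pca_loadings.tsv`, `regressions.json`, `manifest.json` in the output
#'   directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)

  # -- simulate ---------------------------------------------------------
  syn <- config$synthetic
  syn$seed <- derive_seed(config$seed, 1L)
  ds <- synth_dataset(syn)
  write_tsv(format_num_df(ds$sites), od("sites.tsv"))
  write_spectra_csv(ds$spectra, od("spectra.csv"))
  write_tsv(ds$spectra$meta, od("metadata.tsv"))
  write_tsv(format_num_df(ds$truth), od("truth.tsv"))

  # -- preprocess -------------------------------------------------------
  prep <- preprocess_set(ds$spectra, config$preprocessing)
  if (nrow(prep$rejected))
    write_tsv(prep$rejected, od("rejections.tsv"))

  # -- quantify ---------------------------------------------------------
  prof <- profile_cells(prep$spectra, config$bands,
                        full_meta = ds$spectra$meta)
  write_tsv(format_num_df(prof$profiles), od("profiles.tsv"))
  write_tsv(prof$qc, od("qc_report.tsv"))

  # -- analyze ----------------------------------------------------------
  p <- prof$profiles
  rho <- spearman_matrix(p)
  write_tsv(format_num_df(data.frame(label = rownames(rho), rho,
                                     check.names = FALSE)),
            od("correlations.tsv"))
  pca <- pca_biomolecules(p)
  write_tsv(format_num_df(data.frame(cell_id = p$cell_id,
                                     pca$scores[, 1:2, drop = FALSE])),
            od("pca_scores.tsv"))
  write_tsv(format_num_df(data.frame(label = rownames(pca$loadings),
                                     pca$loadings[, 1:2, drop = FALSE],
                                     check.names = FALSE)),
            od("pca_loadings.tsv"))

  taxa <- unique(p$taxon)
  bands <- config$bands$label
  light_fits <- list()
  for (tx in taxa) for (b in bands) {
    r <- tryCatch(light_response_fit(p, b, taxon = tx,
                                     ci_level = config$ci_level),
                  error = function(e) NULL)
    if (!is.null(r)) {
      r$model <- NULL
      light_fits[[paste(tx, b, sep = "|")]] <- r
    }
  }
  pairs <- list(c("lipid_ester", "carbohydrate"),
                c("lipid_ester", "protein_amide2"),
                c("carbohydrate", "protein_amide2"))
  pair_fits <- lapply(pairs, function(pr) {
    f <- fixed_factor_fit(p, pr[1], pr[2], alpha = config$alpha,
                          threshold_pct = config$group_threshold_pct)
    for (g in c("LLT", "HLT")) if (!is.null(f[[g]])) f[[g]]$model <- NULL
    f
  })
  names(pair_fits) <- vapply(pairs, paste, "", collapse = "_vs_")
  jsonlite::write_json(list(light_response = light_fits,
                            fixed_factor = pair_fits),
                       od("regressions.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")

  # -- manifest ---------------------------------------------------------
  outputs <- c("sites.tsv", "spectra.csv", "metadata.tsv", "truth.tsv",
               "profiles.tsv", "qc_report.tsv", "correlations.tsv",
               "pca_scores.tsv", "pca_loadings.tsv", "regressions.json")
  sums <- tools::md5sum(vapply(outputs, od, ""))
  names(sums) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("iceftir")),
    seed = config$seed,
    n_sites = nrow(ds$sites), n_taxa = length(taxa),
    n_cells = nrow(prof$profiles), n_points = n_spectra(ds$spectra),
    n_rejected_points = nrow(prep$rejected),
    checksums = as.list(sums))
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# Format numeric columns to a fixed significant-digit text representation so
# written tables are byte-identical across platforms for the same inputs.
#' @keywords internal
format_num_df <- function(df, digits = 12) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
  df
}
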