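#' Construct a set of single-point FTIR spectra
#'
#' Container for absorbance (or transformed) spectra measured at individual
#' points on individual cells. All spectra in a set share one uniform,
#' ascending wavenumber grid; the processing state is tracked so the
#' conditioning chain (raw -> second_derivative -> normalized) cannot be
#' applied out of order or twice.
#'
#' @param wavenumbers Numeric wavenumber grid, cm^-1. Descending
#'   (instrument convention, 4000 -> 800) is accepted and stored ascending.
#' @param values Numeric matrix, one row per wavenumber, one column per
#'   measured point.
#' @param meta Data frame with one row per column of `values`; must contain
#'   `point_id`, and for quantification `cell_id`, `taxon`, `station_id`,
#'   `light_pct`.
#' @param state One of `"raw"`, `"second_derivative"`, `"normalized"`.
#' @return An object of class `ftir_set`.
#' @export
ftir_set <- function(wavenumbers, values, meta = NULL, state = "raw") {
  values <- as.matrix(values)
  if (length(wavenumbers) != nrow(values))
    stop("length(wavenumbers) must equal nrow(values)")
  state <- match.arg(state, c("raw", "second_derivative", "normalized"))
  if (is.unsorted(wavenumbers)) {
    o <- order(wavenumbers)
    wavenumbers <- wavenumbers[o]
    values <- values[o, , drop = FALSE]
  }
  step <- diff(wavenumbers)
  if (any(step <= 0)) stop("wavenumber grid must be strictly monotone")
  if (diff(range(step)) > 1e-6 * mean(step))
    stop("wavenumber grid must be uniform; resample before constructing an ftir_set")
  if (is.null(meta))
    meta <- data.frame(point_id = paste0("pt", seq_len(ncol(values))),
                       stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(values))
    stop("meta must have one row per spectrum column")
  colnames(values) <- meta$point_id
  structure(list(wavenumbers = as.numeric(wavenumbers), values = values,
                 meta = meta, state = state),
            class = "ftir_set")
}

#' @export
print.ftir_set <- function(x, ...) {
  cat(sprintf("<ftir_set> %d spectra x %d wavenumbers (%g-%g cm^-1), state: %s\n",
              ncol(x$values), nrow(x$values),
              min(x$wavenumbers), max(x$wavenumbers), x$state))
  invisible(x)
}

#' Number of spectra in a set
#' @param x An `ftir_set`.
#' @return Integer count of measured points.
#' @export
n_spectra <- function(x) ncol(x$values)

#' Subset an ftir_set by spectrum (column)
#' @param x An `ftir_set`.
#' @param i Column index/logical/point-id selector.
#' @param ... Unused.
#' @export
`[.ftir_set` <- function(x, i, ...) {
  ftir_set(x$wavenumbers, x$values[, i, drop = FALSE],
           x$meta[match(colnames(x$values[, i, drop = FALSE]), x$meta$point_id), ,
                  drop = FALSE],
           state = x$state)
}

#' Write a spectra matrix to CSV
#'
#' Wide-matrix dialect: column 1 is the wavenumber (written descending,
#' 4000 -> 800, the instrument convention), one column per measured point.
#'
#' @param x An `ftir_set`.
#' @param path Output CSV path.
#' @export
write_spectra_csv <- function(x, path) {
  o <- order(x$wavenumbers, decreasing = TRUE)
  df <- data.frame(wavenumber = x$wavenumbers[o],
                   x$values[o, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectra matrix from CSV
#'
#' Accepts ascending or descending wavenumber order; spectra are stored
#' ascending internally.
#'
#' @param path CSV with wavenumber first column.
#' @param meta Optional metadata data frame (see [ftir_set()]); matched to
#'   columns by `point_id`.
#' @param state Processing state of the stored values (default `"raw"`).
#' @return An `ftir_set`.
#' @export
read_spectra_csv <- function(path, meta = NULL, state = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  wn <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.null(meta)) {
    idx <- match(colnames(vals), meta$point_id)
    if (anyNA(idx))
      stop("metadata is missing point ids: ",
           paste(utils::head(colnames(vals)[is.na(idx)]), collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
  }
  ftir_set(wn, vals, meta, state = state)
}
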