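# Band-window location and integration on normalized second-derivative
# spectra. Absorbance maxima appear as minima after the second derivative,
# so windows are anchored on the local minimum near the nominal centre and
# bounded by the flanking zero crossings of the signal (capped at a fixed
# half-width), and the negated signal is integrated.

# Window + area for every spectrum column x every band; the shared engine
# behind locate_band_window / integrate_band / profile_cells.
#' @keywords internal
band_areas <- function(x, bands, search_halfwidth = 8, min_window = 8) {
  stopifnot(inherits(x, "ftir_set"))
  if (!x$state %in% c("normalized", "second_derivative"))
    stop("band quantification expects second-derivative or normalized ",
         "spectra (state is '", x$state, "')")
  wn <- x$wavenumbers
  npts <- ncol(x$values)
  nb <- nrow(bands)
  areas <- matrix(NA_real_, npts, nb,
                  dimnames = list(colnames(x$values), bands$label))
  fallback <- matrix(FALSE, npts, nb,
                     dimnames = dimnames(areas))
  for (b in seq_len(nb)) {
    centre <- bands$centre[b]
    hw <- bands$half_width[b]
    if (centre < min(wn) || centre > max(wn))
      stop("band centre ", centre, " cm^-1 outside the measured range")
    cap <- which(wn >= centre - hw & wn <= centre + hw)
    srch <- which(wn >= centre - search_halfwidth &
                  wn <= centre + search_halfwidth)
    use_zc <- identical(bands$window_policy[b], "zero_crossing")
    for (j in seq_len(npts)) {
      v <- x$values[, j]
      win <- band_window_idx(v, wn, srch, cap, use_zc, min_window)
      fallback[j, b] <- win$fallback
      areas[j, b] <- pracma::trapz(wn[win$sel], -v[win$sel])
    }
  }
  list(areas = areas, fallback = fallback)
}

# Window selection for one spectrum and one band: local minimum of the
# second-derivative signal near the centre, bounded by flanking zero
# crossings and capped at the fixed half-width. No dip at all, or a window
# narrower than a physically plausible band (min_window, cm^-1 equivalent in
# grid points), marks the spectrum as noise-like for this band: the fixed
# half-width window is used and flagged.
#' @keywords internal
band_window_idx <- function(v, wn, srch, cap, use_zc, min_window) {
  i_min <- srch[which.min(v[srch])]
  if (!use_zc)
    return(list(sel = cap, fallback = FALSE))
  if (v[i_min] >= 0)
    return(list(sel = cap, fallback = TRUE))
  lo_cand <- cap[cap < i_min]
  hi_cand <- cap[cap > i_min]
  nn_lo <- lo_cand[v[lo_cand] >= 0]
  nn_hi <- hi_cand[v[hi_cand] >= 0]
  lo <- if (length(nn_lo)) max(nn_lo) else min(cap)
  hi <- if (length(nn_hi)) min(nn_hi) else max(cap)
  if (wn[hi] - wn[lo] < min_window)
    return(list(sel = cap, fallback = TRUE))
  list(sel = lo:hi, fallback = FALSE)
}

#' Locate the integration window for one band
#'
#' Finds the local minimum of the normalized second-derivative signal within
#' +/- 8 cm^-1 of the nominal band centre and bounds the window at the
#' flanking zero crossings, capped at the band's fixed half-width (default
#' 12 cm^-1). If the signal shows no negative dip near the centre (e.g. pure
#' noise) the fixed half-width window is used and flagged.
#'
#' @param x An `ftir_set` in state `"normalized"` containing one spectrum
#'   (or use `column` to select one).
#' @param band One row of a band registry (see [default_band_registry()]).
#' @param column Spectrum column to use (default 1).
#' @return Numeric `c(lo, hi)` wavenumber bounds, with attribute `fallback`.
#' @export
locate_band_window <- function(x, band, column = 1L) {
  stopifnot(inherits(x, "ftir_set"))
  if (!x$state %in% c("normalized", "second_derivative"))
    stop("locate_band_window expects second-derivative or normalized spectra")
  wn <- x$wavenumbers
  v <- x$values[, column]
  hw <- band$half_width[1]
  centre <- band$centre[1]
  if (centre < min(wn) || centre > max(wn))
    stop("band centre ", centre, " cm^-1 outside the measured range")
  cap <- which(wn >= centre - hw & wn <= centre + hw)
  srch <- which(wn >= centre - 8 & wn <= centre + 8)
  win <- band_window_idx(v, wn, srch, cap,
                         identical(band$window_policy[1], "zero_crossing"), 8)
  out <- c(wn[min(win$sel)], wn[max(win$sel)])
  attr(out, "fallback") <- win$fallback
  out
}

#' Integrate one band window to a relative content
#'
#' Trapezoid integral of the negated second-derivative signal over the
#' window, so stronger absorbance gives a larger positive area (Beer-Lambert
#' proportionality between absorbance and analyte amount makes the area a
#' relative concentration within a band). Negative values are not clipped.
#'
#' @param x An `ftir_set` in state `"normalized"`.
#' @param window Numeric `c(lo, hi)` wavenumber bounds.
#' @param column Spectrum column to integrate (default 1).
#' @return Signed area (relative content, arbitrary units).
#' @export
integrate_band <- function(x, window, column = 1L) {
  stopifnot(inherits(x, "ftir_set"))
  if (!x$state %in% c("normalized", "second_derivative"))
    stop("integrate_band expects second-derivative or normalized spectra")
  sel <- which(x$wavenumbers >= window[1] & x$wavenumbers <= window[2])
  if (length(sel) < 2) stop("empty band window")
  pracma::trapz(x$wavenumbers[sel], -x$values[sel, column])
}

#' Quantify per-cell relative biomolecular contents
#'
#' Integrates every registry band for every measured point and aggregates
#' points to cells by the unweighted mean, yielding one profile row per
#' cell. Because absorption coefficients differ between biomolecules, areas
#' are comparable across samples only within a band, never across bands.
#'
#' @param x An `ftir_set` in state `"normalized"` whose metadata carries
#'   `cell_id`, `taxon`, `station_id`, `light_pct`.
#' @param bands Band registry data frame (default
#'   [default_band_registry()]).
#' @param full_meta Optional metadata of all originally measured points;
#'   cells whose every point was rejected upstream are then reported in the
#'   qc table rather than silently missing.
#' @param aggregate `"cell"` (default) averages points per cell; `"point"`
#'   returns one row per measured point (points treated as replicates).
#' @return List with `profiles` (data frame: cell metadata, `n_points`,
#'   `qc_fallback_bands`, one column per band label) and `qc` (dropped-cell
#'   report).
#' @export
profile_cells <- function(x, bands = default_band_registry(),
                          full_meta = NULL,
                          aggregate = c("cell", "point")) {
  aggregate <- match.arg(aggregate)
  bands <- validate_band_registry(bands)
  need <- c("point_id", "cell_id", "taxon", "station_id", "light_pct")
  miss <- setdiff(need, names(x$meta))
  if (length(miss))
    stop("spectrum metadata is missing: ", paste(miss, collapse = ", "))
  res <- band_areas(x, bands)
  meta <- x$meta
  if (aggregate == "point") {
    profiles <- cbind(meta[, need], n_points = 1L,
                      qc_fallback_bands = rowSums(res$fallback),
                      as.data.frame(res$areas))
    rownames(profiles) <- NULL
  } else {
    npts <- rowsum(rep(1L, nrow(meta)), meta$cell_id)
    sums <- rowsum(res$areas, meta$cell_id)
    fb <- rowsum(res$fallback + 0L, meta$cell_id)
    cells <- rownames(sums)
    first <- meta[match(cells, meta$cell_id),
                  c("cell_id", "taxon", "station_id", "light_pct")]
    profiles <- cbind(first, n_points = as.integer(npts[, 1]),
                      qc_fallback_bands = as.integer(rowSums(fb)),
                      as.data.frame(sums / npts[, 1]))
    rownames(profiles) <- NULL
  }
  qc <- data.frame(cell_id = character(), reason = character(),
                   stringsAsFactors = FALSE)
  if (!is.null(full_meta)) {
    lost <- setdiff(unique(full_meta$cell_id), unique(meta$cell_id))
    if (length(lost))
      qc <- data.frame(cell_id = lost, reason = "all points rejected",
                       stringsAsFactors = FALSE)
  }
  list(profiles = profiles, qc = qc)
}
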