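#' Preprocessing parameters for the spectral conditioning chain
#'
#' @param half_window Points either side of the centre in the Savitzky-Golay
#'   window (default 4, i.e. a 9-point window).
#' @param poly_order Savitzky-Golay polynomial order (default 3).
#' @param derivative_order Derivative order (default 2).
#' @param snv Apply Standard Normal Variate normalization after the
#'   derivative (default TRUE).
#' @param analysis_range Optional 2-column matrix of wavenumber intervals
#'   (cm^-1) to which the analysis is restricted; NULL = full measured range.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(half_window = 4L, poly_order = 3L,
                              derivative_order = 2L, snv = TRUE,
                              analysis_range = NULL) {
  window <- 2L * as.integer(half_window) + 1L
  if (window <= poly_order)
    stop("window length (2*half_window + 1) must exceed poly_order")
  if (derivative_order > poly_order)
    stop("derivative_order must be <= poly_order")
  if (!is.null(analysis_range)) {
    analysis_range <- matrix(as.numeric(analysis_range), ncol = 2)
    if (any(analysis_range[, 2] <= analysis_range[, 1]))
      stop("analysis_range intervals must be increasing")
  }
  structure(list(half_window = as.integer(half_window),
                 poly_order = as.integer(poly_order),
                 derivative_order = as.integer(derivative_order),
                 snv = isTRUE(snv), analysis_range = analysis_range),
            class = "preprocess_params")
}

#' Savitzky-Golay smoothed second derivative
#'
#' Single combined Savitzky-Golay pass (default 9-point window, third-order
#' polynomial, second derivative), scaled by the grid step so the output
#' approximates d2A/dnu2 and is independent of digitization density. The
#' half-window of points at each grid edge, where the filter is not a pure
#' interior convolution, is dropped; all assigned bands sit well inside the
#' measured range.
#'
#' @param x An `ftir_set` in state `"raw"`.
#' @param p A [preprocess_params()] object.
#' @return An `ftir_set` in state `"second_derivative"` on the edge-trimmed
#'   grid.
#' @export
savgol_second_derivative <- function(x, p = preprocess_params()) {
  stopifnot(inherits(x, "ftir_set"))
  if (x$state != "raw")
    stop("savgol_second_derivative expects a raw spectrum set (state is '",
         x$state, "'); spectra must not be processed twice")
  n <- 2L * p$half_window + 1L
  if (nrow(x$values) < n)
    stop("spectrum shorter than the Savitzky-Golay window (", n, " points)")
  step <- mean(diff(x$wavenumbers))
  # interior FIR row of the Savitzky-Golay projection matrix, applied to
  # all spectra at once; edge rows are dropped below so only the pure
  # interior convolution survives
  fir <- signal::sgolay(p = p$poly_order, n = n,
                        m = p$derivative_order)[p$half_window + 1L, ]
  d2 <- stats::filter(x$values, fir / step^p$derivative_order,
                      method = "convolution", sides = 2)
  keep <- (p$half_window + 1L):(nrow(x$values) - p$half_window)
  d2 <- matrix(d2[keep, , drop = FALSE], ncol = ncol(x$values),
               dimnames = list(NULL, colnames(x$values)))
  ftir_set(x$wavenumbers[keep], d2, x$meta,
           state = "second_derivative")
}

#' Standard Normal Variate normalization
#'
#' Per-spectrum centring and scaling to zero mean and unit standard
#' deviation (population convention, divide by n) over the analysis range,
#' removing multiplicative scatter and offset differences between points.
#'
#' @param x An `ftir_set` in state `"second_derivative"`.
#' @param p A [preprocess_params()]; `p$analysis_range` restricts the points
#'   used (and retained).
#' @return An `ftir_set` in state `"normalized"`.
#' @export
snv <- function(x, p = preprocess_params()) {
  stopifnot(inherits(x, "ftir_set"))
  if (x$state != "second_derivative")
    stop("snv expects a second-derivative spectrum set (state is '",
         x$state, "')")
  keep <- rep(TRUE, length(x$wavenumbers))
  if (!is.null(p$analysis_range)) {
    keep <- rowSums(outer(x$wavenumbers, p$analysis_range[, 1], ">=") &
                    outer(x$wavenumbers, p$analysis_range[, 2], "<=")) > 0
    if (!any(keep)) stop("analysis_range excludes every grid point")
  }
  v <- x$values[keep, , drop = FALSE]
  mu <- colMeans(v)
  sdp <- sqrt(colMeans(sweep(v, 2, mu)^2))
  bad <- sdp == 0 | !is.finite(sdp)
  if (any(bad))
    stop("constant spectrum cannot be SNV-normalized: ",
         paste(colnames(v)[bad], collapse = ", "))
  out <- sweep(sweep(v, 2, mu), 2, sdp, `/`)
  ftir_set(x$wavenumbers[keep], out, x$meta, state = "normalized")
}

#' Apply the full conditioning chain to a spectrum set
#'
#' Savitzky-Golay second derivative followed by SNV, per spectrum, in that
#' order. Spectra that cannot be normalized (zero variance after the
#' derivative) are dropped and reported rather than silently discarded.
#'
#' @param x An `ftir_set` in state `"raw"`.
#' @param p A [preprocess_params()].
#' @return List with `spectra` (processed `ftir_set`) and `rejected`
#'   (data frame `point_id`, `reason`; zero rows when all spectra pass).
#' @export
preprocess_set <- function(x, p = preprocess_params()) {
  stopifnot(inherits(x, "ftir_set"))
  rejected <- data.frame(point_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (n_spectra(x) == 0)
    return(list(spectra = x, rejected = rejected))
  d2 <- savgol_second_derivative(x, p)
  keep <- rep(TRUE, length(d2$wavenumbers))
  if (!is.null(p$analysis_range))
    keep <- rowSums(outer(d2$wavenumbers, p$analysis_range[, 1], ">=") &
                    outer(d2$wavenumbers, p$analysis_range[, 2], "<=")) > 0
  v <- d2$values[keep, , drop = FALSE]
  sdp <- sqrt(colMeans(sweep(v, 2, colMeans(v))^2))
  bad <- sdp == 0 | !is.finite(sdp)
  if (any(bad)) {
    rejected <- data.frame(point_id = colnames(d2$values)[bad],
                           reason = "zero variance after second derivative",
                           stringsAsFactors = FALSE)
    d2 <- d2[!bad]
  }
  if (!p$snv)
    return(list(spectra = d2, rejected = rejected))
  if (n_spectra(d2) == 0)
    return(list(spectra = d2, rejected = rejected))
  list(spectra = snv(d2, p), rejected = rejected)
}
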