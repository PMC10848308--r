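# Statistical layer over per-cell band-area profiles: normality gating,
# Spearman correlation structure, PCA ordination, per-taxon light-response
# regressions, fixed-factor (LLT vs HLT) biomolecule-pair regressions,
# Welch group comparison and residual diagnostics.

#' Gate values through a Shapiro-Wilk normality test
#'
#' Tests the raw values for normality; if rejected (p < alpha) the values
#' are log10-transformed before analysis. Non-positive values cannot enter
#' the log path and are excluded with a count (no pseudo-offset is added).
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level of the Shapiro-Wilk test (default 0.05).
#' @return List: `scale` ("raw" or "log10"), `values` (possibly transformed,
#'   exclusions dropped), `shapiro_p`, `n_excluded`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3)
    stop("normality_gate needs at least 3 finite values")
  p <- stats::shapiro.test(values)$p.value
  if (p >= alpha)
    return(list(scale = "raw", values = values, shapiro_p = p,
                n_excluded = 0L))
  pos <- values > 0
  if (!any(pos))
    stop("log10 transform required but no positive values available")
  list(scale = "log10", values = log10(values[pos]), shapiro_p = p,
       n_excluded = sum(!pos))
}

#' Spearman rank-correlation matrix of band areas
#'
#' Pairwise Spearman rho over cells, all taxa and sites pooled; ties receive
#' average ranks.
#'
#' @param profiles Cell-profile data frame from [profile_cells()].
#' @param bands Character vector of band-label columns; default all registry
#'   labels present.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(profiles, bands = NULL) {
  if (is.null(bands))
    bands <- intersect(default_band_registry()$label, names(profiles))
  if (nrow(profiles) < 3) stop("need at least 3 cells")
  stats::cor(as.matrix(profiles[, bands, drop = FALSE]), method = "spearman")
}

#' Principal component ordination of biomolecular profiles
#'
#' PCA of the cell x band area matrix after standardization (centred, unit
#' variance per band, since bands have heterogeneous absorption scales),
#' via singular value decomposition. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param profiles Cell-profile data frame.
#' @param bands Band-label columns to use; default all present.
#' @return List: `scores` (cells x components), `loadings` (bands x
#'   components), `variance_explained` (fraction per component).
#' @export
pca_biomolecules <- function(profiles, bands = NULL) {
  if (is.null(bands))
    bands <- intersect(default_band_registry()$label, names(profiles))
  if (length(bands) < 2) stop("need at least 2 bands")
  m <- as.matrix(profiles[, bands, drop = FALSE])
  if (nrow(m) < 3) stop("need at least 3 cells")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance band(s): ", paste(bands[sds == 0], collapse = ", "))
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

# Package an lm fit into the common regression-result shape.
#' @keywords internal
regression_result <- function(model, response, predictor, group,
                              ci_band = NULL) {
  sm <- summary(model)
  fs <- sm$fstatistic
  co <- stats::coef(model)
  list(response = response, predictor = predictor, group = group,
       slope = unname(co[2]), intercept = unname(co[1]),
       F = unname(fs[1]), df = unname(c(fs[2], fs[3])),
       p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       r_squared = sm$r.squared, ci_band = ci_band,
       n = length(stats::residuals(model)), model = model)
}

#' Per-taxon light-response regression on site means
#'
#' Ordinary least squares of log10(site-mean band area) on percent incoming
#' PAR, one point per sampling site, with a 95% confidence band. When any
#' site contributes fewer than `min_cells_ci` cells, the confidence band is
#' truncated at the smallest such site's light level (data-sparse sites
#' support the fitted line but not the interval).
#'
#' @param profiles Cell-profile data frame.
#' @param band Band label (response).
#' @param taxon Optional taxon to subset to; NULL pools all taxa.
#' @param ci_level Confidence level (default 0.95).
#' @param min_cells_ci Minimum cells per site for the site to support the
#'   confidence band (default 3).
#' @param max_light Optional upper percent-PAR bound; sites above it are
#'   excluded from the fit (used to fit below a saturation threshold).
#' @return A regression result list (slope, intercept, F, df, p, r_squared,
#'   ci_band, n) for the site-mean fit.
#' @export
light_response_fit <- function(profiles, band, taxon = NULL,
                               ci_level = 0.95, min_cells_ci = 3,
                               max_light = NULL) {
  d <- profiles
  if (!is.null(taxon)) d <- d[d$taxon == taxon, , drop = FALSE]
  if (!is.null(max_light)) d <- d[d$light_pct <= max_light, , drop = FALSE]
  if (!band %in% names(d)) stop("unknown band label: ", band)
  agg <- stats::aggregate(d[[band]],
                          by = list(light_pct = d$light_pct,
                                    station_id = d$station_id),
                          FUN = mean)
  names(agg)[3] <- "mean_area"
  counts <- stats::aggregate(d[[band]],
                             by = list(station_id = d$station_id),
                             FUN = length)
  agg$n_cells <- counts$x[match(agg$station_id, counts$station_id)]
  agg <- agg[agg$mean_area > 0, , drop = FALSE]
  if (nrow(agg) < 3)
    stop("need at least 3 sites with positive mean area (have ",
         nrow(agg), ")")
  agg$y <- log10(agg$mean_area)
  fit <- stats::lm(y ~ light_pct, data = agg)
  sparse <- agg$light_pct[agg$n_cells < min_cells_ci]
  ci_max <- if (length(sparse)) min(sparse) else Inf
  grid <- agg[agg$light_pct < ci_max, , drop = FALSE]
  ci_band <- NULL
  if (nrow(agg) >= 3 && nrow(grid) >= 1) {
    pr <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = ci_level)
    ci_band <- data.frame(light_pct = grid$light_pct, fit = pr[, "fit"],
                          lwr = pr[, "lwr"], upr = pr[, "upr"])
  }
  out <- regression_result(fit, band,
                           "light_pct",
                           if (is.null(taxon)) "all" else taxon, ci_band)
  out$site_means <- agg[, c("station_id", "light_pct", "mean_area", "n_cells")]
  out
}

#' Fixed-factor (LLT vs HLT) biomolecule-pair regressions
#'
#' Cell-level regressions of one band's content on another, fitted
#' separately for the low and high light-transmissivity groups, with a
#' nested-model F-test quantifying whether splitting by light level improves
#' on a single pooled line (the "fixed factor" comparison). Both variables
#' pass through the normality gate (log10 if non-normal; non-positive cells
#' excluded with a count). A per-group fit is flagged reportable only when
#' its own F-test is significant.
#'
#' @param profiles Cell-profile data frame (`light_pct` column defines the
#'   groups via the 5% incoming-PAR threshold).
#' @param x_band,y_band Band labels for predictor and response.
#' @param alpha Significance level (default 0.05).
#' @param threshold_pct LLT/HLT boundary in percent incoming PAR (default 5).
#' @return List: `LLT`, `HLT` (regression results or NULL when n < 3, with
#'   `reportable` flags), `improvement` (F, df, p, significant) for the
#'   two-line vs pooled comparison, `transform`, `n_excluded`.
#' @export
fixed_factor_fit <- function(profiles, x_band, y_band, alpha = 0.05,
                             threshold_pct = 5) {
  for (b in c(x_band, y_band))
    if (!b %in% names(profiles)) stop("unknown band label: ", b)
  d <- profiles[, c("cell_id", "light_pct", x_band, y_band)]
  names(d)[3:4] <- c("x", "y")
  gx <- normality_gate(d$x); gy <- normality_gate(d$y)
  transform <- if (gx$scale == "log10" || gy$scale == "log10") "log10" else "raw"
  n_excluded <- 0L
  if (transform == "log10") {
    ok <- d$x > 0 & d$y > 0
    n_excluded <- sum(!ok)
    d <- d[ok, , drop = FALSE]
    d$x <- log10(d$x); d$y <- log10(d$y)
  }
  d$group <- classify_light(d$light_pct / 100, threshold = threshold_pct / 100)
  fit_group <- function(g) {
    dg <- d[d$group == g, , drop = FALSE]
    if (nrow(dg) < 3) return(NULL)
    r <- regression_result(stats::lm(y ~ x, data = dg), y_band, x_band, g)
    r$reportable <- is.finite(r$p) && r$p < alpha
    r
  }
  res <- list(LLT = fit_group("LLT"), HLT = fit_group("HLT"))
  improvement <- NULL
  if (!is.null(res$LLT) && !is.null(res$HLT)) {
    pooled <- stats::lm(y ~ x, data = d)
    split_fit <- stats::lm(y ~ x * group, data = d)
    an <- stats::anova(pooled, split_fit)
    improvement <- list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                        p = an$`Pr(>F)`[2],
                        significant = an$`Pr(>F)`[2] < alpha)
  }
  c(res, list(improvement = improvement, transform = transform,
              n_excluded = n_excluded))
}

#' Welch two-group comparison
#'
#' Welch two-sample t statistic with Welch-Satterthwaite degrees of freedom
#' (reported both exactly and floored, the integer convention used when
#' quoting `t(df)`).
#'
#' @param values_a,values_b Numeric vectors, each n >= 2.
#' @return List: `t`, `df`, `df_floor`, `p` (two-sided).
#' @export
group_mean_compare <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       df_floor = floor(unname(tt$parameter)), p = tt$p.value)
}

#' Welch comparison from summary statistics
#'
#' Closed-form Welch t from group means, standard deviations and sizes, for
#' comparisons where only the printed summaries are available.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return List: `t`, `df`, `df_floor`, `p` (two-sided).
#' @export
welch_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, df_floor = floor(df),
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Residual homoscedasticity diagnostics
#'
#' Breusch-Pagan score test of the fitted model plus a residual-vs-fitted
#' summary. Advisory only: no automatic refit is performed, and fits with
#' few observations are flagged low-power.
#'
#' @param result A regression result from this package (carrying `$model`)
#'   or an `lm` object.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return List: `bp_statistic`, `bp_df`, `bp_p`, `homoscedastic` (verdict
#'   at `alpha`), `n`, `low_power` (TRUE when n < 10),
#'   `residual_vs_fitted_cor`.
#' @export
residual_diagnostics <- function(result, alpha = 0.05) {
  model <- if (inherits(result, "lm")) result else result$model
  if (is.null(model)) stop("no fitted model to diagnose")
  bp <- lmtest::bptest(model)
  n <- length(stats::residuals(model))
  list(bp_statistic = unname(bp$statistic), bp_df = unname(bp$parameter),
       bp_p = bp$p.value, homoscedastic = bp$p.value >= alpha,
       n = n, low_power = n < 10,
       residual_vs_fitted_cor =
         stats::cor(abs(stats::residuals(model)), stats::fitted(model)))
}
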