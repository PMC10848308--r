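make_profiles <- function(n, f_light = NULL, seed = 1) {
  # direct cell-profile construction with a single latent light-driven factor
  set.seed(seed)
  light <- rep(c(1.3, 1.5, 4.3, 10.0, 15.3, 23.2), length.out = n)
  f <- if (is.null(f_light)) rep(1, n) else f_light(light)
  data.frame(cell_id = sprintf("c%03d", seq_len(n)),
             taxon = "Haslea spp.",
             station_id = rep(paste0("S", 1:6), length.out = n),
             light_pct = light,
             lipid_ester = f * exp(rnorm(n, 0, 0.1)),
             sat_lipid_2852 = f * exp(rnorm(n, 0, 0.1)),
             carbohydrate = f * exp(rnorm(n, 0, 0.1)),
             protein_amide2 = exp(rnorm(n, 0, 0.1)),
             stringsAsFactors = FALSE)
}

test_that("normality gate keeps normal data raw and logs lognormal data", {
  set.seed(50)
  raw <- normality_gate(rnorm(50))
  expect_equal(raw$scale, "raw")
  set.seed(51)
  ln <- normality_gate(rlnorm(50, sdlog = 1))
  expect_equal(ln$scale, "log10")
  expect_equal(ln$n_excluded, 0L)
  # non-positive values excluded (not offset) on the log path
  set.seed(52)
  mixed <- c(rlnorm(50, sdlog = 1), -1, 0)
  g <- normality_gate(mixed)
  expect_equal(g$n_excluded, 2L)
  expect_equal(length(g$values), 50)
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("Spearman matrix is monotone-invariant with correct extremes", {
  x <- seq(-2, 2, length.out = 20)
  p <- data.frame(cell_id = 1:20, lipid_ester = x, carbohydrate = x^3,
                  protein_amide2 = -x)
  rho <- spearman_matrix(p, c("lipid_ester", "carbohydrate", "protein_amide2"))
  expect_equal(rho["lipid_ester", "carbohydrate"], 1)
  expect_equal(rho["lipid_ester", "protein_amide2"], -1)
  expect_equal(diag(rho), c(lipid_ester = 1, carbohydrate = 1,
                            protein_amide2 = 1))
  expect_equal(rho, t(rho))
  # invariance under a strictly monotone transform of one band
  p2 <- p; p2$lipid_ester <- exp(p2$lipid_ester)
  expect_equal(spearman_matrix(p2, names(p)[-1]), rho)
})

test_that("bands sharing a latent light factor correlate strongly", {
  p <- make_profiles(300, f_light = function(L) 1 + pmin(L, 15) / 7, seed = 53)
  rho <- spearman_matrix(p)
  expect_gt(rho["lipid_ester", "sat_lipid_2852"], 0.75)
  expect_gt(rho["lipid_ester", "carbohydrate"], 0.75)
  expect_lt(abs(rho["lipid_ester", "protein_amide2"]), 0.4)
})

test_that("PCA ordination satisfies its algebraic contract", {
  p <- make_profiles(40, f_light = function(L) 1 + L / 10, seed = 54)
  bands <- c("lipid_ester", "sat_lipid_2852", "carbohydrate", "protein_amide2")
  pc <- pca_biomolecules(p, bands)
  expect_equal(sum(pc$variance_explained), 1)
  expect_equal(unname(colMeans(pc$scores)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(crossprod(pc$loadings)), diag(4), tolerance = 1e-9)
  # reconstruction of the standardized matrix from all components
  z <- scale(as.matrix(p[, bands]))
  rec <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(unclass(z) - rec)), 1e-8)
  # two perfectly correlated bands: one component carries everything
  q <- data.frame(cell_id = 1:20, a = 1:20, b = 2 * (1:20) + 3)
  pc2 <- pca_biomolecules(q, c("a", "b"))
  expect_equal(pc2$variance_explained[1], 1)
  q$b <- 1
  expect_error(pca_biomolecules(q, c("a", "b")), "zero-variance.*b")
})

test_that("a dominant light-driven factor loads onto PC1", {
  p <- make_profiles(300, f_light = function(L) 1 + L / 7, seed = 55)
  pc <- pca_biomolecules(p)
  expect_gt(abs(cor(pc$scores[, 1], p$light_pct, method = "spearman")), 0.9)
})

test_that("light-response fit is exact on exact data and recovers slopes", {
  # exact log-linear site means -> R^2 = 1
  p <- make_profiles(60, seed = 56)
  p$lipid_ester <- 10^(0.02 * p$light_pct - 1)
  f <- suppressWarnings(light_response_fit(p, "lipid_ester"))  # exact fit
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$slope, 0.02, tolerance = 1e-9)
  expect_equal(f$df[2], f$n - 2)
  expect_error(light_response_fit(p[p$light_pct < 1.4, ], "lipid_ester"),
               "3 sites")

  # slope-recovery coverage: the 95% CI contains the true slope in >= 93/100
  b <- 0.02
  covered <- 0
  for (r in 1:100) {
    set.seed(600 + r)
    q <- make_profiles(60, seed = 600 + r)
    q$lipid_ester <- 10^(b * q$light_pct + rnorm(60, 0, 0.1))
    fit <- light_response_fit(q, "lipid_ester")
    ci <- confint(fit$model)["light_pct", ]
    covered <- covered + (ci[1] <= b && b <= ci[2])
  }
  expect_gte(covered, 93)
})

test_that("flat responses trigger false positives at roughly the alpha rate", {
  hits <- 0
  for (r in 1:100) {
    q <- make_profiles(60, seed = 700 + r)
    hits <- hits + (light_response_fit(q, "protein_amide2")$p < 0.05)
  }
  expect_lte(hits, 12)  # ~5 expected under the null
})

test_that("the confidence band is truncated at data-sparse sites", {
  p <- make_profiles(60, seed = 57)
  p$lipid_ester <- 10^(0.02 * p$light_pct + rnorm(60, 0, 0.05))
  # leave a single cell at the highest-light site
  p_sparse <- rbind(p[p$light_pct != 23.2, ], p[p$light_pct == 23.2, ][1, ])
  f <- light_response_fit(p_sparse, "lipid_ester", min_cells_ci = 3)
  expect_true(all(f$ci_band$light_pct < 23.2))
  full <- light_response_fit(p, "lipid_ester", min_cells_ci = 3)
  expect_true(23.2 %in% full$ci_band$light_pct)
})

test_that("fixed-factor splitting is detected when and only when present", {
  # identical relation in both groups: improvement significant at ~alpha rate
  sig <- 0
  for (r in 1:30) {
    set.seed(800 + r)
    n <- 120
    p <- data.frame(cell_id = seq_len(n),
                    light_pct = rep(c(1.5, 10), each = n / 2))
    p$x <- rnorm(n, 5)
    p$y <- 1 + 0.5 * p$x + rnorm(n, 0, 0.3)
    f <- fixed_factor_fit(p, "x", "y")
    sig <- sig + f$improvement$significant
  }
  expect_lte(sig, 7)

  # a parallel shift between light groups is detected
  set.seed(900)
  n <- 200
  p <- data.frame(cell_id = seq_len(n),
                  light_pct = rep(c(1.5, 10), each = n / 2))
  p$x <- rnorm(n, 5)
  p$y <- 1 + 0.5 * p$x + 1.5 * (p$light_pct > 5) + rnorm(n, 0, 0.3)
  f <- fixed_factor_fit(p, "x", "y")
  expect_true(f$improvement$significant)
  expect_true(f$HLT$reportable)
  expect_equal(f$HLT$group, "HLT")

  # unrelated x and y: reportable flags raised at ~alpha rate
  flags <- 0
  for (r in 1:30) {
    set.seed(950 + r)
    p <- data.frame(cell_id = 1:120, light_pct = rep(c(1.5, 10), each = 60),
                    x = rnorm(120, 5), y = rnorm(120, 3, 0.3))
    f <- fixed_factor_fit(p, "x", "y")
    flags <- flags + f$LLT$reportable + f$HLT$reportable
  }
  expect_lte(flags, 12)  # 60 tests at alpha = 0.05

  # a group with too few cells is absent, not fabricated
  p <- data.frame(cell_id = 1:22, light_pct = c(rep(1.5, 2), rep(10, 20)),
                  x = rnorm(22, 5), y = rnorm(22, 3, 0.3))
  f <- fixed_factor_fit(p, "x", "y")
  expect_null(f$LLT)
  expect_null(f$improvement)
})

test_that("Welch comparison matches its closed form and the isotope contrast", {
  expect_equal(group_mean_compare(c(1, 2, 3), c(1, 2, 3))$t, 0)
  set.seed(60)
  jit <- group_mean_compare(rnorm(3, 0, 1e-6), 1 + rnorm(3, 0, 1e-6))
  expect_lt(jit$p, 0.05)
  expect_error(group_mean_compare(1, c(1, 2)), "at least 2")
  # carbon stable-isotope contrast between light regimes, from printed
  # summaries: t close to 4 with 2 (floored Welch) degrees of freedom
  w <- welch_t_summary(-17.42, 3.2, 3, -24.85, 0.5, 3)
  expect_equal(w$t, 4.0, tolerance = 0.1)
  expect_equal(w$df_floor, 2)
  expect_lt(w$p, 0.06)
  # agreement with t.test on raw vectors
  a <- c(1.2, 0.8, 1.1); b <- c(2.4, 2.6, 2.1)
  w2 <- welch_t_summary(mean(a), sd(a), 3, mean(b), sd(b), 3)
  expect_equal(w2$t, group_mean_compare(a, b)$t, tolerance = 1e-12)
})

test_that("residual diagnostics flag heteroscedasticity and low power", {
  # iid residuals: rejected at ~alpha rate over replicates
  bad <- 0
  for (r in 1:40) {
    set.seed(970 + r)
    x <- rnorm(100); y <- 1 + x + rnorm(100)
    bad <- bad + !residual_diagnostics(lm(y ~ x))$homoscedastic
  }
  expect_lte(bad, 8)
  # variance growing with the mean is caught
  set.seed(61)
  x <- runif(100, 1, 5); y <- x + rnorm(100, 0, 0.2 * x^2)
  expect_false(residual_diagnostics(lm(y ~ x))$homoscedastic)
  # tiny fits are advisory only
  d <- residual_diagnostics(lm(c(1, 2.1, 2.9) ~ c(1, 2, 3)))
  expect_true(d$low_power)
})

test_that("OLS results are invariant to order and rescale exactly", {
  p <- make_profiles(60, seed = 62)
  p$lipid_ester <- 10^(0.02 * p$light_pct + rnorm(60, 0, 0.05))
  f1 <- light_response_fit(p, "lipid_ester")
  f2 <- light_response_fit(p[sample(60), ], "lipid_ester")
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$p, f2$p)
  # predictor rescale: slope rescales exactly inversely
  p10 <- p; p10$light_pct <- p10$light_pct * 10
  f3 <- light_response_fit(p10, "lipid_ester")
  expect_equal(f3$slope, f1$slope / 10, tolerance = 1e-12)
  expect_equal(f3$r_squared, f1$r_squared, tolerance = 1e-12)
})
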