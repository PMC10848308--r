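#!/usr/bin/env Rscript

# Statistical layer over the per-cell biomolecular profiles.
#
# Spearman correlation structure among bands, PCA ordination across the
# light gradient, per-taxon light-response regressions of the key bands
# (with the below-saturation lipid fit), and the fixed-factor (LLT vs HLT)
# biomolecule-pair regressions with the nested-model improvement test.

suppressPackageStartupMessages(library(iceftir))

prof <- read.delim("results/profiles.tsv")
validate_table(prof, "profiles")

## correlation structure ------------------------------------------------
rho <- spearman_matrix(prof)
write.table(data.frame(label = rownames(rho), rho, check.names = FALSE),
            "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
lipid_family <- c("lipid_ester", "sat_lipid_2921", "sat_lipid_2852",
                  "unsat_fa")
fam <- rho[lipid_family, lipid_family]
cat(sprintf("Median Spearman rho within the lipid family: %.2f\n",
            median(fam[upper.tri(fam)])))

## ordination ------------------------------------------------------------
pca <- pca_biomolecules(prof)
write.table(data.frame(label = rownames(pca$loadings),
                       pca$loadings[, 1:2]),
            "results/pca_loadings.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PC1 explains %.1f%% of the variation; |cor(PC1, light)| = %.2f\n",
            100 * pca$variance_explained[1],
            abs(cor(pca$scores[, 1], prof$light_pct, method = "spearman"))))

## light-response regressions -------------------------------------------
fits <- list()
for (tx in unique(prof$taxon)) {
  for (b in c("lipid_ester", "carbohydrate", "protein_amide2", "silica")) {
    max_l <- if (b %in% c("lipid_ester", "carbohydrate")) 15.5 else NULL
    f <- tryCatch(light_response_fit(prof, b, taxon = tx, max_light = max_l),
                  error = function(e) NULL)
    if (is.null(f)) next
    f$model <- NULL
    fits[[paste(tx, b, sep = "|")]] <- f
    cat(sprintf("%-18s %-14s slope %+.4f  F(%d,%d) = %6.2f  p = %.4f  R2 = %.2f\n",
                tx, b, f$slope, f$df[1], f$df[2], f$F, f$p, f$r_squared))
  }
}

## fixed-factor pair regressions ----------------------------------------
pairs <- list(c("lipid_ester", "carbohydrate"),
              c("lipid_ester", "protein_amide2"),
              c("carbohydrate", "protein_amide2"))
pair_fits <- list()
for (pr in pairs) {
  f <- fixed_factor_fit(prof, pr[1], pr[2])
  key <- paste(pr, collapse = "_vs_")
  cat(sprintf("\n%s: split improves on pooled: %s (F = %.2f, p = %.3g)\n",
              key, f$improvement$significant, f$improvement$F,
              f$improvement$p))
  for (g in c("LLT", "HLT")) if (!is.null(f[[g]])) {
    cat(sprintf("  %s: slope %+.3f, F(%d,%d) = %.2f, p = %.3g, R2 = %.2f%s\n",
                g, f[[g]]$slope, f[[g]]$df[1], f[[g]]$df[2], f[[g]]$F,
                f[[g]]$p, f[[g]]$r_squared,
                if (f[[g]]$reportable) "" else "  [not reportable]"))
    d <- residual_diagnostics(f[[g]])
    if (!d$homoscedastic)
      cat("    note: Breusch-Pagan flags heteroscedastic residuals\n")
    f[[g]]$model <- NULL
  }
  pair_fits[[key]] <- f
}

jsonlite::write_json(list(light_response = fits, fixed_factor = pair_fits),
                     "results/regressions.json", auto_unbox = TRUE,
                     digits = 10, pretty = TRUE, na = "null")
cat("\nWrote results/correlations.tsv, pca_loadings.tsv, regressions.json\n")
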