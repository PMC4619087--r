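#!/usr/bin/env Rscript
# Statistical stage over the pooled individual feature space: standardized
# linear PCA, Welch t-tests of the species on the first two component
# scores, Fisher exact test of ever-switching by species, and the
# radial-SVM repeated 10% holdout (99 splits).

library(commdyn)
dir.create("results/feature_analysis", recursive = TRUE,
           showWarnings = FALSE)

parts <- lapply(c("grevys", "onager"), function(stub) {
  tl <- parse_sightings(sprintf("results/data/%s_sightings.csv", stub))
  s <- infer(tl)
  im <- individual_metrics(s)
  at <- read_attributes(sprintf("results/data/%s_attributes.csv", stub))
  im$individual_id <- paste0(stub, "_", im$individual_id)
  at$individual_id <- paste0(stub, "_", at$individual_id)
  list(im = im, at = at)
})
im <- do.call(rbind, lapply(parts, `[[`, "im"))
at <- do.call(rbind, lapply(parts, `[[`, "at"))
fm <- build_feature_matrix(im, at)

pca <- run_pca(fm, standardize = TRUE)
write.csv(data.frame(metric = rownames(pca$loadings), pca$loadings),
          "results/feature_analysis/pca_loadings.csv", row.names = FALSE)
write.csv(data.frame(component = seq_along(pca$variance_fraction),
                     variance_fraction = pca$variance_fraction),
          "results/feature_analysis/pca_variance.csv", row.names = FALSE)
write.csv(data.frame(individual_id = rownames(pca$scores),
                     species = fm$labels$species, pca$scores),
          "results/feature_analysis/pca_scores.csv", row.names = FALSE)

tt1 <- group_ttest(pca$scores, fm$labels$species, 1L)
tt2 <- group_ttest(pca$scores, fm$labels$species, 2L)
fp <- fisher_switching(im, fm$labels$species)
acc <- svm_cv(fm, fm$labels$species, n_sims = 99L, holdout = 0.1, seed = 1L)
write.csv(data.frame(
  quantity = c("pc1_variance", "pc2_variance", "t_pc1", "p_pc1", "t_pc2",
               "p_pc2", "fisher_switching_p", "svm_accuracy"),
  value = c(pca$variance_fraction[1], pca$variance_fraction[2],
            tt1$statistic, tt1$p_value, tt2$statistic, tt2$p_value,
            fp, acc)),
  "results/feature_analysis/statistics.csv", row.names = FALSE)

message(sprintf("PC1/PC2 variance: %.1f%% / %.1f%%",
                100 * pca$variance_fraction[1],
                100 * pca$variance_fraction[2]))
message(sprintf("species t on PC1: %.2f (p=%.2g); PC2: %.2f (p=%.2g)",
                tt1$statistic, tt1$p_value, tt2$statistic, tt2$p_value))
message(sprintf("Fisher ever-switching p: %.3g", fp))
message(sprintf("radial-SVM 99x10%% holdout accuracy: %.1f%%", 100 * acc))
message("wrote results/feature_analysis/")
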