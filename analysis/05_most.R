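#!/usr/bin/env Rscript
# Stage 5: Methylation Outlier Sample Test. Filters probes, runs scaled
# PCA with parallel-analysis retention, Grubbs tests per retained PC before
# and after covariate adjustment, applies the dual FDR < 0.1 rule, and
# runs loading enrichment on the PC that carries an injected outlier.

suppressMessages(library(dnmtrio))

meth <- readRDS("scratch/sim/methylation.rds")
res <- most_detect(meth$beta, meth$covariates, meth$annotation,
                   meth$detection_p, fdr = 0.1, seed = 20160803)

message("retained ", res$pca$retained_k, " of 20 PCs by parallel analysis")
write.table(res$grubbs_raw, "results/05_grubbs_raw.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$grubbs_adjusted, "results/05_grubbs_adjusted.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$outliers, "results/05_outliers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("outliers (dual FDR < 0.1): ",
        if (nrow(res$outliers)) paste(unique(res$outliers$sample), collapse = ", ")
        else "none")
message("injected: ", paste(meth$truth$sample_id, collapse = ", "))

# loading enrichment on the first retained PC, against synthetic gene sets
if (res$pca$retained_k >= 1) {
  probes <- rownames(res$pca$loadings)
  genes <- sprintf("MG%04d", rep(1:2000, length.out = length(probes)))
  pg <- data.frame(probe = probes, gene = genes, stringsAsFactors = FALSE)
  set.seed(5)
  sets <- lapply(1:6, function(i) sample(unique(genes), 150))
  names(sets) <- paste0("function_", 1:6)
  le <- loading_enrichment(res$pca$loadings[, 1], pg, sets,
                           top_fraction = 0.02)
  write.table(le, "results/05_loading_enrichment.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}

diag <- data.frame(pc = seq_along(res$shapiro_p),
                   eigenvalue = res$pca$eigenvalues[seq_along(res$shapiro_p)],
                   perm_max = res$pca$perm_max[seq_along(res$shapiro_p)],
                   shapiro_p = res$shapiro_p)
write.table(diag, "results/05_pc_diagnostics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
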