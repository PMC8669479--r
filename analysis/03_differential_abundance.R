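#!/usr/bin/env Rscript

# Stage 3: differential barcode abundance, hit calling, PCA and profile
# correlation.
#
# For each compound, treated replicates are tested against the solvent
# controls with the NB likelihood-ratio test (median-of-ratios size
# factors, moderated method-of-moments dispersions), p values are
# BH-adjusted, and strains are called enriched (candidate importer
# deletion) at log2FC >= 0.5, p <= 0.001, padj <= 0.1, or depleted
# (candidate exporter deletion) symmetrically. Sample structure is
# inspected by PCA of shifted-log profiles, and the two azole-like
# compounds are compared by Pearson correlation of their log2FC profiles.

suppressMessages(library(cgprofiler))

base <- "scratch/screen_sim"
cm <- read_count_matrix("results/counts.tsv", "results/samples_all.tsv")

tables <- list()
for (cmpd in c("azoleA", "azoleB")) {
  tab <- diffabund(cm, cmpd)
  tables[[cmpd]] <- tab
  write.table(as.data.frame(tab),
              sprintf("results/diffabund_%s.tsv", cmpd),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

hits <- compound_hit_summary(tables)
write.table(hits$report, "results/hit_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d compounds select >= 1 enriched strain\n",
            hits$n_compounds_with_enriched, length(tables)))
for (cmpd in names(tables)) {
  enr <- hits$per_compound[[cmpd]]$enriched
  dep <- hits$per_compound[[cmpd]]$depleted
  cat(sprintf("  %s: importer candidates {%s}; exporter candidates {%s}\n",
              cmpd,
              paste(sprintf("%s (log2FC %.2f)", enr$barcode_id, enr$log2fc),
                    collapse = ", "),
              paste(sprintf("%s (log2FC %.2f)", dep$barcode_id, dep$log2fc),
                    collapse = ", ")))
}

# truth check against the planted effects
truth <- read.delim(file.path(base, "azoleA", "truth.tsv"))
planted <- truth$barcode_id[truth$delta != 0]
called_a <- tables$azoleA$barcode_id[tables$azoleA$call != "ns"]
cat(sprintf("azoleA: %d/%d planted effects recalled, %d false calls\n",
            length(intersect(called_a, planted)), length(planted),
            length(setdiff(called_a, planted))))

# PCA of shifted-log profiles: replicates should cluster by condition
sf <- compute_size_factors(cm)
pca <- run_pca(shifted_log_transform(cm, sf))
scores <- data.frame(sample_id = rownames(pca$scores),
                     pca$scores[, 1:3])
write.table(scores, "results/pca_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$var_explained[1], 100 * pca$var_explained[2]))

# shared-route analysis: correlation of the two compound profiles
pc <- profile_correlation(tables$azoleA, tables$azoleB)
cat(sprintf("azoleA vs azoleB: r^2 = %.4f over %d shared barcodes\n",
            pc$r_squared, pc$n_shared))
write.table(data.frame(pair = "azoleA_vs_azoleB", r = pc$r,
                       r_squared = pc$r_squared, n_shared = pc$n_shared),
            "results/profile_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
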