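#!/usr/bin/env Rscript
# Sample-level expression structure: Pearson correlation among samples,
# PCA variance fractions, and hierarchical clustering of samples on
# correlation distance.

source("analysis/00_config.R")

cm <- need_counts()
manifest <- read_manifest(res_path("manifest.tsv"))
rpm <- rpm_normalize(cm)
lz <- expression_transform(rpm, log2 = TRUE, pseudocount = 1, zscore = TRUE)

cc <- pearson_matrix(lz)
write_tsv(data.frame(sample_id = rownames(cc), round(cc, 4),
                     check.names = FALSE),
          res_path("pearson_matrix.tsv"))
same <- outer(manifest$tissue, manifest$tissue, "==") & upper.tri(cc)
diff <- outer(manifest$tissue, manifest$tissue, "!=") & upper.tri(cc)
message(sprintf("  mean correlation: %.3f within tissue vs %.3f between",
                mean(cc[same]), mean(cc[diff])))

pca <- pca_profiles(lz)
vf <- data.frame(component = seq_along(pca$var_frac),
                 var_frac_pct = round(100 * pca$var_frac, 2))
write_tsv(utils::head(vf, 10), res_path("pca_variance.tsv"))
message(sprintf("  PC1 %.2f%%, PC2 %.2f%%, PC3 %.2f%% of variance",
                vf$var_frac_pct[1], vf$var_frac_pct[2], vf$var_frac_pct[3]))
coords <- data.frame(sample_id = rownames(pca$coords),
                     round(pca$coords[, 1:3], 3))
write_tsv(merge(manifest, coords, by = "sample_id"),
          res_path("pca_coordinates.tsv"))

hc <- hcluster_order(cor_distance(lz))
write_tsv(data.frame(order = seq_along(hc$order), sample_id = hc$order),
          res_path("sample_cluster_order.tsv"))
# do samples cluster by tissue? count adjacent same-tissue pairs
tis <- manifest$tissue[match(hc$order, manifest$sample_id)]
message(sprintf("  %d/%d adjacent leaf pairs share a tissue",
                sum(utils::head(tis, -1) == tis[-1]), length(tis) - 1))
message("Done.")
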