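#!/usr/bin/env Rscript
# Cross-tissue DE structure and target logic: overlap distribution,
# direction conservation, specificity enrichment (chi-square), seed-site
# target prediction, the miRNA-mRNA network and gene-set enrichment.

source("analysis/00_config.R")

de <- utils::read.delim(res_path("de_results.tsv"))
spec <- utils::read.delim(res_path("specificity.tsv"))
utr <- read_fasta(data_path("utr.fa"))
mature <- read_fasta(data_path("mature.fa"))
gene_sets <- read_gmt(data_path("gene_sets.gmt"))
genes <- read_gene_annotation(data_path("genes.tsv"))
gene_dirs <- utils::read.delim(data_path("truth_true_gene_dirs.tsv"))

hits <- de[de$is_de, ]
sets <- split(hits$mirna, factor(hits$tissue, unique(de$tissue)))
ov <- overlap_distribution(sets)
tab3 <- data.frame(n_tissues = as.integer(names(ov$counts)),
                   n_mirnas = as.integer(ov$counts),
                   percent = format_percent(ov$counts, ov$total_unique))
write_tsv(tab3, res_path("table3_overlap.tsv"))
message(sprintf("  %d unique DE miRNAs; %s%% DE in one tissue only",
                ov$total_unique, tab3$percent[1]))

cons <- direction_conservation(de)
message(sprintf("  %d of %d DE miRNAs direction-conserved across >= 2 tissues",
                sum(cons$conserved), length(cons$conserved)))
heat <- data.frame(mirna = rownames(cons$heatmap),
                   round(cons$heatmap, 3), check.names = FALSE)
write_tsv(heat, res_path("conservation_heatmap.tsv"))

chi <- specificity_enrichment(spec$mirna %in% hits$mirna,
                              spec$category == "tissue_specific")
message(sprintf("  DE x tissue-specific chi-square = %.3f, p = %.3g",
                chi$statistic, chi$p_value))

targets <- predict_targets(mature[unique(hits$mirna)], utr)
write_tsv(targets, res_path("target_sites.tsv"))
message(sprintf("  %d seed sites (%s)", nrow(targets),
                paste(names(table(targets$site_type)),
                      table(targets$site_type), collapse = ", ")))

net <- build_network(unique(hits[c("mirna", "tissue", "direction")]),
                     gene_dirs, targets)
write_tsv(net, res_path("network_edges.tsv"))
message(sprintf("  %d anti-correlated miRNA-mRNA edges", nrow(net)))

universe <- unique(genes$gene_id)
enr <- geneset_enrichment(intersect(unique(targets$gene), universe),
                          gene_sets, universe)
enr$p_value <- signif(enr$p_value, 4); enr$fdr <- signif(enr$fdr, 4)
write_tsv(enr, res_path("geneset_enrichment.tsv"))
message("  top set: ", enr$set[1], " (p = ", enr$p_value[1], ")")
message("Done.")
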