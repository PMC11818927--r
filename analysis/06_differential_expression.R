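#!/usr/bin/env Rscript
# Prenatal vs postnatal differential expression within each tissue:
# TMM + exact conditional NB test + BH, FC > 1.5 and FDR < 0.05.

source("analysis/00_config.R")

cm <- need_counts()
manifest <- read_manifest(res_path("manifest.tsv"))

de <- de_analysis(cm, manifest)
write_tsv(cbind(de[c("mirna", "tissue")], round(de[3:5], 5),
                de[c("direction", "is_de")]),
          res_path("de_results.tsv"))

hits <- de[de$is_de, ]
per <- table(factor(hits$tissue, unique(manifest$tissue)))
tab2 <- data.frame(tissue = c(names(per), "Total"),
                   n_de = c(as.integer(per), nrow(hits)))
write_tsv(tab2, res_path("table2_de_counts.tsv"))
message("  DE events per tissue: ",
        paste(names(per), per, collapse = ", "),
        " (", nrow(hits), " events, ", length(unique(hits$mirna)),
        " unique miRNAs)")

truth <- utils::read.delim(data_path("truth_true_de.tsv"))
tkey <- paste(truth$mirna, truth$tissue)
ckey <- paste(hits$mirna, hits$tissue)
elig <- tkey[truth$mirna %in% rownames(cm$counts)]
message(sprintf("  truth recovery: recall %.2f, precision %.2f",
                mean(elig %in% ckey),
                if (length(ckey)) mean(ckey %in% tkey) else NA))
# sign convention check against the planted fold changes
m <- merge(hits, truth, by = c("mirna", "tissue"))
message(sprintf("  direction agreement with truth: %d/%d",
                sum(sign(m$log2fc.x) == sign(m$log2fc.y)), nrow(m)))
message("Done.")
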