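#!/usr/bin/env Rscript
# Annotate detected miRNAs: known/conserved/novel classes, arm usage
# census, and genomic context of their precursors.

source("analysis/00_config.R")

cm <- need_counts()
same_ref <- read_fasta(data_path("ref_same_species.fa"))
other_ref <- read_fasta(data_path("ref_other_species.fa"))
genes <- read_gene_annotation(data_path("genes.tsv"))
ref <- generate_reference(study_config)   # deterministic regeneration

detected <- ref$mature[ref$mature$id %in% rownames(cm$counts), ]
message(nrow(detected), " detected miRNAs")

detected$class <- as.character(classify_mirna(detected$sequence,
                                              same_ref, other_ref))
tab <- table(detected$class)
message(sprintf("  classes: %d known, %d conserved, %d novel",
                tab["known"], tab["conserved"], tab["novel"]))

census <- arm_census(detected, ref$hairpin$id)
census$pct_matures <- format_percent(
  census$matures, census$matures[census$class == "Total"])
write_tsv(census, res_path("table1_class_census.tsv"))

hp <- ref$hairpin[ref$hairpin$id %in% detected$precursor_id, ]
ctx <- genomic_context(hp, genes)
ctx_tab <- as.data.frame(table(factor(ctx, c("intronic", "intergenic",
                                             "exonic", "intron_exon"))))
names(ctx_tab) <- c("context", "n")
ctx_tab$percent <- format_percent(ctx_tab$n, sum(ctx_tab$n))
write_tsv(ctx_tab, res_path("genomic_context.tsv"))
message("  context breakdown: ",
        paste(sprintf("%s %s%%", ctx_tab$context, ctx_tab$percent),
              collapse = ", "))
message("Done.")
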