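#!/usr/bin/env Rscript
# Generate the synthetic study: references, design, counts, raw reads and
# assay tables, with ground truth for the downstream recovery checks.

source("analysis/00_config.R")

message("Generating reference set and truth tables (seed ", STUDY_SEED, ")")
ref <- generate_reference(study_config)
manifest <- sample_manifest(study_config)
message(sprintf("  %d mature miRNAs on %d precursors; %d genes; %d samples",
                nrow(ref$mature), nrow(ref$hairpin),
                length(unique(ref$genes$gene_id)), nrow(manifest)))

write_fasta(setNames(ref$mature$sequence, ref$mature$id),
            data_path("mature.fa"))
write_fasta(setNames(ref$hairpin$sequence, ref$hairpin$id),
            data_path("hairpin.fa"))
write_fasta(ref$utr, data_path("utr.fa"))
write_fasta(ref$same_species_ref, data_path("ref_same_species.fa"))
write_fasta(ref$other_species_ref, data_path("ref_other_species.fa"))
write_gene_annotation(ref$genes, data_path("genes.tsv"))
write_gmt(ref$gene_sets, data_path("gene_sets.gmt"))
write_manifest(manifest, res_path("manifest.tsv"))
for (nm in names(ref$truth)) {
  write_tsv(ref$truth[[nm]], data_path(paste0("truth_", nm, ".tsv")))
}

message("Simulating counts and synthesizing reads")
cm <- simulate_counts(study_config, ref$truth, manifest)
write_count_matrix(cm, data_path("true_counts.tsv"))
rs <- synthesize_reads(cm, setNames(ref$mature$sequence, ref$mature$id),
                       study_config, data_path("fastq"))
write_tsv(rs, data_path("read_synthesis_stats.tsv"))
message(sprintf("  %d reads across %d samples (%.1f%% junk)",
                sum(rs$n_reads), nrow(rs),
                100 * sum(rs$n_junk) / sum(rs$n_reads)))

message("Simulating assay tables")
assays <- simulate_assays(study_config)
for (nm in names(assays)) {
  write_tsv(assays[[nm]], data_path(paste0("assay_", nm, ".tsv")))
}
message("Done.")
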