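# Shared settings for the analysis scripts. Source this from each driver.
#
# The study configuration mirrors the perinatal design (6 tissues x
# prenatal/postnatal x 3 replicates, one postnatal spleen replicate
# dropped -> 35 samples) at desk scale: 300 miRNAs and 30-60k reads per
# sample.

library(perinatmir)

STUDY_SEED <- 20260926L
study_config <- synthetic_config(seed = STUDY_SEED)

DATA_DIR <- "scratch/analysis"      # bulky artifacts (FASTQ, caches)
RESULTS_DIR <- "results"            # small summary tables
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

res_path <- function(...) file.path(RESULTS_DIR, ...)
data_path <- function(...) file.path(DATA_DIR, ...)

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}

need_counts <- function() {
  p <- res_path("counts_filtered.tsv")
  if (!file.exists(p)) stop("run analysis/02_quantify.R first (missing ", p, ")")
  read_count_matrix(p)
}
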