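# End-to-end orchestration over synthetic data and machine-readable census
# tables: annotation-class census, per-tissue DE counts, cross-tissue
# overlap shares, genomic-context breakdown and the specificity census,
# with the percentage conventions used throughout (2 decimals, half-up,
# trailing zeros trimmed).

#' Census tables with percentages
#'
#' Builds the four summary tables of a pipeline run: the annotation-class /
#' arm census, per-tissue DE counts, the cross-tissue overlap distribution,
#' the genomic-context breakdown and the specificity census. Every
#' percentage is 100 x numerator / denominator of counts present in the
#' same table, rounded half-up to 2 decimals.
#'
#' @param class_census output of [arm_census()].
#' @param de_results data.frame from [de_analysis()].
#' @param specificity data.frame from [specificity_analysis()].
#' @param contexts named context vector from [genomic_context()].
#' @return list of data.frames: \code{classes}, \code{de_per_tissue},
#'   \code{overlap}, \code{contexts}, \code{specificity}.
#' @export
summarize_tables <- function(class_census, de_results, specificity, contexts) {
  total_mat <- class_census$matures[class_census$class == "Total"]
  classes <- class_census
  classes$pct_matures <- format_percent(classes$matures, total_mat)

  de_sets <- split(de_results$mirna[de_results$is_de],
                   de_results$tissue[de_results$is_de])
  for (t in setdiff(unique(de_results$tissue), names(de_sets))) {
    de_sets[[t]] <- character(0)
  }
  per_tissue <- data.frame(tissue = names(de_sets),
                           n_de = vapply(de_sets, length, 0L),
                           row.names = NULL, stringsAsFactors = FALSE)
  per_tissue <- rbind(per_tissue,
                      data.frame(tissue = "Total",
                                 n_de = sum(per_tissue$n_de)))

  ov <- overlap_distribution(de_sets)
  overlap <- data.frame(n_tissues = as.integer(names(ov$counts)),
                        n_mirnas = as.integer(ov$counts),
                        percent = if (ov$total_unique > 0) {
                          format_percent(ov$counts, ov$total_unique)
                        } else NA_character_,
                        stringsAsFactors = FALSE)
  attr(overlap, "total_unique") <- ov$total_unique

  ctx <- table(factor(contexts, c("intronic", "intergenic", "exonic",
                                  "intron_exon")))
  contexts_tab <- data.frame(context = names(ctx), n = as.integer(ctx),
                             percent = format_percent(as.integer(ctx),
                                                      sum(ctx)),
                             stringsAsFactors = FALSE)

  cat_tab <- table(specificity$category)
  spec_tab <- data.frame(category = names(cat_tab),
                         n = as.integer(cat_tab),
                         percent = format_percent(as.integer(cat_tab),
                                                  sum(cat_tab)),
                         stringsAsFactors = FALSE)

  list(classes = classes, de_per_tissue = per_tissue, overlap = overlap,
       contexts = contexts_tab, specificity = spec_tab)
}

#' Run the full synthetic pipeline
#'
#' Generates references, counts and reads for the configuration, then runs
#' quantification, annotation, expression profiling, specificity scoring,
#' per-tissue differential expression, cross-tissue / target / network
#' analysis and the assay statistics, in that order, and assembles a
#' machine-readable report. When \code{outdir} is given, intermediate
#' artifacts (FASTQ, count matrix, tables) and the JSON report are written
#' there.
#'
#' @param config a [synthetic_config()].
#' @param outdir optional output directory; FASTQ files go to
#'   \code{file.path(outdir, "fastq")}. Defaults to a session temporary
#'   directory.
#' @param three_prime_tolerance isomiR tolerance passed to the quantifier.
#' @return list of class \code{pipeline_report}; see the methods vignette
#'   for the section layout.
#' @export
run_pipeline <- function(config = synthetic_config(), outdir = NULL,
                         three_prime_tolerance = 0L) {
  write_out <- !is.null(outdir)
  if (!write_out) outdir <- file.path(tempdir(), "perinatmir_run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  ## simulate
  ref <- generate_reference(config)
  manifest <- sample_manifest(config)
  cm_true <- simulate_counts(config, ref$truth, manifest)
  mature_seqs <- stats::setNames(ref$mature$sequence, ref$mature$id)
  read_stats <- synthesize_reads(cm_true, mature_seqs, config,
                                 file.path(outdir, "fastq"))

  ## quantify
  paths <- stats::setNames(read_stats$path, read_stats$sample_id)
  q <- quantify_samples(paths, mature_seqs, config$adapter,
                        hairpins = stats::setNames(ref$hairpin$sequence,
                                                   ref$hairpin$id),
                        precursor_of = stats::setNames(ref$mature$precursor_id,
                                                       ref$mature$id),
                        three_prime_tolerance = three_prime_tolerance)
  cm <- detection_filter(q$cm)
  rpm <- rpm_normalize(cm)

  ## annotate (identified = detection-filtered miRNAs)
  detected <- ref$mature[ref$mature$id %in% rownames(cm$counts), ]
  detected$class <- as.character(
    classify_mirna(detected$sequence, ref$same_species_ref,
                   ref$other_species_ref))
  census <- arm_census(detected, ref$hairpin$id)
  det_prec <- ref$hairpin[ref$hairpin$id %in% detected$precursor_id, ]
  contexts <- genomic_context(det_prec, ref$genes)

  ## expression profiles
  lz <- expression_transform(rpm, log2 = TRUE, pseudocount = 1, zscore = TRUE)
  pearson <- pearson_matrix(lz)
  pca <- pca_profiles(lz)

  ## specificity
  spec <- specificity_analysis(rpm, manifest)

  ## differential expression
  de <- de_analysis(cm, manifest)

  ## cross-tissue, targets, network, enrichment
  de_hits <- de[de$is_de, ]
  tables <- summarize_tables(census, de, spec, contexts)
  conservation <- direction_conservation(de)
  spec_flag <- spec$category == "tissue_specific"
  de_flag <- spec$mirna %in% de_hits$mirna
  enrich2x2 <- specificity_enrichment(de_flag, spec_flag)
  de_mirna_seqs <- mature_seqs[unique(de_hits$mirna)]
  targets <- if (length(de_mirna_seqs)) {
    predict_targets(de_mirna_seqs, ref$utr)
  } else {
    data.frame(mirna = character(0), gene = character(0),
               start0 = integer(0), site_type = character(0))
  }
  network <- build_network(
    unique(de_hits[c("mirna", "tissue", "direction")]),
    ref$truth$true_gene_dirs, targets)
  universe <- unique(ref$genes$gene_id)
  target_genes <- intersect(unique(targets$gene), universe)
  enrichment <- if (length(target_genes)) {
    geneset_enrichment(target_genes, ref$gene_sets, universe)
  } else NULL

  ## assays
  assays <- simulate_assays(config)
  ct <- ddct(assays$ct, calibrator = "prenatal")
  luc <- luciferase_relative_activity(assays$luciferase)
  glu <- glucose_output(assays$glucose$glucose, assays$glucose$protein,
                        assays$glucose$group)
  blood <- stats::aggregate(glucose_mmol_l ~ time_h, assays$blood_glucose,
                            mean)
  luc_wt <- luc[luc$construct == "Wt", ]
  assay_report <- list(
    relative_expression = stats::aggregate(rel_expr ~ target + group, ct,
                                           mean),
    luciferase_wt_test = group_compare(luc_wt$activity, luc_wt$treatment),
    glucose_summary = glu$summary,
    glucose_anova = group_compare(glu$wells$normalized, glu$wells$group),
    blood_glucose_mean = blood,
    blood_glucose_nadir = blood$glucose_mmol_l[which.min(blood$glucose_mmol_l)])

  ## truth-aware recovery
  truth_de_key <- paste(ref$truth$true_de$mirna, ref$truth$true_de$tissue)
  called_key <- paste(de_hits$mirna, de_hits$tissue)
  eligible <- truth_de_key[ref$truth$true_de$mirna %in% rownames(cm$counts)]
  recovery <- list(
    de_recall = if (length(eligible)) mean(eligible %in% called_key) else NA,
    de_precision = if (length(called_key)) {
      mean(called_key %in% truth_de_key)
    } else NA)
  spec_truth <- ref$truth$true_specific
  spec_truth <- spec_truth[spec_truth$tissue != "none" &
                             spec_truth$mirna %in% spec$mirna, ]
  assigned <- spec$assigned_tissue[match(spec_truth$mirna, spec$mirna)]
  recovery$tissue_assignment_accuracy <-
    if (nrow(spec_truth)) mean(assigned == spec_truth$tissue) else NA

  report <- list(
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      package = as.character(utils::packageVersion("perinatmir")),
                      r_version = R.version.string),
    design = list(n_samples = nrow(manifest),
                  tissues = config$tissues,
                  n_mirnas_simulated = config$n_mirnas,
                  n_mirnas_detected = nrow(cm$counts)),
    read_stats = merge(read_stats[c("sample_id", "n_reads", "n_junk")],
                       q$stats, by = "sample_id"),
    length_distribution = as.list(q$length_dist),
    tables = tables,
    pca_var_frac = pca$var_frac[seq_len(min(5, length(pca$var_frac)))],
    specificity_chisq = list(statistic = enrich2x2$statistic,
                             p_value = enrich2x2$p_value),
    conserved_de = sum(conservation$conserved),
    n_network_edges = nrow(network),
    enrichment = enrichment,
    assays = assay_report,
    recovery = recovery)
  class(report) <- c("pipeline_report", "list")

  if (write_out) {
    write_count_matrix(cm, file.path(outdir, "counts.tsv"))
    write_manifest(manifest, file.path(outdir, "manifest.tsv"))
    utils::write.table(de, file.path(outdir, "de_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(spec, file.path(outdir, "specificity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(targets, file.path(outdir, "target_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(network, file.path(outdir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# internal: md5 of the deparsed configuration (provenance only)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

# internal: strip classes jsonlite cannot serialize cleanly
report_to_json <- function(report) {
  rapply(unclass(report), function(x) {
    if (inherits(x, "table") || inherits(x, "matrix")) {
      as.data.frame(as.table(x))
    } else x
  }, how = "replace", classes = c("table", "matrix"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("perinatmir pipeline report\n")
  cat(sprintf("  samples: %d; miRNAs detected: %d of %d simulated\n",
              x$design$n_samples, x$design$n_mirnas_detected,
              x$design$n_mirnas_simulated))
  cat(sprintf("  DE events: %d (unique miRNAs: %d); network edges: %d\n",
              x$tables$de_per_tissue$n_de[x$tables$de_per_tissue$tissue == "Total"],
              attr(x$tables$overlap, "total_unique"), x$n_network_edges))
  cat(sprintf("  DE recall %.2f, precision %.2f; tissue assignment accuracy %.2f\n",
              x$recovery$de_recall, x$recovery$de_precision,
              x$recovery$tissue_assignment_accuracy))
  invisible(x)
}
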