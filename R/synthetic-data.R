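# Synthetic study generator: references, sample design, negative-binomial
# counts, raw reads and wet-lab assay tables, together with ground-truth
# tables so every downstream stage of the analysis can be checked against
# what was planted.

#' Mature miR-22-3p sequence (DNA alphabet)
#'
#' The anchor miRNA of the liver gluconeogenesis axis; planted into the
#' synthetic same-species reference so that target prediction and the
#' luciferase workflow have a realistic worked example.
#' @export
MIR22_3P <- "AAGCTGCCAGTTGAAGAACTGT"

#' AKT3 3'UTR wild-type fragment
#'
#' Carries the canonical miR-22-3p 8mer seed site (GGCAGCT followed by A).
#' @export
AKT3_UTR_WT <- "GAGCTCGGGTTCAAGGGCATTTTACTAAGGCAGCTAAGACATATGCAGACATAGATCTCGAG"

#' AKT3 3'UTR fragment with the seed site mutated
#' @export
AKT3_UTR_MUT <- "GAGCTCGGGTTCAAGGGCATTTTACTAATAGCTAGAAGACATATGCAGACATAGATCTCGAG"

DNA_BASES <- c("A", "C", "G", "T")

# internal: one random DNA string of length len
rand_seq <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

#' Configuration of the synthetic perinatal study
#'
#' Defaults mirror the study design the pipeline is built for: six tissues,
#' prenatal and postnatal stages, three replicates per cell, and one
#' postnatal spleen replicate dropped for RNA quality, leaving 35 samples.
#' Reference size and library depth are desk-scale stand-ins (see the
#' methods vignette).
#'
#' @param seed integer RNG seed; all stochastic stages derive from it.
#' @param tissues tissue names.
#' @param n_reps replicates per tissue x stage (>= 2).
#' @param drop_samples sample ids to omit from the design.
#' @param n_mirnas number of mature miRNAs to generate.
#' @param frac_specific fraction of miRNAs with one-tissue-dominant expression.
#' @param frac_de per-tissue fraction of miRNAs differentially expressed
#'   between stages.
#' @param fc_range fold-change interval for true DE; lower bound must
#'   exceed 1 (default lower bound 2, comfortably above the 1.5 calling
#'   threshold).
#' @param dispersion negative-binomial dispersion phi.
#' @param libsize_range interval of reads per sample.
#' @param adapter 3' sequencing adapter.
#' @param class_props proportions of known/conserved/novel miRNAs (sum 1).
#' @param context_props proportions of intronic/intergenic/exonic/intron_exon
#'   precursor placements (sum 1).
#' @param dominance_ratio expression multiplier of the dominant tissue for
#'   tissue-specific miRNAs.
#' @param junk_frac fraction of junk reads (adapter dimers, short inserts)
#'   added during read synthesis.
#' @param read_length raw read length.
#' @param error_rate per-base substitution rate during read synthesis
#'   (default 0; the quantifier matches exactly).
#' @param include_mir22 plant miR-22-3p / AKT3 as a known anchor pair when a
#'   "known" slot is available.
#' @return validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             tissues = c("heart", "liver", "spleen", "lung",
                                         "muscle", "duodenum"),
                             n_reps = 3L,
                             drop_samples = "spleen_postnatal_3",
                             n_mirnas = 300L,
                             frac_specific = 0.583,
                             frac_de = 0.025,
                             fc_range = c(2, 8),
                             dispersion = 0.1,
                             libsize_range = c(30000, 60000),
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             class_props = c(known = 444, conserved = 697,
                                             novel = 370) / 1511,
                             context_props = c(intronic = 516, intergenic = 319,
                                               exonic = 1, intron_exon = 135) / 971,
                             dominance_ratio = 10,
                             junk_frac = 0.02,
                             read_length = 50L,
                             error_rate = 0,
                             include_mir22 = TRUE) {
  cfg <- list(seed = as.integer(seed), tissues = tissues,
              n_reps = as.integer(n_reps), drop_samples = drop_samples,
              n_mirnas = as.integer(n_mirnas), frac_specific = frac_specific,
              frac_de = frac_de, fc_range = fc_range, dispersion = dispersion,
              libsize_range = libsize_range, adapter = normalize_seq(adapter),
              class_props = class_props, context_props = context_props,
              dominance_ratio = dominance_ratio, junk_frac = junk_frac,
              read_length = as.integer(read_length), error_rate = error_rate,
              include_mir22 = include_mir22)
  for (f in c("frac_specific", "frac_de", "junk_frac", "error_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) config_error(f, "must be in [0, 1]")
  }
  if (length(tissues) < 2) config_error("tissues", "need at least 2 tissues")
  if (cfg$n_reps < 2) config_error("n_reps", "must be >= 2")
  if (length(fc_range) != 2 || fc_range[1] <= 1 || diff(fc_range) < 0) {
    config_error("fc_range", "lower bound must be > 1 and range non-decreasing")
  }
  if (abs(sum(class_props) - 1) > 1e-9) {
    config_error("class_props", "proportions must sum to 1")
  }
  if (length(class_props) != 3 || any(class_props < 0)) {
    config_error("class_props", "need 3 non-negative proportions")
  }
  if (abs(sum(context_props) - 1) > 1e-9) {
    config_error("context_props", "proportions must sum to 1")
  }
  if (length(context_props) != 4 || any(context_props < 0)) {
    config_error("context_props", "need 4 non-negative proportions")
  }
  if (cfg$dispersion < 0) config_error("dispersion", "must be >= 0")
  if (cfg$libsize_range[1] <= 0 || diff(cfg$libsize_range) < 0) {
    config_error("libsize_range", "must be a positive non-decreasing interval")
  }
  if (!nzchar(cfg$adapter)) config_error("adapter", "must be non-empty")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Build the sample design for a configuration
#'
#' One row per tissue x stage x replicate cell, minus the dropped samples.
#' Sample ids follow \code{<tissue>_<stage>_<replicate>}.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with sample_id, tissue, stage, replicate.
#' @export
sample_manifest <- function(config) {
  d <- expand.grid(replicate = seq_len(config$n_reps),
                   stage = c("prenatal", "postnatal"),
                   tissue = config$tissues,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample_id <- paste(d$tissue, d$stage, d$replicate, sep = "_")
  d <- d[!(d$sample_id %in% config$drop_samples),
         c("sample_id", "tissue", "stage", "replicate")]
  rownames(d) <- NULL
  d
}

#' Generate the synthetic reference set and ground truth
#'
#' Produces mature and hairpin miRNA tables, a gene annotation with exon
#' structure on a virtual chromosome, 3'UTR sequences with planted seed
#' sites (including the AKT3 wild-type fragment verbatim, plus a synthetic
#' mutant-site control entry), a same-species and an other-species mature
#' reference realizing the configured known/conserved/novel proportions, a
#' GMT gene-set collection, and the truth tables used by recovery tests.
#'
#' Deterministic given \code{config$seed}.
#'
#' @param config a [synthetic_config()].
#' @return list with elements \code{mature}, \code{hairpin}, \code{genes},
#'   \code{utr}, \code{gene_sets}, \code{same_species_ref},
#'   \code{other_species_ref} and \code{truth}.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_mirnas

  ## -- class labels -------------------------------------------------------
  class_counts <- apportion(n, config$class_props)
  labels <- rep(c("known", "conserved", "novel"), class_counts)
  with_mir22 <- config$include_mir22 && class_counts[1] >= 1
  if (with_mir22) {
    labels <- labels[-match("known", labels)]
  }
  labels <- sample(labels)
  if (with_mir22) labels <- c("known", labels)

  ## -- mature sequences with unique seeds ---------------------------------
  len_support <- 19:26
  len_probs <- c(0.07, 0.09, 0.18, 0.38, 0.13, 0.07, 0.05, 0.03)
  seed_pool <- unique(replicate(3 * n + 50, rand_seq(7)))
  seed_pool <- setdiff(seed_pool, seed_of(MIR22_3P))
  if (length(seed_pool) < n + 20) stop("seed pool exhausted; increase pool")
  seeds <- seed_pool[seq_len(n)]
  decoy_seeds <- seed_pool[(n + 1):(n + 10)]
  lens <- sample(len_support, n, replace = TRUE, prob = len_probs)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(sample(DNA_BASES, 1), seeds[i], rand_seq(lens[i] - 8))
  }, "")
  if (with_mir22) {
    seqs[1] <- MIR22_3P
    seeds[1] <- seed_of(MIR22_3P)
  }

  ## -- precursors: arm structure ------------------------------------------
  arm_props <- c(p5 = 203, p3 = 228, both = 540) / 971
  arm_types <- character(0)
  covered <- 0
  while (covered < n) {
    a <- if (n - covered == 1) {
      sample(c("p5", "p3"), 1, prob = arm_props[1:2] / sum(arm_props[1:2]))
    } else sample(names(arm_props), 1, prob = arm_props)
    if (with_mir22 && covered == 0) a <- "p3"
    arm_types <- c(arm_types, a)
    covered <- covered + if (a == "both") 2 else 1
  }
  n_prec <- length(arm_types)
  prec_ids <- sprintf("pre-mir-%03d", seq_len(n_prec))
  if (with_mir22) prec_ids[1] <- "ssc-mir-22"

  mature <- data.frame(id = character(n), sequence = seqs,
                       precursor_id = character(n), arm = character(n),
                       class = labels, stringsAsFactors = FALSE)
  k <- 1
  hairpin_seq <- character(n_prec)
  for (j in seq_len(n_prec)) {
    arms <- switch(arm_types[j], p5 = "5p", p3 = "3p", both = c("5p", "3p"))
    idx <- k:(k + length(arms) - 1)
    mature$precursor_id[idx] <- prec_ids[j]
    mature$arm[idx] <- arms
    mature$id[idx] <- paste0(sub("^pre-", "", prec_ids[j]), "-", arms)
    five <- if ("5p" %in% arms) seqs[idx[match("5p", arms)]] else rand_seq(21)
    three <- if ("3p" %in% arms) seqs[idx[match("3p", arms)]] else rand_seq(21)
    hairpin_seq[j] <- paste0(rand_seq(sample(6:12, 1)), five,
                             rand_seq(sample(14:20, 1)), three,
                             rand_seq(sample(6:12, 1)))
    k <- k + length(arms)
  }
  if (with_mir22) mature$id[1] <- "ssc-miR-22-3p"

  ## -- gene models on a virtual chromosome --------------------------------
  context_counts <- apportion(n_prec, config$context_props)
  contexts <- sample(rep(c("intronic", "intergenic", "exonic", "intron_exon"),
                         context_counts))
  n_genes <- max(10L, n_prec)
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  gene_ids[n_genes] <- "AKT3"
  exon_rows <- vector("list", n_genes)
  gene_span <- matrix(0L, n_genes, 2)
  cursor <- 1000L
  for (g in seq_len(n_genes)) {
    n_ex <- sample(3:5, 1)
    strand <- sample(c("+", "-"), 1)
    starts <- ends <- integer(n_ex)
    pos <- cursor
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + sample(200:400, 1)
      pos <- ends[e] + sample(300:800, 1)    # next exon after an intron
    }
    exon_rows[[g]] <- data.frame(gene_id = gene_ids[g], chrom = "chr1",
                                 strand = strand, feature = "exon",
                                 start0 = starts, end0 = ends,
                                 stringsAsFactors = FALSE)
    gene_span[g, ] <- c(starts[1], ends[n_ex])
    cursor <- ends[n_ex] + sample(600:1500, 1)
  }
  genes <- do.call(rbind, exon_rows)
  chrom_len <- cursor + 2000L

  ## -- place precursors per context ---------------------------------------
  place <- function(ctx, L) {
    g <- sample(n_genes, 1)
    ex <- exon_rows[[g]]
    if (ctx == "intergenic") {
      gaps <- rbind(c(0L, gene_span[1, 1]),
                    cbind(gene_span[-n_genes, 2], gene_span[-1, 1]),
                    c(gene_span[n_genes, 2], chrom_len))
      ok <- which(gaps[, 2] - gaps[, 1] >= L + 20)
      gp <- gaps[sample(ok, 1), ]
      s <- sample(seq(gp[1] + 10, gp[2] - L - 10), 1)
    } else if (ctx == "exonic") {
      e <- sample(nrow(ex), 1)
      s <- sample(seq(ex$start0[e], ex$end0[e] - L), 1)
    } else if (ctx == "intronic") {
      e <- sample(nrow(ex) - 1, 1)       # intron after exon e
      s <- sample(seq(ex$end0[e], ex$start0[e + 1] - L), 1)
    } else {                              # intron_exon: span a junction
      e <- sample(nrow(ex) - 1, 1)
      in_exon <- L %/% 2L
      s <- ex$end0[e] - in_exon
    }
    c(s, s + L)
  }
  hp_pos <- t(mapply(place, contexts, nchar(hairpin_seq)))
  hairpin <- data.frame(id = prec_ids, sequence = hairpin_seq, chrom = "chr1",
                        start0 = as.integer(hp_pos[, 1]),
                        end0 = as.integer(hp_pos[, 2]),
                        strand = sample(c("+", "-"), n_prec, replace = TRUE),
                        stringsAsFactors = FALSE)

  ## -- species references realizing the classes ---------------------------
  same_ref <- c()
  other_ref <- c()
  for (i in seq_len(n)) {
    if (labels[i] == "known") {
      same_ref[paste0("ssc-ref-", mature$id[i])] <- seqs[i]
    } else if (labels[i] == "conserved") {
      alt <- paste0(sample(DNA_BASES, 1), seeds[i], rand_seq(12))
      while (alt == seqs[i]) alt <- paste0(sample(DNA_BASES, 1), seeds[i],
                                           rand_seq(12))
      other_ref[paste0("hsa-ref-", mature$id[i])] <- alt
    }
  }
  if (with_mir22) names(same_ref)[1] <- "ssc-miR-22-3p"
  for (d in seq_along(decoy_seeds)) {
    nm <- sprintf("decoy-%02d", d)
    sq <- paste0(sample(DNA_BASES, 1), decoy_seeds[d], rand_seq(13))
    if (d %% 2 == 0) same_ref[paste0("ssc-", nm)] <- sq
    else other_ref[paste0("hsa-", nm)] <- sq
  }

  ## -- truth: tissue specificity and differential expression --------------
  n_spec <- round(config$frac_specific * n)
  spec_mirnas <- sample(mature$id, n_spec)
  true_specific <- data.frame(
    mirna = mature$id,
    tissue = ifelse(mature$id %in% spec_mirnas,
                    sample(config$tissues, n, replace = TRUE), "none"),
    stringsAsFactors = FALSE)

  n_de <- round(config$frac_de * n)
  de_rows <- lapply(config$tissues, function(t) {
    if (n_de == 0) {
      return(data.frame(mirna = character(0), tissue = character(0),
                        log2fc = numeric(0), stringsAsFactors = FALSE))
    }
    m <- sample(mature$id, n_de)
    lfc <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, log2(config$fc_range[1]), log2(config$fc_range[2]))
    data.frame(mirna = m, tissue = t, log2fc = lfc, stringsAsFactors = FALSE)
  })
  true_de <- do.call(rbind, de_rows)
  if (with_mir22 &&
      !any(true_de$mirna == "ssc-miR-22-3p" & true_de$tissue == "liver")) {
    true_de <- rbind(true_de,
                     data.frame(mirna = "ssc-miR-22-3p", tissue = "liver",
                                log2fc = log2(2.8)))
  }

  ## -- UTRs with planted seed sites ---------------------------------------
  utr <- vapply(gene_ids, function(g) rand_seq(sample(300:600, 1)), "")
  pad1 <- rand_seq(150); pad2 <- rand_seq(150)
  utr["AKT3"] <- paste0(pad1, AKT3_UTR_WT, pad2)

  target_mirnas <- unique(true_de$mirna)
  planted <- list()
  used_sites <- lapply(utr, function(x) integer(0))
  for (m in target_mirnas) {
    sq <- mature$sequence[mature$id == m]
    site <- paste0(revcomp(seed_of(sq)), "A")   # 8mer site
    n_t <- sample(1:3, 1)
    gs <- sample(setdiff(gene_ids, "AKT3"), n_t)
    if (m == "ssc-miR-22-3p") gs <- unique(c("AKT3", gs[-1]))
    for (g in gs) {
      if (g == "AKT3") { planted[[length(planted) + 1]] <-
        data.frame(mirna = m, gene = g); next }  # site already in Wt fragment
      L <- nchar(utr[[g]])
      for (try in 1:25) {
        pos <- sample(seq(20L, L - 30L), 1)
        if (!any(abs(used_sites[[g]] - pos) < 10)) {
          substr(utr[[g]], pos, pos + 7L) <- site
          used_sites[[g]] <- c(used_sites[[g]], pos)
          planted[[length(planted) + 1]] <- data.frame(mirna = m, gene = g)
          break
        }
      }
    }
  }
  true_targets <- if (length(planted)) do.call(rbind, planted) else
    data.frame(mirna = character(0), gene = character(0))
  utr["AKT3_site_mut"] <- paste0(pad1, AKT3_UTR_MUT, pad2)  # synthetic control

  ## -- mRNA direction truth (targets respond opposite to their miRNA) -----
  gd <- merge(true_de, true_targets, by = "mirna")
  true_gene_dirs <- unique(data.frame(
    gene = gd$gene, tissue = gd$tissue,
    direction = ifelse(gd$log2fc > 0, "down", "up"),
    stringsAsFactors = FALSE))
  true_gene_dirs <- true_gene_dirs[!duplicated(true_gene_dirs[c("gene", "tissue")]), ]

  ## -- gene sets ----------------------------------------------------------
  targeted <- unique(true_targets$gene)
  pick <- function(k, from = gene_ids) sample(from, min(k, length(from)))
  gene_sets <- list(
    PI3K_AKT_SIGNALING = unique(c("AKT3", pick(round(n_genes * 0.12)))),
    TARGET_RESPONSE = unique(c(pick(max(3, round(length(targeted) * 0.8)),
                                    from = if (length(targeted) >= 3) targeted
                                           else gene_ids),
                               pick(round(n_genes * 0.05)))),
    GLUCONEOGENESIS = pick(round(n_genes * 0.10)),
    IMMUNE_RESPONSE = pick(round(n_genes * 0.15)),
    MUSCLE_DIFFERENTIATION = pick(round(n_genes * 0.10)),
    EPITHELIAL_PROLIFERATION = pick(round(n_genes * 0.12)))

  truth <- list(true_de = true_de, true_specific = true_specific,
                true_targets = true_targets,
                true_class = mature[c("id", "class")],
                true_context = data.frame(precursor = prec_ids,
                                          context = contexts,
                                          stringsAsFactors = FALSE),
                true_gene_dirs = true_gene_dirs)
  names(truth$true_class) <- c("mirna", "class")

  list(mature = mature, hairpin = hairpin, genes = genes, utr = utr,
       gene_sets = gene_sets, same_species_ref = same_ref,
       other_species_ref = other_ref, truth = truth)
}

#' Simulate the count matrix for a design
#'
#' Counts are drawn NB(mu, phi) where mu combines the sample's target
#' library size, the miRNA's baseline abundance, a dominance multiplier in
#' the specific tissue of tissue-specific miRNAs, and a stage multiplier
#' 2^log2FC in postnatal samples of tissues where the miRNA is truly DE.
#' With \code{dispersion = 0} the Poisson limit is used.
#'
#' @param config a [synthetic_config()].
#' @param truth truth tables from [generate_reference()].
#' @param design sample manifest (see [sample_manifest()]).
#' @return a [count_matrix()].
#' @export
simulate_counts <- function(config, truth, design = sample_manifest(config)) {
  if (nrow(design) == 0) stop("empty design")
  set.seed(config$seed + 1L)
  mirnas <- truth$true_class$mirna
  n <- length(mirnas)
  # relative abundances; normalized so a sample's expected depth matches
  # its target library size (before tissue/stage multipliers)
  baseline <- stats::rlnorm(n, meanlog = log(300), sdlog = 1.3)
  baseline <- baseline / sum(baseline)
  libs <- round(stats::runif(nrow(design), config$libsize_range[1],
                             config$libsize_range[2]))

  spec_tissue <- truth$true_specific$tissue[match(mirnas, truth$true_specific$mirna)]
  de_key <- paste(truth$true_de$mirna, truth$true_de$tissue)
  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(mirnas, design$sample_id))
  for (j in seq_len(nrow(design))) {
    t_j <- design$tissue[j]
    mult <- ifelse(!is.na(spec_tissue) & spec_tissue == t_j,
                   config$dominance_ratio, 1)
    if (design$stage[j] == "postnatal") {
      hit <- match(paste(mirnas, t_j), de_key)
      mult <- mult * ifelse(is.na(hit), 1, 2^truth$true_de$log2fc[hit])
    }
    mu <- baseline * libs[j] * mult
    counts[, j] <- if (config$dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }
  count_matrix(counts)
}

#' Synthesize per-sample FASTQ files from a count matrix
#'
#' Each real read is the mature sequence followed by the 3' adapter, padded
#' with random bases to the raw read length (or truncated). A configurable
#' fraction of junk reads -- adapter dimers and sub-18-nt inserts -- is
#' appended and reported. Qualities are constant Q40.
#'
#' @param cm a [count_matrix()].
#' @param mature_seqs named character vector: miRNA id -> mature sequence.
#' @param config a [synthetic_config()].
#' @param outdir output directory for FASTQ files.
#' @return data.frame with sample_id, path, n_reads, n_real, n_junk.
#' @export
synthesize_reads <- function(cm, mature_seqs, config, outdir) {
  missing <- setdiff(rownames(cm$counts), names(mature_seqs))
  if (length(missing)) {
    stop("no mature sequence for miRNA(s): ", paste(missing, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 2L)
  L <- config$read_length
  adapter <- config$adapter
  pads <- vapply(1:200, function(i) rand_seq(L), "")
  stats <- vector("list", ncol(cm$counts))

  for (j in seq_len(ncol(cm$counts))) {
    sample_id <- colnames(cm$counts)[j]
    cts <- cm$counts[, j]
    inserts <- rep(mature_seqs[rownames(cm$counts)], times = cts)
    if (config$error_rate > 0 && length(inserts)) {
      inserts <- vapply(inserts, mutate_seq, "", rate = config$error_rate,
                        USE.NAMES = FALSE)
    }
    n_real <- length(inserts)
    n_junk <- round(config$junk_frac * n_real / (1 - config$junk_frac))
    if (n_junk > 0) {
      dimers <- rep("", ceiling(n_junk / 2))          # adapter-dimer inserts
      shorts <- vapply(seq_len(n_junk - length(dimers)),
                       function(i) rand_seq(sample(8:16, 1)), "")
      inserts <- c(inserts, dimers, shorts)
    }
    reads <- substr(paste0(inserts, adapter, sample(pads, length(inserts),
                                                    replace = TRUE)), 1, L)
    ord <- sample(length(reads))
    reads <- reads[ord]
    path <- file.path(outdir, paste0(sample_id, ".fastq"))
    write_fastq(data.frame(id = sprintf("%s_%06d", sample_id,
                                        seq_along(reads)),
                           sequence = reads,
                           quality = strrep("I", L)), path)
    stats[[j]] <- data.frame(sample_id = sample_id, path = path,
                             n_reads = length(reads), n_real = n_real,
                             n_junk = length(reads) - n_real,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, stats)
}

# internal: per-base substitutions at the given rate
mutate_seq <- function(x, rate) {
  b <- strsplit(x, "")[[1]]
  hit <- stats::runif(length(b)) < rate
  if (any(hit)) {
    b[hit] <- vapply(b[hit], function(o) sample(setdiff(DNA_BASES, o), 1), "")
  }
  paste(b, collapse = "")
}

#' Simulate wet-lab assay tables
#'
#' Generates (i) a qRT-PCR Ct table constructed so that the 2^-ddCt method
#' recovers the programmed fold changes, (ii) a dual-luciferase table with
#' the programmed mimic/control activity ratios per construct, (iii) a
#' glucose-production table with per-well protein content, and (iv) a
#' neonatal blood-glucose time series falling from 6.03 mmol/L at birth to a
#' 1.23 mmol/L nadir at 3 h and rebounding to 2.23 mmol/L at 6 h.
#'
#' @param config a [synthetic_config()] (only the seed is used).
#' @param qpcr_folds named numeric vector of true expression fold changes
#'   (treatment vs calibrator) per target; all must be > 0.
#' @param qpcr_refs named character vector of reference genes per target.
#' @param ct_noise_sd Gaussian SD added to every Ct value.
#' @param luc_ratios named numeric vector: construct -> true relative
#'   activity of the mimic versus the mimic control.
#' @param luc_noise_sd lognormal noise SD on luciferase signals.
#' @param glucose_means named numeric vector of true protein-normalized
#'   glucose production per group.
#' @param glucose_noise_sd lognormal noise SD on glucose output.
#' @param n_reps replicates per group/well condition.
#' @param glucose_curve anchor points (time h -> mmol/L) of the blood
#'   glucose trajectory.
#' @param blood_noise_sd Gaussian SD of individual blood-glucose readings.
#' @param n_piglets piglets measured per time point.
#' @return list with elements \code{ct}, \code{luciferase}, \code{glucose},
#'   \code{blood_glucose}.
#' @export
simulate_assays <- function(config,
                            qpcr_folds = c("miR-22-3p" = 2.8, AKT3 = 0.45,
                                           FoxO1 = 2.0, PCK1 = 3.5, G6PC = 3.0),
                            qpcr_refs = c("miR-22-3p" = "U6", AKT3 = "GAPDH",
                                          FoxO1 = "GAPDH", PCK1 = "GAPDH",
                                          G6PC = "GAPDH"),
                            ct_noise_sd = 0.15,
                            luc_ratios = c(Wt = 0.55, Mut = 1.0),
                            luc_noise_sd = 0.08,
                            glucose_means = c(mimic_control = 1.0, mimic = 1.6,
                                              inhibitor = 0.6),
                            glucose_noise_sd = 0.08,
                            n_reps = 3L,
                            glucose_curve = c("0" = 6.03, "3" = 1.23, "6" = 2.23),
                            blood_noise_sd = 0.15,
                            n_piglets = 6L) {
  if (any(qpcr_folds <= 0)) stop("fold changes must be > 0")
  set.seed(config$seed + 3L)

  ## qRT-PCR: Ct = ref Ct + base - log2(expression) + noise
  ct <- do.call(rbind, lapply(names(qpcr_folds), function(g) {
    base <- stats::runif(1, 3, 8)
    ref_base <- stats::runif(1, 16, 22)
    grp <- rep(c("prenatal", "postnatal"), each = n_reps)
    expr <- ifelse(grp == "postnatal", qpcr_folds[[g]], 1)
    ref_ct <- ref_base + stats::rnorm(length(grp), 0, ct_noise_sd)
    data.frame(sample_id = paste0(g, "_", grp, "_", seq_len(n_reps)),
               group = grp, target = g,
               target_ct = ref_ct + base - log2(expr) +
                 stats::rnorm(length(grp), 0, ct_noise_sd),
               reference = qpcr_refs[[g]], reference_ct = ref_ct,
               stringsAsFactors = FALSE)
  }))

  ## dual luciferase: firefly/Renilla with programmed mimic ratios
  luc <- do.call(rbind, lapply(names(luc_ratios), function(con) {
    trt <- rep(c("mimic_control", "mimic"), each = n_reps)
    renilla <- stats::rlnorm(length(trt), log(2e5), 0.1)
    ratio <- ifelse(trt == "mimic", luc_ratios[[con]], 1)
    firefly <- renilla * 1.25 * ratio *
      stats::rlnorm(length(trt), 0, luc_noise_sd)
    data.frame(construct = con, treatment = trt, firefly = firefly,
               renilla = renilla, stringsAsFactors = FALSE)
  }))

  ## glucose production with per-well protein content
  glu <- do.call(rbind, lapply(names(glucose_means), function(g) {
    protein <- stats::rnorm(n_reps, 1, 0.05)
    protein[protein <= 0.1] <- 0.1
    data.frame(group = g,
               glucose = glucose_means[[g]] * protein *
                 stats::rlnorm(n_reps, 0, glucose_noise_sd),
               protein = protein, stringsAsFactors = FALSE)
  }))

  ## blood glucose: fall to the nadir then partial rebound
  anchors_t <- as.numeric(names(glucose_curve))
  g0 <- glucose_curve[[1]]; gmin <- glucose_curve[[2]]; g6 <- glucose_curve[[3]]
  t_nadir <- anchors_t[2]; t_end <- anchors_t[3]
  traj <- function(t) {
    ifelse(t <= t_nadir,
           gmin + (g0 - gmin) * ((t_nadir - t) / t_nadir)^1.7,
           gmin + (g6 - gmin) * ((t - t_nadir) / (t_end - t_nadir))^1.2)
  }
  times <- seq(anchors_t[1], t_end, by = 1)
  blood <- do.call(rbind, lapply(times, function(t) {
    data.frame(time_h = t, piglet = seq_len(n_piglets),
               glucose_mmol_l = pmax(0.2, traj(t) +
                                       stats::rnorm(n_piglets, 0, blood_noise_sd)))
  }))

  list(ct = ct, luciferase = luc, glucose = glu, blood_glucose = blood)
}
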