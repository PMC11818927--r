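test_that("configuration invariants are enforced with the field named", {
  expect_error(synthetic_config(frac_de = 1.2), "frac_de")
  expect_error(synthetic_config(fc_range = c(1, 3)), "fc_range")
  expect_error(synthetic_config(class_props = c(0.5, 0.4, 0.2)), "class_props")
  expect_error(synthetic_config(context_props = c(1, 0, 0, 0.5)),
               "context_props")
  expect_error(synthetic_config(n_reps = 1), "n_reps")
})

test_that("default design drops one postnatal spleen replicate (35 samples)", {
  mf <- sample_manifest(synthetic_config())
  expect_equal(nrow(mf), 35)
  expect_equal(sum(mf$stage == "prenatal"), 18)
  expect_equal(sum(mf$stage == "postnatal"), 17)
  expect_false("spleen_postnatal_3" %in% mf$sample_id)
})

test_that("reference generation is deterministic and honors proportions", {
  cfg <- tiny_config()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)

  # FASTA serialization is byte-identical across runs
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(setNames(r1$mature$sequence, r1$mature$id), f1)
  write_fasta(setNames(r2$mature$sequence, r2$mature$id), f2)
  expect_identical(readLines(f1), readLines(f2))

  # class and context counts within 1 of the configured proportions
  cls <- table(r1$truth$true_class$class)
  expect_true(all(abs(cls[c("known", "conserved", "novel")] -
                        cfg$n_mirnas * cfg$class_props) <= 1))
  ctx <- table(factor(r1$truth$true_context$context,
                      c("intronic", "intergenic", "exonic", "intron_exon")))
  expect_true(all(abs(ctx - nrow(r1$hairpin) * cfg$context_props) <= 1))
})

test_that("hairpins contain their matures and have plausible lengths", {
  r <- generate_reference(tiny_config())
  hp <- setNames(r$hairpin$sequence, r$hairpin$id)
  expect_true(all(nchar(hp) >= 60 & nchar(hp) <= 120))
  found <- mapply(grepl, r$mature$sequence, hp[r$mature$precursor_id],
                  MoreArgs = list(fixed = TRUE))
  expect_true(all(found))
})

test_that("degenerate class proportions make every mature a known reference hit", {
  cfg <- tiny_config(class_props = c(1, 0, 0))
  r <- generate_reference(cfg)
  expect_true(all(r$mature$sequence %in% r$same_species_ref))
})

test_that("degenerate context proportions verified by the per-base oracle", {
  cfg <- tiny_config(context_props = c(1, 0, 0, 0))
  r <- generate_reference(cfg)
  expect_true(all(r$truth$true_context$context == "intronic"))
  for (i in seq_len(nrow(r$hairpin))) {
    expect_equal(naive_context(r$hairpin[i, ], r$genes), "intronic")
  }
})

test_that("planted references realize the classification contract", {
  r <- generate_reference(tiny_config())
  cls <- classify_mirna(r$mature$sequence, r$same_species_ref,
                        r$other_species_ref)
  expect_equal(as.character(cls), r$truth$true_class$class)
})

test_that("simulated counts match NB moment formulas", {
  # one miRNA, mu = 100, phi = 0.1: variance = mu + phi mu^2 = 1100
  set.seed(99)
  draws <- rnbinom(1e4, mu = 100, size = 10)
  se <- sqrt(1100 / 1e4)
  expect_lt(abs(mean(draws) - 100), 3 * se)
  expect_lt(abs(var(draws) / 1100 - 1), 0.1)
})

test_that("dispersion zero gives the Poisson variance/mean limit", {
  cfg <- tiny_config(dispersion = 0, frac_de = 0, frac_specific = 0)
  r <- generate_reference(cfg)
  mf <- sample_manifest(cfg)
  cm <- simulate_counts(cfg, r$truth, mf)
  # pool relative deviations of variance/mean over well-expressed miRNAs;
  # under Poisson the ratio concentrates at 1
  expr <- sweep(cm$counts, 2, cm$lib_sizes / mean(cm$lib_sizes), "/")
  keep <- rowMeans(expr) > 20
  ratio <- apply(expr[keep, ], 1, var) / rowMeans(expr[keep, ])
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("frac_de = 0 leaves the truth DE table empty", {
  cfg <- tiny_config(frac_de = 0, include_mir22 = FALSE)
  r <- generate_reference(cfg)
  expect_equal(nrow(r$truth$true_de), 0)
})

test_that("count simulation is deterministic and respects the design", {
  cfg <- tiny_config()
  r <- generate_reference(cfg)
  mf <- sample_manifest(cfg)
  expect_identical(simulate_counts(cfg, r$truth, mf),
                   simulate_counts(cfg, r$truth, mf))
  expect_error(simulate_counts(cfg, r$truth, mf[0, ]), "empty design")
})

test_that("synthesized reads carry insert + adapter and exact multiplicities", {
  cfg <- tiny_config()
  r <- generate_reference(cfg)
  m <- setNames(r$mature$sequence, r$mature$id)[1:3]
  cts <- matrix(c(5L, 0L, 2L), 3, 1,
                dimnames = list(names(m), "s1"))
  cm <- count_matrix(cts)
  out <- synthesize_reads(cm, m, cfg, tempfile("fqdir"))
  fq <- read_fastq(out$path[1])
  expect_equal(nrow(fq), 7)
  expect_equal(out$n_junk, 0)
  # bases after each insert begin with the adapter
  ins <- trim_adapter(fq$sequence, cfg$adapter)
  expect_equal(sort(table(ins)[unique(ins)]),
               sort(table(rep(m[c(1, 3)], c(5, 2)))[unique(ins)]),
               ignore_attr = TRUE)
  first <- fq$sequence[1]
  insert_len <- nchar(ins[1])
  expect_equal(substr(first, insert_len + 1,
                      insert_len + nchar(cfg$adapter)), cfg$adapter)
  expect_error(synthesize_reads(cm, m[-1], cfg, tempfile()),
               "no mature sequence")
})

test_that("assay tables invert through their downstream statistics", {
  cfg <- tiny_config()
  # zero noise: ddct recovers the programmed fold exactly
  a0 <- simulate_assays(cfg, qpcr_folds = c(AKT3 = 4),
                        qpcr_refs = c(AKT3 = "GAPDH"), ct_noise_sd = 0)
  rel <- ddct(a0$ct, "prenatal")
  expect_equal(rel$rel_expr[rel$group == "postnatal"], rep(4, 3))
  expect_equal(mean(rel$rel_expr[rel$group == "prenatal"]), 1)

  # treatment ratio 1 -> relative activity 1 (zero noise)
  a1 <- simulate_assays(cfg, luc_ratios = c(Mut = 1), luc_noise_sd = 0)
  act <- luciferase_relative_activity(a1$luciferase)
  expect_equal(act$activity, rep(1, nrow(act)), tolerance = 1e-12)

  expect_error(simulate_assays(cfg, qpcr_folds = c(AKT3 = -1)),
               "fold changes")
})

test_that("Monte-Carlo ddct recovery of a programmed fold is unbiased", {
  folds <- replicate(50, {
    cfg <- synthetic_config(seed = sample.int(1e6, 1))
    a <- simulate_assays(cfg, qpcr_folds = c(G = 2.5),
                         qpcr_refs = c(G = "U6"), ct_noise_sd = 0.05)
    rel <- ddct(a$ct, "prenatal")
    mean(rel$rel_expr[rel$group == "postnatal"])
  })
  expect_lt(abs(mean(folds) / 2.5 - 1), 0.05)
})

test_that("blood-glucose trajectory falls to the nadir then rebounds", {
  a <- simulate_assays(tiny_config(), blood_noise_sd = 0)
  m <- aggregate(glucose_mmol_l ~ time_h, a$blood_glucose, mean)
  expect_equal(m$glucose_mmol_l[m$time_h == 0], 6.03, tolerance = 1e-9)
  expect_equal(min(m$glucose_mmol_l), 1.23, tolerance = 1e-9)
  expect_equal(m$time_h[which.min(m$glucose_mmol_l)], 3)
  expect_equal(m$glucose_mmol_l[m$time_h == 6], 2.23, tolerance = 1e-9)
})
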