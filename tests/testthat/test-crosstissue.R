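test_that("overlap distribution counts exact tissue membership", {
  ov <- overlap_distribution(list(A = c("m1", "m2"), B = "m1"))
  expect_equal(unname(ov$counts[1:2]), c(1L, 1L))
  expect_equal(ov$total_unique, 2)
  # disjoint sets: everything at k = 1
  ov2 <- overlap_distribution(list(A = c("x", "y"), B = "z", C = character(0)))
  expect_equal(unname(ov2$counts), c(3L, 0L, 0L))
  # permutation invariance and the weighted-sum identity
  sets <- list(h = c("a", "b", "c"), l = c("a", "d"), s = c("a", "b"))
  o1 <- overlap_distribution(sets)
  o2 <- overlap_distribution(rev(sets))
  expect_equal(o1$counts, o2$counts)
  expect_equal(sum(as.integer(names(o1$counts)) * o1$counts),
               sum(lengths(sets)))
})

test_that("study-scale overlap counts reproduce the printed shares", {
  # overlap counts by tissue multiplicity: 119 / 33 / 10 / 2 / 0 / 0
  counts <- c(119L, 33L, 10L, 2L, 0L, 0L)
  total <- sum(counts)
  expect_equal(total, 164)
  expect_equal(percent_value(counts[1], total), 72.56)
  expect_equal(percent_value(counts[2], total), 20.12)
  expect_equal(percent_value(counts[3], total), 6.10)
  expect_equal(percent_value(counts[4], total), 1.22)
})

test_that("direction conservation requires >= 2 tissues and one direction", {
  de <- data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m3", "m4"),
    tissue = c("liver", "lung", "liver", "lung", "heart", "liver"),
    log2fc = c(1, 2, 1, -1, 1.5, -2),
    direction = c("up", "up", "up", "down", "up", "down"),
    is_de = TRUE)
  dc <- direction_conservation(de)
  expect_true(dc$conserved[["m1"]])      # up in two tissues
  expect_false(dc$conserved[["m2"]])     # opposite directions
  expect_false(dc$conserved[["m3"]])     # one tissue only
  expect_equal(dc$heatmap["m1", "liver"], 1)
  expect_true(is.na(dc$heatmap["m3", "liver"]))
})

test_that("chi-square matches the sum((O-E)^2/E) oracle", {
  x <- specificity_enrichment(rep(c(TRUE, FALSE), each = 20),
                              rep(c(TRUE, FALSE), times = 20))
  expect_equal(x$statistic, 0)
  expect_equal(x$p_value, 1)

  de <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 10, 30))
  sp <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))
  y <- specificity_enrichment(de, sp)
  expect_equal(y$statistic, 20)
  # swapping the two flags leaves the statistic unchanged
  expect_equal(specificity_enrichment(sp, de)$statistic, y$statistic)

  set.seed(28)
  for (i in 1:20) {
    a <- sample(2:30, 4, replace = TRUE)
    f1 <- rep(c(TRUE, TRUE, FALSE, FALSE), a)
    f2 <- rep(c(TRUE, FALSE, TRUE, FALSE), a)
    z <- suppressWarnings(specificity_enrichment(f1, f2))
    O <- matrix(a, 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(z$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
  }
  # zero margin -> undefined
  z0 <- specificity_enrichment(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_true(is.na(z0$statistic))
})

test_that("seed scan finds the single 8mer in the AKT3 wild-type fragment", {
  wt <- predict_targets(c(`miR-22-3p` = MIR22_3P), c(AKT3 = AKT3_UTR_WT))
  expect_equal(nrow(wt), 1)
  expect_equal(wt$site_type, "8mer")
  expect_equal(substr(AKT3_UTR_WT, wt$start0 + 1, wt$start0 + 8), "GGCAGCTA")
  mut <- predict_targets(c(`miR-22-3p` = MIR22_3P), c(AKT3 = AKT3_UTR_MUT))
  expect_equal(nrow(mut), 0)
})

test_that("seed scan classifies constructed site types and short UTRs", {
  mir <- "TAAGCTGCCAGTTGAAGAACTG"       # seed AAGCTGC, rc GCAGCTT
  rc8 <- revcomp(seed_of(mir))
  # 8mer at position 0 when the UTR is rc(positions 1-8)
  u8 <- revcomp(substr(mir, 1, 8))
  hit8 <- predict_targets(c(m = mir), c(g = u8))
  expect_equal(hit8$start0, 0L)
  expect_equal(hit8$site_type, "8mer")
  # 7mer-m8: core without the trailing A
  hit7 <- predict_targets(c(m = mir), c(g = paste0("CCC", rc8, "GCC")))
  expect_equal(hit7$site_type, "7mer-m8")
  # 7mer-A1: rc of 2-7 + A, mismatching position 8
  u7a1 <- paste0("CCC", "A", revcomp(substr(mir, 2, 7)), "A", "CC")
  hit7a <- predict_targets(c(m = mir), c(g = u7a1))
  expect_equal(hit7a$site_type, "7mer-A1")
  # UTR shorter than 8 nt yields nothing
  expect_equal(nrow(predict_targets(c(m = mir), c(g = "ACGTACG"))), 0)
})

test_that("seed scan equals the naive motif oracle on random UTRs", {
  set.seed(29)
  mir <- c(mA = "TAAGCTGCCAGTTGAAGAACTG", mB = MIR22_3P)
  for (i in 1:10) {
    utr <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    # occasionally plant a site to exercise non-empty paths
    if (i %% 2 == 0) {
      substr(utr, 100, 107) <- paste0(revcomp(seed_of(mir[1])), "A")
    }
    got <- predict_targets(mir, c(u = utr))
    for (m in names(mir)) {
      want <- naive_seed_scan(mir[[m]], utr)
      sub <- got[got$mirna == m, c("start0", "site_type")]
      rownames(sub) <- rownames(want) <- NULL
      expect_equal(sub, want)
    }
  }
})

test_that("planted target truth is fully recovered (no false negatives)", {
  cfg <- tiny_config(seed = 33, frac_de = 0.2)
  r <- generate_reference(cfg)
  seqs <- setNames(r$mature$sequence, r$mature$id)
  tt <- r$truth$true_targets
  pred <- predict_targets(seqs[unique(tt$mirna)], r$utr)
  have <- paste(pred$mirna, pred$gene)
  expect_true(all(paste(tt$mirna, tt$gene) %in% have))
})

test_that("network edges require a site and opposite directions", {
  mirna_dirs <- data.frame(mirna = c("m1", "m1", "m2"),
                           tissue = c("liver", "lung", "liver"),
                           direction = c("up", "up", "up"))
  gene_dirs <- data.frame(gene = c("g1", "g1", "g2"),
                          tissue = c("liver", "lung", "liver"),
                          direction = c("down", "up", "down"))
  targets <- data.frame(mirna = "m1", gene = "g1",
                        start0 = 0L, site_type = "8mer")
  net <- build_network(mirna_dirs, gene_dirs, targets)
  # m1-g1 in liver: opposite -> edge; in lung: same direction -> no edge;
  # m2 has no predicted site -> no edge despite opposite g2 direction
  expect_equal(nrow(net), 1)
  expect_equal(net$mirna, "m1")
  expect_equal(net$tissue, "liver")
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), miss = paste0("g", 16:19))
  genes <- paste0("g", 1:5)
  res <- geneset_enrichment(genes, sets, universe)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "hit"],
               enum_hyper_p(5, 5, 20, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "miss"],
               enum_hyper_p(0, 4, 20, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "miss"], 1)

  set.seed(30)
  for (i in 1:20) {
    N <- sample(10:25, 1)
    uni <- paste0("u", seq_len(N))
    st <- sample(uni, sample(2:(N - 1), 1))
    gl <- sample(uni, sample(2:(N - 1), 1))
    r <- geneset_enrichment(gl, list(s = st), uni)
    expect_equal(r$p_value,
                 enum_hyper_p(length(intersect(gl, st)), length(st), N,
                              length(gl)),
                 tolerance = 1e-12)
  }
  expect_error(geneset_enrichment("x", sets, character(0)), "empty")
  expect_error(geneset_enrichment("zz", sets, universe), "outside")
})
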