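test_that("adapter trimming handles full, absent and partial adapters", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "TAAGCTGCCAGTTGAAGAACTG"
  expect_equal(trim_adapter(paste0(insert, adapter), adapter), insert)
  expect_true(is.na(trim_adapter("ACGTACGTACGTACGTACGT", adapter)))
  expect_equal(trim_adapter("ACGTACGTACGT", adapter, keep_untrimmed = TRUE),
               "ACGTACGTACGT")
  expect_error(trim_adapter("ACGT", ""), "adapter")
  expect_error(trim_adapter("ACGT", adapter, min_overlap = 3), "min_overlap")
})

test_that("3'-suffix partial adapters trim at the longest overlap", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTAC"
  # brute-force oracle: scan all suffix/prefix overlap lengths
  for (k in c(5, 6, 10, 15)) {
    read <- paste0(insert, substr(adapter, 1, k))
    best <- NA
    for (kk in nchar(read):5) {
      if (kk < nchar(adapter) &&
          substr(read, nchar(read) - kk + 1, nchar(read)) ==
          substr(adapter, 1, kk)) { best <- kk; break }
    }
    expect_equal(trim_adapter(read, adapter, min_overlap = 5),
                 substr(read, 1, nchar(read) - best))
  }
  # overlap below min_overlap is not trimmed
  expect_true(is.na(trim_adapter(paste0(insert, substr(adapter, 1, 4)),
                                 adapter, min_overlap = 5)))
})

test_that("cleaning collapses duplicates and filters by length and quality", {
  ins <- c(rep("TAAGCTGCCAGTTGAAGAACTG", 3), "ACGTACGTACGTACGTA",
           NA, "TAAGCTGCCAGTTGAAGAACTG")
  qual <- c(rep(strrep("I", 30), 4), strrep("I", 30), strrep("#", 30))
  cc <- clean_and_collapse(ins, qual, length_window = c(18, 26),
                           min_mean_quality = 20)
  # 3 good copies of the 22-mer; the 17-mer, the NA and the low-quality read drop
  expect_equal(nrow(cc$collapsed), 1)
  expect_equal(cc$collapsed$multiplicity, 3)
  expect_equal(cc$length_dist, c("22" = 1), ignore_attr = TRUE)
  expect_equal(cc$n_clean, 3)
  expect_error(clean_and_collapse(ins, length_window = c(10, 26)),
               "length_window")
})

test_that("malformed FASTQ raises a parse error naming the record", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "record 2")
})

test_that("read assignment: unique, ambiguous and tolerant matching", {
  ref <- c(mirA = "TAAGCTGCCAGTTGAAGAACTG",
           mirB = "ACGTACGTAAGGTTCCAAGGTT",
           mirB2 = "ACGTACGTAAGGTTCCAAGGTT")   # same sequence as mirB
  col <- data.frame(sequence = c("TAAGCTGCCAGTTGAAGAACTG",
                                 "ACGTACGTAAGGTTCCAAGGTT",
                                 "GGGGGGGGGGGGGGGGGGGGGG"),
                    multiplicity = c(4L, 2L, 1L))
  asg <- assign_reads(col, ref)
  expect_equal(asg$counts[["mirA"]], 4)
  expect_equal(asg$ambiguous, 2)   # two identical matures: discarded, tallied
  expect_equal(asg$unmatched, 1)
  # conservation of multiplicity
  expect_equal(sum(asg$counts) + asg$ambiguous + asg$unmatched,
               sum(col$multiplicity))
  expect_error(assign_reads(col, c(a = "ACGT", a = "ACGG")), "duplicate")
})

test_that("3' tolerance matches the exhaustive-variant oracle", {
  set.seed(5)
  cfg <- tiny_config()
  r <- generate_reference(cfg)
  ref <- setNames(r$mature$sequence, r$mature$id)
  hp <- setNames(r$hairpin$sequence, r$hairpin$id)
  pof <- setNames(r$mature$precursor_id, r$mature$id)
  # probe trimmed/extended variants of random matures plus random junk
  probes <- character(0)
  for (i in sample(length(ref), 8)) {
    m <- ref[[i]]
    probes <- c(probes, m, substr(m, 1, nchar(m) - 1),
                substr(m, 1, nchar(m) - 2))
    h <- hp[[pof[[names(ref)[i]]]]]
    p <- regexpr(m, h, fixed = TRUE)
    probes <- c(probes, substr(h, p, p + nchar(m) + 1))
  }
  probes <- unique(c(probes, replicate(5, paste(sample(c("A", "C", "G", "T"),
                                                       22, TRUE),
                                                collapse = ""))))
  col <- data.frame(sequence = probes,
                    multiplicity = rep(1L, length(probes)))
  asg <- assign_reads(col, ref, hp, pof, three_prime_tolerance = 2)
  for (i in seq_along(probes)) {
    hits <- naive_assign(probes[i], ref, hp, pof, 2)
    got <- asg$counts[hits]
    if (length(hits) == 1) expect_gte(got, 1)
  }
  # totals conserved
  expect_equal(sum(asg$counts) + asg$ambiguous + asg$unmatched, length(probes))
})

test_that("detection filter applies the >=3 in >=1 sample rule at boundaries", {
  m <- rbind(low = c(2L, 2L, 2L), edge = c(3L, 0L, 0L), high = c(10L, 5L, 1L))
  colnames(m) <- paste0("s", 1:3)
  cm <- count_matrix(m)
  f <- detection_filter(cm)
  expect_setequal(rownames(f$counts), c("edge", "high"))
  expect_equal(unname(f$lib_sizes), unname(colSums(m[c("edge", "high"), ])))
  # all pass -> identity
  f2 <- detection_filter(count_matrix(m[3, , drop = FALSE]))
  expect_equal(f2$counts, m[3, , drop = FALSE])
})

test_that("RPM normalization scales to a million and errors on empty libraries", {
  m <- matrix(c(1L, 3L, 10L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cm <- count_matrix(m)
  r <- rpm_normalize(cm)
  expect_equal(r[, "s1"], c(a = 250000, b = 750000))
  expect_equal(unname(colSums(r)), c(1e6, 1e6))
  m0 <- matrix(c(1L, 0L), 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_error(rpm_normalize(count_matrix(m0)), "s2")
})

test_that("noise-free synthesis round-trips to the generating counts", {
  cfg <- tiny_config(seed = 21)
  r <- generate_reference(cfg)
  mf <- sample_manifest(cfg)[1:6, ]
  cm <- simulate_counts(cfg, r$truth, mf)
  seqs <- setNames(r$mature$sequence, r$mature$id)
  rs <- synthesize_reads(cm, seqs, cfg, tempfile("rt"))
  q <- quantify_samples(setNames(rs$path, rs$sample_id), seqs, cfg$adapter,
                        min_mean_quality = 20)
  expect_equal(q$cm$counts[rownames(cm$counts), colnames(cm$counts)],
               cm$counts)
  expect_equal(sum(q$stats$ambiguous), 0)
})
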