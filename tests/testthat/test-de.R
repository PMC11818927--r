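test_that("TMM factors: identities, permutation invariance, edgeR agreement", {
  m <- matrix(rep(c(10L, 50L, 200L, 7L), 3), ncol = 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  nf <- tmm_factors(count_matrix(m))
  expect_equal(unname(nf$factors), rep(1, 3))       # identical columns
  expect_equal(exp(mean(log(nf$factors))), 1)

  set.seed(19)
  n <- 2000
  mu <- exp(rnorm(n, log(200), 1))
  cts <- cbind(s1 = rpois(n, mu), s2 = rpois(n, 2 * mu),
               s3 = rpois(n, 0.7 * mu))
  rownames(cts) <- paste0("g", 1:n)
  cm <- count_matrix(cts)
  nf2 <- tmm_factors(cm)
  # pure depth differences are absorbed by library size: factors ~ 1
  expect_true(all(abs(nf2$factors - 1) < 0.01))
  # gene order permutation leaves factors unchanged
  perm <- sample(n)
  nf3 <- tmm_factors(count_matrix(cts[perm, ]))
  expect_equal(nf3$factors, nf2$factors, tolerance = 1e-12)
  # independent implementation agreement (edgeR)
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(edgeR::DGEList(cts), method = "TMM")
  expect_equal(unname(nf2$factors), fe$samples$norm.factors,
               tolerance = 1e-3)
})

test_that("normalization factor recovers composition bias direction", {
  # sample B: half the genes doubled -> TMM should normalize on the
  # unchanged majority, giving B an effective upward size correction
  set.seed(20)
  n <- 2000
  mu <- exp(rnorm(n, log(200), 0.8))
  bias <- c(rep(2, n * 0.25), rep(1, n * 0.75))
  cts <- cbind(A = rpois(n, mu), B = rpois(n, mu * bias))
  rownames(cts) <- paste0("g", 1:n)
  nf <- tmm_factors(count_matrix(cts))
  eff <- nf$factors * colSums(cts)
  # unchanged genes should equalize: effective ratio tracks the unbiased
  # library ratio (sum over unchanged genes), not the raw column sums
  unbiased_ratio <- sum(cts[bias == 1, "B"]) / sum(cts[bias == 1, "A"])
  expect_equal(unname(eff["B"] / eff["A"]), unbiased_ratio, tolerance = 0.05)
  # and the factors agree with the reference implementation
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(edgeR::DGEList(cts), method = "TMM")
  expect_equal(unname(nf$factors), fe$samples$norm.factors, tolerance = 1e-3)
})

test_that("dispersion estimation recovers the simulating parameter", {
  # Poisson data: estimated common dispersion is near zero
  fx <- nb_fixture(seed = 23, n = 200, phi = 0)
  d0 <- estimate_dispersion(fx$cm, fx$groups)
  expect_lte(d0$common, 0.05)

  # NB data with phi = 0.2: within +-30% over 20 seeds
  ests <- vapply(1:20, function(s) {
    fx <- nb_fixture(seed = 100 + s, n = 200, phi = 0.2)
    estimate_dispersion(fx$cm, fx$groups)$common
  }, 0)
  expect_lt(abs(mean(ests) / 0.2 - 1), 0.3)
  expect_true(all(abs(ests / 0.2 - 1) < 0.5))

  # infinite prior weight collapses tagwise onto the common value
  fx <- nb_fixture(seed = 24, n = 50, phi = 0.1)
  dInf <- estimate_dispersion(fx$cm, fx$groups, prior_weight = Inf)
  expect_true(all(dInf$tagwise == dInf$common))
  expect_warning(
    estimate_dispersion(fx$cm, seq_along(fx$groups)),  # all singleton groups
    "singleton")
})

test_that("exact test: identities, label symmetry and the binomial limit", {
  m <- matrix(c(10L, 10L, 10L, 10L), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  cm <- count_matrix(m)
  grp <- c("A", "A", "B", "B")
  p <- nb_exact_test(cm, grp, dispersion = 0.1,
                     factors = setNames(rep(1, 4), colnames(m)))
  expect_equal(unname(p), 1)            # identical group sums
  expect_equal(nb_exact_test(cm, rev(grp), 0.1,
                             setNames(rep(1, 4), colnames(m))), p)

  # phi = 0 agrees with direct binomial enumeration to 1e-9
  set.seed(25)
  for (i in 1:100) {
    t <- sample(1:50, 1); zA <- sample(0:t, 1)
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    pr <- dbinom(0:t, t, nA / (nA + nB))
    oracle <- sum(pr[pr <= pr[zA + 1] * (1 + 1e-12)])
    expect_equal(perinatmir:::exact_nb_p(zA, t - zA, nA, nB, 0), oracle,
                 tolerance = 1e-9)
  }
  # all-zero gene -> p = 1
  expect_equal(perinatmir:::exact_nb_p(0, 0, 3, 3, 0.1), 1)
})

test_that("null pipeline p-values are calibrated at the 5% level", {
  fx <- nb_fixture(seed = 26, n = 2000, phi = 0.1)
  nf <- tmm_factors(fx$cm)
  disp <- estimate_dispersion(fx$cm, fx$groups, nf$factors)
  p <- nb_exact_test(fx$cm, fx$groups, disp$tagwise, nf$factors)
  # 99% binomial band around 0.05 at n = 2000: mean +- 2.58 * SE
  band <- 0.05 + c(-1, 1) * 2.58 * sqrt(0.05 * 0.95 / 2000)
  expect_gte(mean(p < 0.05), band[1])
  expect_lte(mean(p < 0.05), band[2])
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p
  expect_error(bh_fdr(c(0.1, NA)), "NA")
})

test_that("the DE decision rule applies strict thresholds", {
  calls <- call_de(log2(c(2, 1.5, 4, 1.2)), c(0.04, 0.01, 0.05, 0.001))
  expect_equal(calls$is_de, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$direction, rep("up", 4))
  expect_true(call_de(-log2(1.6), 0.04)$is_de)     # downregulation counts
  expect_equal(call_de(-1, 0.5)$direction, "down")
})

test_that("per-tissue DE recovers planted fold changes with controlled FDR", {
  res <- vapply(1:10, function(s) {
    n <- 200; n_de <- 20
    fx <- nb_fixture(seed = 300 + s, n = n, mu_mean = 200, phi = 0.1,
                     lfc = sample(c(-2, 2), n_de, replace = TRUE))
    nf <- tmm_factors(fx$cm)
    disp <- estimate_dispersion(fx$cm, fx$groups, nf$factors)
    p <- nb_exact_test(fx$cm, fx$groups, disp$tagwise, nf$factors)
    q <- bh_fdr(p)
    lfc <- de_logfc(fx$cm, fx$groups, "pre", nf$factors)
    hits <- which(call_de(lfc, q)$is_de)
    c(recall = mean(seq_len(n_de) %in% hits),
      fdr = if (length(hits)) mean(hits > n_de) else 0)
  }, c(recall = 0, fdr = 0))
  expect_gte(mean(res["recall", ]), 0.8)
  expect_lte(mean(res["fdr", ]), 0.1)
})

test_that("log fold change sign convention round-trips the generator truth", {
  cfg <- synthetic_config(seed = 27, n_mirnas = 80, frac_de = 0.15,
                          fc_range = c(4, 8), frac_specific = 0,
                          libsize_range = c(30000, 50000))
  r <- generate_reference(cfg)
  mf <- sample_manifest(cfg)
  mf <- mf[mf$tissue == "liver", ]
  cm <- simulate_counts(cfg, r$truth, mf)
  de <- suppressWarnings(de_analysis(detection_filter(cm), mf))
  truth <- r$truth$true_de[r$truth$true_de$tissue == "liver", ]
  hit <- merge(de[de$is_de, ], truth, by = "mirna")
  expect_gt(nrow(hit), 0)
  expect_true(all(sign(hit$log2fc.x) == sign(hit$log2fc.y)))
})

test_that("unbalanced groups run with a warning", {
  cfg <- tiny_config()
  r <- generate_reference(cfg)
  mf <- sample_manifest(cfg)
  mf <- mf[mf$tissue == "spleen", ]   # 3 prenatal vs 2 postnatal
  cm <- simulate_counts(cfg, r$truth, mf)
  expect_warning(de_analysis(detection_filter(cm), mf), "unbalanced")
})
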