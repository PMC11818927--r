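# Prenatal vs postnatal differential expression within each tissue:
# trimmed-mean-of-M-values (TMM) normalization, negative-binomial
# dispersion estimation by conditional likelihood on library-size-equalized
# pseudo-counts, the exact conditional NB test, Benjamini-Hochberg
# correction, and the fold-change / FDR decision rule.
#
# The dispersion and exact-test internals follow the quantile-adjusted
# conditional maximum-likelihood approach with two documented
# simplifications: pseudo-counts are obtained by scaling every sample to
# the geometric-mean effective library size (the conditional likelihood is
# evaluated on the resulting non-integer counts), and tagwise shrinkage
# uses a fixed prior weight on the average per-gene likelihood. Calibration
# and recovery, not numerical identity with any particular implementation,
# are the design targets.

#' TMM normalization factors
#'
#' Reference sample: the one whose 75th percentile of count/library-size is
#' closest to the mean across samples. For each sample, M (log2 expression
#' ratio vs the reference) and A (average log2 abundance) are computed over
#' genes positive in both; after trimming the extremes of M
#' (\code{trim_M}) and A (\code{trim_A}), the factor is the
#' inverse-variance-weighted mean of M (delta-method weights). Factors are
#' rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix()] with at least 2 samples.
#' @param trim_M two-sided trim fraction on M values (default 0.30).
#' @param trim_A two-sided trim fraction on A values (default 0.05).
#' @return list with \code{factors} (named, geometric mean 1) and
#'   \code{ref} (reference sample id).
#' @export
tmm_factors <- function(cm, trim_M = 0.30, trim_A = 0.05) {
  y <- cm$counts
  lib <- cm$lib_sizes
  if (ncol(y) < 2) stop("need at least 2 samples")
  if (any(lib <= 0)) stop("library sizes must be positive")

  f75 <- apply(y, 2, function(col) stats::quantile(col / sum(col), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))

  f <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    ok <- y[, j] > 0 & y[, ref] > 0
    if (!any(ok)) {
      stop("sample ", colnames(y)[j],
           " shares no positive genes with the reference")
    }
    yj <- y[ok, j]; yr <- y[ok, ref]
    M <- log2((yj / lib[j]) / (yr / lib[ref]))
    A <- 0.5 * log2((yj / lib[j]) * (yr / lib[ref]))
    w <- (lib[j] - yj) / (lib[j] * yj) + (lib[ref] - yr) / (lib[ref] * yr)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, 0)
  f <- f / exp(mean(log(f)))
  list(factors = stats::setNames(f, colnames(y)), ref = colnames(y)[ref])
}

# internal: scale all samples to the geometric-mean effective library size
equalized_pseudocounts <- function(counts, lib, factors) {
  eff <- lib * factors
  m <- exp(mean(log(eff)))
  sweep(counts, 2, m / eff, "*")
}

# internal: conditional NB log-likelihood of phi for one group of
# equal-library-size (pseudo) counts, given their sum. Rows = genes.
# Returns a genes x length(phi) matrix. A single-sample group carries no
# information (identically zero).
cond_loglik_matrix <- function(pseudo, phi_grid) {
  n <- ncol(pseudo)
  z <- rowSums(pseudo)
  out <- matrix(0, nrow(pseudo), length(phi_grid))
  for (k in seq_along(phi_grid)) {
    phi <- phi_grid[k]
    if (phi < 1e-10) {
      # Poisson limit: conditional likelihood is multinomial-uniform;
      # constant in phi, so contributes nothing to the profile
      out[, k] <- lgamma(z + 1) - rowSums(lgamma(pseudo + 1)) - z * log(n)
      next
    }
    r <- 1 / phi
    out[, k] <- rowSums(lgamma(pseudo + r)) - n * lgamma(r) +
      lgamma(n * r) - lgamma(z + n * r) + lgamma(z + 1) -
      rowSums(lgamma(pseudo + 1))
  }
  out
}

#' Estimate common and tagwise NB dispersion
#'
#' Maximizes the summed conditional log-likelihood over a dispersion grid
#' (library sizes equalized via pseudo-counts first). Tagwise dispersions
#' maximize the per-gene likelihood plus \code{prior_weight} times the mean
#' per-gene likelihood, shrinking noisy per-gene estimates towards the
#' common value; \code{prior_weight = Inf} returns the common value for
#' every gene.
#'
#' @param cm a [count_matrix()].
#' @param groups factor/character of group labels (one per sample).
#' @param factors TMM factors (default: computed).
#' @param phi_grid dispersion grid (default: 0 plus a log-spaced grid from
#'   1e-4 to 4).
#' @param prior_weight shrinkage weight (default 10).
#' @return list with \code{common}, \code{tagwise} (named per miRNA) and
#'   \code{grid}.
#' @export
estimate_dispersion <- function(cm, groups, factors = NULL,
                                phi_grid = c(0, exp(seq(log(1e-4), log(4),
                                                        length.out = 60))),
                                prior_weight = 10) {
  groups <- as.character(groups)
  if (is.null(factors)) factors <- tmm_factors(cm)$factors
  sizes <- table(groups)
  if (all(sizes < 2)) {
    warning("all groups are singletons; falling back to dispersion 0.1")
    return(list(common = 0.1,
                tagwise = stats::setNames(rep(0.1, nrow(cm$counts)),
                                          rownames(cm$counts)),
                grid = phi_grid))
  }
  pseudo <- equalized_pseudocounts(cm$counts, cm$lib_sizes, factors)
  ll <- matrix(0, nrow(cm$counts), length(phi_grid))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    ll <- ll + cond_loglik_matrix(pseudo[, cols, drop = FALSE], phi_grid)
  }
  informative <- rowSums(cm$counts) > 0
  common <- phi_grid[which.max(colSums(ll[informative, , drop = FALSE]))]
  lbar <- colMeans(ll[informative, , drop = FALSE])
  tagwise <- if (is.infinite(prior_weight)) {
    rep(common, nrow(ll))
  } else {
    phi_grid[apply(ll + matrix(prior_weight * lbar, nrow(ll),
                               length(phi_grid), byrow = TRUE), 1, which.max)]
  }
  list(common = common,
       tagwise = stats::setNames(tagwise, rownames(cm$counts)),
       grid = phi_grid)
}

# internal: exact conditional two-sided p-value for one gene.
# zA, zB: integer group sums of pseudo-counts; nA, nB: group sizes;
# phi: dispersion. Two-sided by summing all outcomes with probability no
# greater than the observed one.
exact_nb_p <- function(zA, zB, nA, nB, phi) {
  t <- zA + zB
  if (t == 0) return(1)
  a <- 0:t
  if (phi < 1e-10) {
    logp <- stats::dbinom(a, t, nA / (nA + nB), log = TRUE)
  } else {
    r <- 1 / phi
    mu <- t / (nA + nB)
    logp <- stats::dnbinom(a, size = nA * r, mu = nA * mu, log = TRUE) +
      stats::dnbinom(t - a, size = nB * r, mu = nB * mu, log = TRUE)
    logp <- logp - log(sum(exp(logp - max(logp)))) - max(logp)
  }
  pobs <- logp[zA + 1]
  min(1, sum(exp(logp[logp <= pobs + 1e-10])))
}

#' Exact conditional negative-binomial test
#'
#' Library sizes are equalized via TMM-scaled pseudo-counts; group sums are
#' rounded to the nearest integer and the two-sided exact conditional
#' p-value is computed by enumerating, under NB with the given dispersion
#' and the conditional total, all group-sum outcomes no more probable than
#' the observed one. With dispersion 0 this is exactly the conditional
#' binomial (Poisson) test. All-zero genes return p = 1.
#'
#' @param cm a [count_matrix()].
#' @param groups two group labels, one per sample.
#' @param dispersion scalar or per-miRNA vector of NB dispersions.
#' @param factors TMM factors (default: computed).
#' @return named vector of p-values in (0, 1].
#' @export
nb_exact_test <- function(cm, groups, dispersion, factors = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (is.null(factors)) factors <- tmm_factors(cm)$factors
  pseudo <- equalized_pseudocounts(cm$counts, cm$lib_sizes, factors)
  A <- groups == lv[1]
  zA <- round(rowSums(pseudo[, A, drop = FALSE]))
  zB <- round(rowSums(pseudo[, !A, drop = FALSE]))
  phi <- rep_len(dispersion, nrow(pseudo))
  p <- vapply(seq_len(nrow(pseudo)), function(i) {
    exact_nb_p(zA[i], zB[i], sum(A), sum(!A), phi[i])
  }, 0)
  stats::setNames(p, rownames(cm$counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1]; NA/NaN raise an error.
#' @return step-up adjusted q-values (monotone in p, q >= p).
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Generalized log2 fold change of group means of normalized counts
#'
#' Counts are scaled to the geometric-mean effective library size; a 0.5
#' pseudo-count is added to each group mean before the log ratio
#' \code{log2(mean(case) / mean(baseline))}.
#'
#' @param cm a [count_matrix()].
#' @param groups group labels, one per sample.
#' @param baseline baseline group label (denominator).
#' @param factors TMM factors (default: computed).
#' @param prior pseudo-count added to group means (default 0.5).
#' @return named vector of log2 fold changes (case vs baseline).
#' @export
de_logfc <- function(cm, groups, baseline, factors = NULL, prior = 0.5) {
  groups <- as.character(groups)
  if (is.null(factors)) factors <- tmm_factors(cm)$factors
  pseudo <- equalized_pseudocounts(cm$counts, cm$lib_sizes, factors)
  case <- groups != baseline
  mB <- rowMeans(pseudo[, !case, drop = FALSE])
  mC <- rowMeans(pseudo[, case, drop = FALSE])
  stats::setNames(log2((mC + prior) / (mB + prior)), rownames(cm$counts))
}

#' Apply the differential-expression decision rule
#'
#' DE iff the fold change in either direction exceeds \code{fc_threshold}
#' (strict) and the FDR is below \code{fdr_threshold} (strict).
#'
#' @param log2fc vector of log2 fold changes.
#' @param fdr matching vector of BH FDR values.
#' @param fc_threshold fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return data.frame with is_de and direction ("up"/"down").
#' @export
call_de <- function(log2fc, fdr, fc_threshold = 1.5, fdr_threshold = 0.05) {
  stopifnot(length(log2fc) == length(fdr))
  data.frame(is_de = 2^abs(log2fc) > fc_threshold & fdr < fdr_threshold,
             direction = ifelse(log2fc >= 0, "up", "down"))
}

#' Per-tissue prenatal vs postnatal differential expression
#'
#' For each tissue: subset the samples, normalize (TMM), estimate tagwise
#' dispersion, run the exact conditional NB test, adjust with BH within the
#' tissue, and apply the fold-change/FDR rule. Log2 fold changes are
#' postnatal vs prenatal. A warning is logged for unbalanced groups.
#'
#' @param cm a [count_matrix()] (detection-filtered).
#' @param manifest sample manifest with sample_id, tissue, stage.
#' @param tissues tissues to analyze (default: all in the manifest).
#' @param fc_threshold,fdr_threshold decision thresholds.
#' @param prior_weight tagwise shrinkage weight.
#' @return data.frame: mirna, tissue, log2fc, pvalue, fdr, direction, is_de.
#' @export
de_analysis <- function(cm, manifest, tissues = unique(manifest$tissue),
                        fc_threshold = 1.5, fdr_threshold = 0.05,
                        prior_weight = 10) {
  res <- lapply(tissues, function(t) {
    ids <- manifest$sample_id[manifest$tissue == t]
    ids <- intersect(ids, colnames(cm$counts))
    sub <- subset_count_matrix(cm, cols = ids)
    stage <- manifest$stage[match(ids, manifest$sample_id)]
    sizes <- table(stage)
    if (length(sizes) < 2) stop("tissue ", t, " lacks one of the stages")
    if (length(unique(sizes)) > 1) {
      warning(sprintf("tissue %s has unbalanced groups (%s)", t,
                      paste(sizes, collapse = " vs ")), call. = FALSE)
    }
    nf <- tmm_factors(sub)
    disp <- estimate_dispersion(sub, stage, nf$factors,
                                prior_weight = prior_weight)
    p <- nb_exact_test(sub, stage, disp$tagwise, nf$factors)
    q <- bh_fdr(p)
    lfc <- de_logfc(sub, stage, baseline = "prenatal", factors = nf$factors)
    calls <- call_de(lfc, q, fc_threshold, fdr_threshold)
    data.frame(mirna = rownames(sub$counts), tissue = t, log2fc = unname(lfc),
               pvalue = unname(p), fdr = unname(q), calls,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
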