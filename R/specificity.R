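# Tissue specificity: the tissue-specificity index (TSI), the
# entropy-based tissue-specificity score (TSS), categorical calls and
# specific-tissue assignment, plus the prenatal/postnatal/combined TSI
# variants.
#
# Neither metric has a universally printed formula in the applied
# literature, so the standard forms are adopted here and isolated in this
# file: TSI is the Yanai-style index sum(1 - x_i/x_max)/(N - 1); TSS is the
# Jensen-Shannon specificity score 1 - sqrt(JSD(p, e_t)) with base-2
# logarithms, where e_t is the single-tissue indicator distribution.

#' Tissue-specificity index (TSI)
#'
#' TSI = sum_i (1 - x_i / x_max) / (N - 1) over per-tissue mean expression.
#' 0 for a perfectly uniform profile, 1 for expression confined to a single
#' tissue.
#'
#' @param x non-negative numeric vector of per-tissue mean expression
#'   (length >= 2).
#' @return TSI in [0, 1]; NA for an all-zero profile.
#' @export
tsi <- function(x) {
  if (length(x) < 2) stop("need at least 2 tissues")
  if (any(x < 0)) stop("expression must be non-negative")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Row-wise TSI of an expression matrix
#' @param expr matrix of per-tissue mean expression (miRNA x tissue).
#' @return named numeric vector of TSI values.
#' @export
tsi_matrix <- function(expr) {
  apply(expr, 1, tsi)
}

# internal: Shannon entropy (log2) of a distribution; 0 log 0 = 0
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# internal: Jensen-Shannon divergence (log2) between distributions
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  shannon_entropy(m) - (shannon_entropy(p) + shannon_entropy(q)) / 2
}

#' Tissue-specificity score (TSS) against every tissue
#'
#' TSS_t = 1 - sqrt(JSD(p, e_t)) where p is the expression profile
#' normalized to a distribution and e_t the indicator distribution of
#' tissue t. Equals 1 iff the miRNA is expressed in tissue t only.
#'
#' @param x non-negative per-tissue expression vector (names = tissues);
#'   normalized internally to sum 1.
#' @return named numeric vector of per-tissue TSS values in [0, 1]; all NA
#'   for an all-zero profile.
#' @export
tss <- function(x) {
  if (any(x < 0)) stop("expression must be non-negative")
  if (sum(x) == 0) return(stats::setNames(rep(NA_real_, length(x)), names(x)))
  p <- x / sum(x)
  vapply(seq_along(p), function(t) {
    e <- numeric(length(p)); e[t] <- 1
    1 - sqrt(js_divergence(p, e))
  }, 0) -> s
  stats::setNames(s, names(x))
}

#' Categorize a TSI value
#'
#' Below 0.15: housekeeping; above 0.85: tissue-specific; boundary values
#' fall in the nonspecific middle band (strict inequalities).
#'
#' @param x numeric vector of TSI values in [0, 1] (NA allowed).
#' @param housekeeping_max housekeeping threshold (default 0.15).
#' @param specific_min tissue-specific threshold (default 0.85).
#' @return factor with levels housekeeping, nonspecific, tissue_specific.
#' @export
categorize_tsi <- function(x, housekeeping_max = 0.15, specific_min = 0.85) {
  out <- ifelse(is.na(x), NA_character_,
                ifelse(x < housekeeping_max, "housekeeping",
                       ifelse(x > specific_min, "tissue_specific",
                              "nonspecific")))
  factor(out, levels = c("housekeeping", "nonspecific", "tissue_specific"))
}

#' Assign the specific tissue from TSS scores
#'
#' The tissue with the highest TSS wins; exact ties break to the
#' lexicographically smallest tissue name.
#'
#' @param scores named numeric vector of per-tissue TSS values.
#' @return tissue name.
#' @export
assign_tissue <- function(scores) {
  ok <- is.finite(scores)
  if (!any(ok)) stop("all TSS values undefined")
  s <- scores[ok]
  cand <- names(s)[s == max(s)]
  sort(cand)[1]
}

#' Stage-wise TSI variants
#'
#' Computes per-miRNA TSI from per-tissue mean expression within the
#' prenatal samples, within the postnatal samples, and over all samples.
#' A variant whose sample subset covers fewer than two tissues is NA.
#'
#' @param expr expression matrix (miRNA x sample), typically RPM.
#' @param manifest sample manifest with sample_id, tissue, stage.
#' @return data.frame mirna, tsi_prenatal, tsi_postnatal, tsi_all; the
#'   \code{"missing_cells"} attribute lists tissue x stage cells with no
#'   samples.
#' @export
tsi_variants <- function(expr, manifest) {
  stopifnot(all(colnames(expr) %in% manifest$sample_id))
  mf <- manifest[match(colnames(expr), manifest$sample_id), ]
  variant <- function(keep) {
    sub <- expr[, keep, drop = FALSE]
    tis <- mf$tissue[keep]
    if (length(unique(tis)) < 2) return(rep(NA_real_, nrow(expr)))
    means <- t(apply(sub, 1, function(r) tapply(r, tis, mean)))
    tsi_matrix(means)
  }
  out <- data.frame(
    mirna = rownames(expr),
    tsi_prenatal = variant(mf$stage == "prenatal"),
    tsi_postnatal = variant(mf$stage == "postnatal"),
    tsi_all = variant(rep(TRUE, nrow(mf))),
    row.names = NULL, stringsAsFactors = FALSE)
  cells <- table(mf$tissue, mf$stage)
  miss <- which(cells == 0, arr.ind = TRUE)
  attr(out, "missing_cells") <- if (nrow(miss)) {
    paste(rownames(cells)[miss[, 1]], colnames(cells)[miss[, 2]], sep = ":")
  } else character(0)
  out
}

#' Full specificity analysis of an expression matrix
#'
#' Per-tissue means (over all samples) feed TSI and TSS; the TSI category
#' uses the combined TSI, and the specific tissue is assigned (by maximum
#' TSS) only for tissue-specific miRNAs.
#'
#' @param expr expression matrix (miRNA x sample), typically RPM of
#'   detection-filtered counts.
#' @param manifest sample manifest.
#' @param housekeeping_max,specific_min category thresholds.
#' @return data.frame: mirna, tsi variants, category, assigned_tissue
#'   ("none" unless tissue_specific), and per-tissue tss_<tissue> columns.
#' @export
specificity_analysis <- function(expr, manifest, housekeeping_max = 0.15,
                                 specific_min = 0.85) {
  mf <- manifest[match(colnames(expr), manifest$sample_id), ]
  means <- t(apply(expr, 1, function(r) tapply(r, mf$tissue, mean)))
  variants <- tsi_variants(expr, manifest)
  tss_mat <- t(apply(means, 1, tss))
  colnames(tss_mat) <- paste0("tss_", colnames(means))
  category <- categorize_tsi(variants$tsi_all, housekeeping_max, specific_min)
  assigned <- vapply(seq_len(nrow(expr)), function(i) {
    if (is.na(category[i]) || category[i] != "tissue_specific") return("none")
    assign_tissue(stats::setNames(tss_mat[i, ], colnames(means)))
  }, "")
  data.frame(variants, category = category, assigned_tissue = assigned,
             tss_mat, row.names = NULL, stringsAsFactors = FALSE)
}
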