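# Statistics for the validation assays: 2^-ddCt relative quantification,
# dual-luciferase normalization, protein-normalized glucose production and
# two-group / multi-group comparisons.

#' Relative expression by the 2^-ddCt method
#'
#' Per target gene: dCt = target Ct - reference Ct; ddCt = dCt minus the
#' mean dCt of the calibrator group; relative expression = 2^-ddCt. The
#' calibrator group has geometric mean 1 by construction. Amplification
#' efficiency is fixed at 2 (the method's assumption).
#'
#' @param ct_table data.frame with sample_id, group, target, target_ct,
#'   reference, reference_ct.
#' @param calibrator calibrator group label.
#' @return input data.frame with added columns dct, ddct, rel_expr.
#' @export
ddct <- function(ct_table, calibrator) {
  need <- c("sample_id", "group", "target", "target_ct", "reference_ct")
  stopifnot(all(need %in% names(ct_table)))
  bad <- !is.finite(ct_table$reference_ct)
  if (any(bad)) {
    stop("missing reference Ct for sample(s): ",
         paste(ct_table$sample_id[bad], collapse = ", "))
  }
  if (!any(ct_table$group == calibrator)) {
    stop("no samples in calibrator group '", calibrator, "'")
  }
  out <- ct_table
  out$dct <- out$target_ct - out$reference_ct
  out$ddct <- NA_real_
  for (g in unique(out$target)) {
    sel <- out$target == g
    cal <- mean(out$dct[sel & out$group == calibrator])
    out$ddct[sel] <- out$dct[sel] - cal
  }
  out$rel_expr <- 2^-out$ddct
  out
}

#' Dual-luciferase relative activity
#'
#' Each well's firefly/Renilla ratio is normalized to the mean ratio of the
#' same construct's mimic-control wells, so the control mean is 1.
#'
#' @param luc_table data.frame with construct, treatment
#'   ("mimic"/"mimic_control"), firefly, renilla.
#' @return input with added columns ratio and activity.
#' @export
luciferase_relative_activity <- function(luc_table) {
  stopifnot(all(c("construct", "treatment", "firefly", "renilla") %in%
                  names(luc_table)))
  if (any(luc_table$renilla == 0)) stop("zero Renilla signal")
  out <- luc_table
  out$ratio <- out$firefly / out$renilla
  out$activity <- NA_real_
  for (con in unique(out$construct)) {
    sel <- out$construct == con
    ctrl <- out$ratio[sel & out$treatment == "mimic_control"]
    if (!length(ctrl)) stop("construct ", con, " has no mimic_control wells")
    out$activity[sel] <- out$ratio[sel] / mean(ctrl)
  }
  out
}

#' Protein-normalized glucose production
#'
#' @param glucose raw glucose per well.
#' @param protein protein content per well (> 0).
#' @param group group label per well.
#' @return list with \code{wells} (per-well normalized values) and
#'   \code{summary} (group means and SDs).
#' @export
glucose_output <- function(glucose, protein, group) {
  if (any(protein <= 0)) stop("protein content must be positive")
  norm <- glucose / protein
  s <- data.frame(
    group = unique(group),
    mean = tapply(norm, group, mean)[unique(group)],
    sd = tapply(norm, group, stats::sd)[unique(group)],
    n = as.integer(table(group)[unique(group)]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(wells = data.frame(group = group, glucose = glucose,
                          protein = protein, normalized = norm),
       summary = s)
}

#' Compare assay groups (t-test or one-way ANOVA)
#'
#' Two groups: two-sided two-sample t-test (pooled variance by default);
#' more: one-way ANOVA. Significance flags: ** for p < 0.01, * for
#' p < 0.05, ns otherwise.
#'
#' @param values numeric measurements.
#' @param groups matching group labels (>= 2 groups, >= 2 values each).
#' @param var_equal pooled-variance t-test (default TRUE)?
#' @return list with method, statistic, p_value, flag.
#' @export
group_compare <- function(values, groups, var_equal = TRUE) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (length(sizes) == 2) {
    lv <- names(sizes)
    ht <- stats::t.test(values[groups == lv[1]], values[groups == lv[2]],
                        var.equal = var_equal)
    method <- "t"; statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    fit <- stats::aov(values ~ factor(groups))
    an <- summary(fit)[[1]]
    method <- "anova"; statistic <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
  }
  flag <- if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(method = method, statistic = statistic, p_value = p, flag = flag)
}
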