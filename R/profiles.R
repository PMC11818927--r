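# Sample-level expression structure: transforms, Pearson correlation
# matrix, PCA and hierarchical clustering order.

#' Transform an expression matrix
#'
#' Applies log2(x + pseudocount) and/or per-row z-scoring. The transform is
#' recorded in the \code{"transform"} attribute. Constant rows are left at 0
#' by z-scoring rather than producing NaN.
#'
#' @param expr numeric matrix (miRNA x sample), e.g. RPM values.
#' @param log2 apply log2(x + pseudocount)?
#' @param pseudocount pseudocount for the log transform.
#' @param zscore z-score rows afterwards?
#' @return transformed matrix with attribute \code{transform}.
#' @export
expression_transform <- function(expr, log2 = TRUE, pseudocount = 1,
                                 zscore = FALSE) {
  tag <- "raw"
  if (log2) {
    expr <- base::log2(expr + pseudocount)
    tag <- sprintf("log2(x+%g)", pseudocount)
  }
  if (zscore) {
    mu <- rowMeans(expr)
    sd <- apply(expr, 1, stats::sd)
    expr <- (expr - mu) / ifelse(sd > 0, sd, 1)
    tag <- paste0(tag, " z-scored")
  }
  attr(expr, "transform") <- tag
  expr
}

#' Pearson correlation matrix among samples
#'
#' @param expr numeric matrix (features x samples).
#' @return symmetric sample x sample correlation matrix with unit diagonal;
#'   pairs involving a zero-variance sample are NA and such samples are
#'   listed in the \code{"undefined_samples"} attribute.
#' @export
pearson_matrix <- function(expr) {
  if (nrow(expr) < 2) stop("need at least 2 features")
  sds <- apply(expr, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(expr, method = "pearson"))
  bad <- which(sds == 0)
  if (length(bad)) {
    cc[bad, ] <- NA_real_
    cc[, bad] <- NA_real_
  }
  diag(cc) <- 1
  attr(cc, "undefined_samples") <- colnames(expr)[bad]
  cc
}

#' Principal component analysis of samples
#'
#' Samples are the observations (rows of the internally transposed matrix);
#' components come from the SVD of the column-centered data. Variance
#' fractions are non-increasing and sum to 1 over all returned components.
#'
#' @param expr numeric matrix (features x samples), typically z-scored
#'   log2 RPM.
#' @return list with \code{coords} (samples x components), \code{var_frac},
#'   \code{sdev} and \code{rotation}.
#' @export
pca_profiles <- function(expr) {
  if (ncol(expr) < 2) stop("need at least 2 samples")
  if (anyNA(expr)) stop("missing values not allowed")
  p <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  list(coords = p$x, var_frac = v / sum(v), sdev = p$sdev,
       rotation = p$rotation, center = p$center)
}

#' Correlation distance (1 - Pearson)
#' @param expr numeric matrix (features x samples).
#' @return dist-convertible symmetric matrix of 1 - correlation.
#' @export
cor_distance <- function(expr) {
  1 - pearson_matrix(expr)
}

#' Hierarchical clustering leaf order
#'
#' @param d symmetric distance matrix with zero diagonal (e.g.
#'   [cor_distance()] output).
#' @param linkage linkage method (default "average").
#' @return list with \code{order} (leaf labels in dendrogram order),
#'   \code{merge_heights} and the \code{hclust} object.
#' @export
hcluster_order <- function(d, linkage = "average") {
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  list(order = hc$labels[hc$order], merge_heights = hc$height, hclust = hc)
}
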