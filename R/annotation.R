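# Annotation-class assignment (known / conserved / novel), arm census and
# genomic-context classification of miRNA precursors.

#' Extract the seed of a mature miRNA
#'
#' The seed is the 7-nt substring at positions 2--8 (1-based, inclusive) of
#' the mature sequence; this window is the conventional definition and is
#' configurable.
#'
#' @param sequence character vector of mature sequences (RNA or DNA
#'   alphabet; normalized internally).
#' @param from,to 1-based seed window (default 2--8).
#' @return character vector of T-normalized seeds.
#' @export
seed_of <- function(sequence, from = 2L, to = 8L) {
  sequence <- normalize_seq(sequence)
  if (any(nchar(sequence) < to)) {
    stop(sprintf("sequences must be at least %d nt to extract a seed", to))
  }
  substr(sequence, from, to)
}

#' Classify mature miRNAs as known, conserved or novel
#'
#' A candidate exactly equal to a same-species reference mature is
#' \code{known}; otherwise, one whose seed equals the seed of any
#' other-species reference mature is \code{conserved}; anything else is
#' \code{novel}. Precedence: known > conserved > novel.
#'
#' @param sequences character vector of candidate mature sequences.
#' @param same_species_ref character vector of same-species reference
#'   matures.
#' @param other_species_ref character vector of other-species reference
#'   matures.
#' @return factor with levels known, conserved, novel.
#' @export
classify_mirna <- function(sequences, same_species_ref, other_species_ref) {
  sequences <- normalize_seq(sequences)
  same <- normalize_seq(same_species_ref)
  other_seeds <- unique(seed_of(normalize_seq(other_species_ref)))
  cls <- ifelse(sequences %in% same, "known",
                ifelse(seed_of(sequences) %in% other_seeds,
                       "conserved", "novel"))
  factor(cls, levels = c("known", "conserved", "novel"))
}

#' Census of precursor arm usage per annotation class
#'
#' Counts, for each class, the precursors yielding a 5p mature only, a 3p
#' mature only, or both arms. A precursor with matures of differing classes
#' is counted under the highest-precedence class among them.
#'
#' @param matures data.frame with columns id, precursor_id, arm
#'   ("5p"/"3p") and class.
#' @param precursor_ids optional vector of all precursor ids; matures whose
#'   precursor is absent raise an error.
#' @return data.frame with one row per class plus a Total row: columns
#'   class, precursors, p5_only, p3_only, both, matures.
#' @export
arm_census <- function(matures, precursor_ids = NULL) {
  stopifnot(all(c("id", "precursor_id", "arm", "class") %in% names(matures)))
  if (!is.null(precursor_ids)) {
    orphan <- setdiff(matures$precursor_id, precursor_ids)
    if (length(orphan)) {
      stop("mature(s) reference unknown precursor(s): ",
           paste(orphan, collapse = ", "))
    }
  }
  lv <- c("known", "conserved", "novel")
  per_prec <- split(matures, matures$precursor_id)
  rows <- lapply(per_prec, function(d) {
    cls <- lv[min(match(d$class, lv))]
    kind <- if (all(c("5p", "3p") %in% d$arm)) "both"
            else if ("5p" %in% d$arm) "p5_only" else "p3_only"
    data.frame(class = cls, kind = kind, n_mat = nrow(d))
  })
  tab <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(lv, function(cl) {
    d <- tab[tab$class == cl, ]
    data.frame(class = cl, precursors = nrow(d),
               p5_only = sum(d$kind == "p5_only"),
               p3_only = sum(d$kind == "p3_only"),
               both = sum(d$kind == "both"),
               matures = sum(d$n_mat))
  }))
  rbind(out, data.frame(class = "Total", precursors = sum(out$precursors),
                        p5_only = sum(out$p5_only), p3_only = sum(out$p3_only),
                        both = sum(out$both), matures = sum(out$matures)))
}

#' Genomic context of precursor intervals
#'
#' Classifies each precursor interval against gene models (exon tables):
#' \code{intergenic} if it overlaps no gene span; per overlapping gene,
#' \code{exonic} if it only touches exons, \code{intronic} if only introns,
#' \code{intron_exon} if it touches both within the same gene. When several
#' genes overlap, the per-gene calls are combined with priority
#' intron_exon > exonic > intronic. Strand is ignored. Intervals are
#' 0-based half-open.
#'
#' @param precursors data.frame with columns id, chrom, start0, end0.
#' @param genes gene annotation data.frame (gene_id, chrom, feature = exon,
#'   start0, end0), as from [read_gene_annotation()].
#' @return character vector of contexts, named by precursor id.
#' @export
genomic_context <- function(precursors, genes) {
  if (any(precursors$start0 >= precursors$end0)) {
    stop("malformed precursor interval: start0 must be < end0")
  }
  genes <- genes[genes$feature == "exon", ]
  gl <- split(genes, genes$gene_id)
  spans <- data.frame(
    gene_id = names(gl),
    chrom = vapply(gl, function(d) d$chrom[1], ""),
    start0 = vapply(gl, function(d) min(d$start0), 0),
    end0 = vapply(gl, function(d) max(d$end0), 0),
    stringsAsFactors = FALSE)

  # IRanges is 1-based closed; a 0-based half-open [s, e) maps to [s+1, e]
  pr <- IRanges::IRanges(precursors$start0 + 1L, precursors$end0)
  sp <- IRanges::IRanges(spans$start0 + 1L, spans$end0)
  out <- rep("intergenic", nrow(precursors))

  for (i in seq_len(nrow(precursors))) {
    same_chrom <- spans$chrom == precursors$chrom[i]
    hits <- which(same_chrom &
                    IRanges::overlapsAny(sp, pr[i]))
    if (!length(hits)) next
    calls <- vapply(hits, function(h) {
      ex <- gl[[spans$gene_id[h]]]
      ex <- ex[order(ex$start0), ]
      exr <- IRanges::IRanges(ex$start0 + 1L, ex$end0)
      has_exon <- any(IRanges::overlapsAny(exr, pr[i]))
      has_intron <- FALSE
      if (nrow(ex) > 1) {
        inr <- IRanges::IRanges(ex$end0[-nrow(ex)] + 1L, ex$start0[-1])
        has_intron <- any(IRanges::overlapsAny(inr, pr[i]))
      }
      if (has_exon && has_intron) "intron_exon"
      else if (has_exon) "exonic"
      else if (has_intron) "intronic"
      else "intergenic"    # overlaps the span edge only; should not occur
    }, "")
    pri <- c("intron_exon", "exonic", "intronic", "intergenic")
    out[i] <- pri[min(match(calls, pri))]
  }
  stats::setNames(out, precursors$id)
}
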