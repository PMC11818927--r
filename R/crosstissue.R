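# Cross-tissue DE structure and downstream target logic: overlap
# distribution, direction conservation, the specificity-enrichment
# chi-square, canonical seed-site target prediction, hypergeometric
# gene-set enrichment and the anti-correlated miRNA-mRNA network.

#' Distribution of DE miRNAs over numbers of tissues
#'
#' Counts, for k = 1..n_tissues, the miRNAs differentially expressed in
#' exactly k tissues.
#'
#' @param de_sets named list (tissue -> character vector of DE miRNA ids).
#' @return list with \code{counts} (named integer vector over k),
#'   \code{percent} (share of the unique total, 2 decimals) and
#'   \code{total_unique}.
#' @export
overlap_distribution <- function(de_sets) {
  n_tissues <- length(de_sets)
  membership <- table(unlist(lapply(de_sets, unique)))
  counts <- vapply(seq_len(n_tissues),
                   function(k) sum(membership == k), 0L)
  names(counts) <- seq_len(n_tissues)
  total <- length(membership)
  pct <- if (total > 0) percent_value(counts, total) else counts * NA_real_
  list(counts = counts, percent = pct, total_unique = total)
}

#' Direction conservation of DE miRNAs across tissues
#'
#' A miRNA is direction-conserved iff it is DE in at least two tissues with
#' the same direction in every tissue where it is DE. Also returns the
#' signed log2FC heatmap table (NA where not DE).
#'
#' @param de_results data.frame from [de_analysis()] (mirna, tissue,
#'   log2fc, direction, is_de).
#' @return list with \code{conserved} (named logical per DE miRNA) and
#'   \code{heatmap} (miRNA x tissue matrix of signed log2FC, NA where not
#'   DE).
#' @export
direction_conservation <- function(de_results) {
  de <- de_results[de_results$is_de, ]
  mirnas <- unique(de$mirna)
  conserved <- vapply(mirnas, function(m) {
    d <- de[de$mirna == m, ]
    nrow(d) >= 2 && length(unique(d$direction)) == 1
  }, TRUE)
  tissues <- unique(de_results$tissue)
  heat <- matrix(NA_real_, length(mirnas), length(tissues),
                 dimnames = list(mirnas, tissues))
  heat[cbind(match(de$mirna, mirnas), match(de$tissue, tissues))] <- de$log2fc
  list(conserved = conserved, heatmap = heat)
}

#' Chi-square association between DE status and tissue specificity
#'
#' 2x2 contingency table of DE x tissue-specific flags over a common miRNA
#' universe, tested with a 1-df chi-square without continuity correction.
#'
#' @param de_flag logical vector (is the miRNA DE anywhere?).
#' @param specific_flag matching logical vector (is it tissue-specific?).
#' @return list with \code{table}, \code{statistic}, \code{p_value}; the
#'   statistic and p are NA when a margin is zero.
#' @export
specificity_enrichment <- function(de_flag, specific_flag) {
  stopifnot(length(de_flag) == length(specific_flag))
  tab <- table(factor(de_flag, c(TRUE, FALSE)),
               factor(specific_flag, c(TRUE, FALSE)),
               dnn = c("de", "specific"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, statistic = NA_real_, p_value = NA_real_))
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, statistic = unname(ht$statistic),
       p_value = unname(ht$p.value))
}

#' Predict canonical seed-match target sites in 3'UTRs
#'
#' Site classes follow the canonical definitions: 7mer-m8 = exact match to
#' the reverse complement of miRNA positions 2-8; 7mer-A1 = reverse
#' complement of positions 2-7 followed by an A in the target; 8mer = both
#' (reverse complement of 2-8 followed by A). Overlapping matches report
#' only the strongest class (8mer > 7mer-m8 > 7mer-A1). UTRs shorter than
#' 8 nt yield no sites. Scanning is on the given strand only, with no
#' wobble pairing.
#'
#' @param mirna_seqs named character vector of mature miRNA sequences.
#' @param utrs named character vector of 3'UTR sequences (DNA).
#' @return data.frame: mirna, gene, start0 (0-based site start in the UTR),
#'   site_type.
#' @export
predict_targets <- function(mirna_seqs, utrs) {
  stopifnot(!is.null(names(mirna_seqs)), !is.null(names(utrs)))
  utrs <- toupper(utrs)
  res <- list()
  for (m in names(mirna_seqs)) {
    sq <- normalize_seq(mirna_seqs[[m]])
    core8 <- revcomp(seed_of(sq))                 # rc of positions 2-8
    motifs <- c(`8mer` = paste0(core8, "A"),
                `7mer-m8` = core8,
                `7mer-A1` = paste0(revcomp(substr(sq, 2, 7)), "A"))
    for (g in names(utrs)) {
      utr <- utrs[[g]]
      if (nchar(utr) < 8) next
      cand <- list()
      for (ty in names(motifs)) {
        hits <- gregexpr(motifs[[ty]], utr, fixed = TRUE)[[1]]
        if (hits[1] > 0) {
          cand[[ty]] <- data.frame(start0 = as.integer(hits) - 1L,
                                   end0 = as.integer(hits) - 1L +
                                     nchar(motifs[[ty]]),
                                   site_type = ty,
                                   stringsAsFactors = FALSE)
        }
      }
      if (!length(cand)) next
      cand <- do.call(rbind, cand)
      # strongest class first, then position; greedily drop overlaps
      cand <- cand[order(match(cand$site_type, names(motifs)), cand$start0), ]
      kept <- integer(0)
      for (i in seq_len(nrow(cand))) {
        clash <- any(cand$start0[i] < cand$end0[kept] &
                       cand$end0[i] > cand$start0[kept])
        if (!clash) kept <- c(kept, i)
      }
      keep <- cand[kept, ]
      res[[length(res) + 1]] <- data.frame(mirna = m, gene = g,
                                           start0 = keep$start0,
                                           site_type = keep$site_type,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(mirna = character(0), gene = character(0),
                      start0 = integer(0), site_type = character(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$mirna, out$gene, out$start0), , drop = FALSE]
}

#' Build the miRNA-mRNA regulatory network
#'
#' An edge joins a DE miRNA to a predicted target gene when, in the same
#' tissue, the gene's expression moved in the direction opposite to the
#' miRNA (repression logic).
#'
#' @param mirna_dirs data.frame: mirna, tissue, direction ("up"/"down") of
#'   DE miRNAs.
#' @param gene_dirs data.frame: gene, tissue, direction of mRNA changes.
#' @param targets data.frame from [predict_targets()] (mirna, gene).
#' @return data.frame of edges: mirna, gene, tissue, mirna_direction,
#'   gene_direction.
#' @export
build_network <- function(mirna_dirs, gene_dirs, targets) {
  pairs <- unique(targets[c("mirna", "gene")])
  e <- merge(mirna_dirs, pairs, by = "mirna")
  e <- merge(e, gene_dirs, by = c("gene", "tissue"),
             suffixes = c("_mirna", "_gene"))
  e <- e[e$direction_mirna != e$direction_gene, ]
  out <- data.frame(mirna = e$mirna, gene = e$gene, tissue = e$tissue,
                    mirna_direction = e$direction_mirna,
                    gene_direction = e$direction_gene,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$gene, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each set, the one-sided (upper-tail) hypergeometric probability of
#' drawing at least the observed overlap when sampling the gene list from
#' the universe, with BH correction across sets.
#'
#' @param genes character vector of hit genes (must be within the universe).
#' @param gene_sets named list of character vectors (GMT-style).
#' @param universe character vector: the gene universe.
#' @return data.frame: set, overlap, set_size, list_size, universe_size,
#'   p_value, fdr.
#' @export
geneset_enrichment <- function(genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  genes <- unique(genes)
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    stop("gene list contains ids outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(universe); n <- length(genes)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), universe)
    k <- length(intersect(genes, set))
    p <- stats::phyper(k - 1, length(set), N - length(set), n,
                       lower.tail = FALSE)
    data.frame(set = s, overlap = k, set_size = length(set), list_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}
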