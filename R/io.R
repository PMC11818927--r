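# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA / FASTQ (via Biostrings), a GFF-like TSV gene annotation, GMT gene
# sets, TSV sample manifests and TSV count matrices.

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' On a malformed file the error message reports the index of the first
#' structurally broken record.
#'
#' @param path file path.
#' @return data.frame with columns id, sequence, quality.
#' @export
read_fastq <- function(path) {
  bad <- locate_bad_fastq_record(path)
  if (!is.na(bad)) {
    stop(sprintf("malformed FASTQ record %d in %s", bad, path), call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL)
}

# internal: structural scan; returns the index of the first broken record,
# or NA when every record has its four well-formed lines
locate_bad_fastq_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0) return(NA_integer_)
  if (n %% 4 != 0) return((n %/% 4) + 1L)
  heads <- lines[seq(1, n, by = 4)]
  seps <- lines[seq(3, n, by = 4)]
  seqs <- lines[seq(2, n, by = 4)]
  quals <- lines[seq(4, n, by = 4)]
  bad <- !startsWith(heads, "@") | !startsWith(seps, "+") |
    nchar(seqs) != nchar(quals)
  if (any(bad)) which(bad)[1] else NA_integer_
}

#' Write reads as FASTQ (Phred+33)
#' @param reads data.frame with columns id, sequence, quality.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$id
  qual <- Biostrings::PhredQuality(reads$quality)
  qs <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeXStringSet(qs, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read the GFF-like TSV gene annotation
#'
#' Disk format: tab-separated with header
#' \code{gene_id, chrom, strand, feature, start, end}, one row per exon,
#' 1-based inclusive coordinates. Internally coordinates become 0-based
#' half-open (\code{start0}, \code{end0}).
#'
#' @param path file path.
#' @return data.frame with columns gene_id, chrom, strand, feature, start0, end0.
#' @export
read_gene_annotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "feature", "start", "end")
  if (!all(need %in% names(d))) {
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  }
  conv <- gff_to_interval(d$start, d$end)
  data.frame(d[c("gene_id", "chrom", "strand", "feature")], conv,
             stringsAsFactors = FALSE)
}

#' Write the gene annotation table (converting back to 1-based inclusive)
#' @param genes data.frame with columns gene_id, chrom, strand, feature, start0, end0.
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  conv <- interval_to_gff(genes$start0, genes$end0)
  out <- data.frame(genes[c("gene_id", "chrom", "strand", "feature")], conv)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#' @param path file path.
#' @return named list of character vectors (set name -> gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (second GMT column).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample manifest (TSV: sample_id, tissue, stage, replicate)
#' @param path file path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "stage", "replicate")
  if (!all(need %in% names(d))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  d
}

#' Write a sample manifest
#' @param manifest data.frame with sample_id, tissue, stage, replicate.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix (TSV, miRNAs as rows, sample IDs as header)
#' @param path file path.
#' @return a [count_matrix()] object.
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  count_matrix(as.matrix(d))
}

#' Write a count matrix as TSV
#' @param cm a [count_matrix()] object.
#' @param path output path.
#' @export
write_count_matrix <- function(cm, path) {
  out <- data.frame(mirna = rownames(cm$counts), cm$counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
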