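# From raw small-RNA reads to a filtered, normalized miRNA count matrix:
# adapter trimming, quality filtering and collapsing, direct assignment to
# mature sequences, the detection filter and RPM normalization.

#' Trim the 3' adapter from read sequences
#'
#' The insert is everything before the earliest occurrence of the full
#' adapter. When the full adapter is absent, a read suffix equal to an
#' adapter prefix of at least \code{min_overlap} bases is trimmed (the
#' longest such overlap wins). Reads with no adapter evidence yield
#' \code{NA} unless \code{keep_untrimmed} is set, in which case the full
#' read is retained as the insert.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter-prefix overlap at the read 3' end (>= 5).
#' @param keep_untrimmed retain full-length reads with no adapter?
#' @return character vector of inserts (NA where no adapter was found and
#'   retention is disabled).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L, keep_untrimmed = FALSE) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (min_overlap < 5) stop("min_overlap must be >= 5")
  adapter <- normalize_seq(adapter)
  reads <- toupper(reads)
  pos <- regexpr(adapter, reads, fixed = TRUE)
  insert <- ifelse(pos > 0, substr(reads, 1, pos - 1), NA_character_)

  todo <- which(is.na(insert))
  if (length(todo)) {
    L <- nchar(reads[todo])
    found <- rep(NA_integer_, length(todo))
    ks <- seq(min(nchar(adapter) - 1L, max(L)), min_overlap)   # longest first
    for (k in ks) {
      open <- is.na(found) & L >= k
      if (!any(open)) break
      hit <- open & substr(reads[todo], L - k + 1L, L) == substr(adapter, 1L, k)
      found[hit] <- L[hit] - k
    }
    insert[todo[!is.na(found)]] <-
      substr(reads[todo[!is.na(found)]], 1, found[!is.na(found)])
  }
  if (keep_untrimmed) insert[is.na(insert)] <- reads[is.na(insert)]
  insert
}

#' Quality- and length-filter inserts and collapse duplicates
#'
#' Inserts outside the length window, below the mean Phred quality, or
#' untrimmed (\code{NA}) are dropped; identical surviving inserts are merged
#' with summed multiplicity. The insert length distribution is computed over
#' retained inserts, weighted by multiplicity.
#'
#' @param inserts character vector of trimmed inserts (NA = untrimmed).
#' @param qualities optional Phred+33 quality strings of the original reads;
#'   mean quality is evaluated over the insert bases.
#' @param length_window integer c(min, max) insert length window, within
#'   15--35 nt.
#' @param min_mean_quality minimum mean Phred quality (default Q20).
#' @return list with \code{collapsed} (data.frame sequence, multiplicity,
#'   class \code{collapsed_reads}), \code{length_dist} (named fractions) and
#'   \code{n_clean} (total retained multiplicity).
#' @export
clean_and_collapse <- function(inserts, qualities = NULL,
                               length_window = c(18L, 26L),
                               min_mean_quality = 20) {
  if (length_window[1] < 15 || length_window[2] > 35 ||
      length_window[1] > length_window[2]) {
    stop("length_window must lie within [15, 35]")
  }
  keep <- !is.na(inserts)
  len <- nchar(inserts)
  keep <- keep & len >= length_window[1] & len <= length_window[2]
  if (!is.null(qualities) && min_mean_quality > 0) {
    mq <- mean_phred(substr(qualities, 1, ifelse(is.na(len), 0, len)))
    keep <- keep & !is.na(mq) & mq >= min_mean_quality
  }
  retained <- inserts[keep]
  tab <- table(retained)
  collapsed <- data.frame(sequence = names(tab),
                          multiplicity = as.integer(tab),
                          stringsAsFactors = FALSE, row.names = NULL)
  class(collapsed) <- c("collapsed_reads", "data.frame")
  ld <- if (nrow(collapsed)) {
    d <- tapply(collapsed$multiplicity, nchar(collapsed$sequence), sum)
    d / sum(d)
  } else numeric(0)
  list(collapsed = collapsed, length_dist = ld,
       n_clean = sum(collapsed$multiplicity))
}

# internal: mean Phred score of Phred+33 quality strings
mean_phred <- function(q) {
  vapply(q, function(s) {
    if (!nzchar(s)) return(NA_real_)
    mean(utf8ToInt(s)) - 33
  }, 0, USE.NAMES = FALSE)
}

#' Assign collapsed reads to mature miRNAs
#'
#' An insert matching exactly one mature sequence adds its multiplicity to
#' that miRNA. Matching is exact, optionally extended to 3'-end isomiRs:
#' with \code{three_prime_tolerance = t}, trimmed variants (up to t bases
#' removed from the mature 3' end) and -- when hairpin templates are given
#' -- templated extensions (up to t genomic bases appended) also match.
#' Inserts matching more than one miRNA are discarded and tallied as
#' ambiguous; the rest are unmatched.
#'
#' @param collapsed \code{collapsed_reads} data.frame (sequence, multiplicity).
#' @param mature_ref named character vector: miRNA id -> mature sequence.
#' @param hairpins optional named character vector of hairpin sequences used
#'   to template 3' extensions; names are matched through
#'   \code{precursor_of}.
#' @param precursor_of optional named character vector: miRNA id ->
#'   hairpin/precursor id.
#' @param three_prime_tolerance max 3' trim/extension in nt (default 0).
#' @return list with \code{counts} (named integer vector over all reference
#'   miRNAs), \code{ambiguous} and \code{unmatched} multiplicity tallies.
#' @export
assign_reads <- function(collapsed, mature_ref, hairpins = NULL,
                         precursor_of = NULL, three_prime_tolerance = 0L) {
  if (anyDuplicated(names(mature_ref))) stop("duplicate mature miRNA ids")
  if (is.null(names(mature_ref))) stop("mature reference must be named")
  mature_ref <- normalize_seq(mature_ref)
  tol <- as.integer(three_prime_tolerance)

  variants <- variant_table(mature_ref, hairpins, precursor_of, tol)
  hit_ids <- split(variants$id, variants$seq)
  n_hits <- lengths(lapply(hit_ids, unique))

  counts <- stats::setNames(integer(length(mature_ref)), names(mature_ref))
  ambiguous <- 0L; unmatched <- 0L
  m <- hit_ids[collapsed$sequence]
  for (i in seq_len(nrow(collapsed))) {
    ids <- unique(m[[i]])
    if (is.null(ids)) {
      unmatched <- unmatched + collapsed$multiplicity[i]
    } else if (length(ids) == 1L) {
      counts[ids] <- counts[ids] + collapsed$multiplicity[i]
    } else {
      ambiguous <- ambiguous + collapsed$multiplicity[i]
    }
  }
  list(counts = counts, ambiguous = ambiguous, unmatched = unmatched)
}

# internal: enumerate the matchable sequence variants of every mature
variant_table <- function(mature_ref, hairpins, precursor_of, tol) {
  ids <- names(mature_ref)
  out <- data.frame(id = ids, seq = unname(mature_ref),
                    stringsAsFactors = FALSE)
  if (tol > 0) {
    for (k in seq_len(tol)) {
      trimmed <- substr(mature_ref, 1, nchar(mature_ref) - k)
      out <- rbind(out, data.frame(id = ids, seq = unname(trimmed)))
    }
    if (!is.null(hairpins) && !is.null(precursor_of)) {
      hp <- normalize_seq(hairpins)
      for (i in seq_along(mature_ref)) {
        h <- hp[[precursor_of[[ids[i]]]]]
        p <- regexpr(mature_ref[[i]], h, fixed = TRUE)
        if (p > 0) {
          end <- p + nchar(mature_ref[[i]]) - 1L
          avail <- min(tol, nchar(h) - end)
          if (avail > 0) {
            ext <- vapply(seq_len(avail), function(k)
              substr(h, p, end + k), "")
            out <- rbind(out, data.frame(id = ids[i], seq = ext))
          }
        }
      }
    }
  }
  out
}

#' Quantify one FASTQ file against a mature reference
#'
#' Convenience wrapper: read, trim, clean/collapse, assign.
#'
#' @param path FASTQ path.
#' @param mature_ref named character vector of mature sequences.
#' @param adapter 3' adapter sequence.
#' @param length_window,min_mean_quality,min_overlap see
#'   [clean_and_collapse()] and [trim_adapter()].
#' @param ... passed to [assign_reads()].
#' @return list with \code{counts}, \code{ambiguous}, \code{unmatched},
#'   \code{n_clean}, \code{length_dist}.
#' @export
quantify_sample <- function(path, mature_ref, adapter,
                            length_window = c(18L, 26L),
                            min_mean_quality = 20, min_overlap = 5L, ...) {
  fq <- read_fastq(path)
  inserts <- trim_adapter(fq$sequence, adapter, min_overlap = min_overlap)
  cc <- clean_and_collapse(inserts, fq$quality, length_window,
                           min_mean_quality)
  asg <- assign_reads(cc$collapsed, mature_ref, ...)
  c(asg, list(n_clean = cc$n_clean, length_dist = cc$length_dist))
}

#' Quantify a set of per-sample FASTQ files into a count matrix
#'
#' @param paths named character vector: sample id -> FASTQ path.
#' @param mature_ref named character vector of mature sequences.
#' @param adapter 3' adapter sequence.
#' @param ... passed on to [quantify_sample()].
#' @return list with \code{cm} (a [count_matrix()]; library sizes = assigned
#'   reads) and \code{stats} (per-sample clean/assigned/ambiguous/unmatched
#'   tallies) and \code{length_dist} (pooled insert-length fractions).
#' @export
quantify_samples <- function(paths, mature_ref, adapter, ...) {
  stopifnot(!is.null(names(paths)))
  per <- lapply(paths, quantify_sample, mature_ref = mature_ref,
                adapter = adapter, ...)
  counts <- vapply(per, `[[`, numeric(length(mature_ref)), "counts")
  rownames(counts) <- names(mature_ref)
  stats <- data.frame(
    sample_id = names(paths),
    n_clean = vapply(per, `[[`, 0, "n_clean"),
    assigned = colSums(counts),
    ambiguous = vapply(per, `[[`, 0, "ambiguous"),
    unmatched = vapply(per, `[[`, 0, "unmatched"),
    row.names = NULL, stringsAsFactors = FALSE)
  pooled <- Reduce(function(a, b) {
    all_len <- union(names(a), names(b))
    av <- stats::setNames(numeric(length(all_len)), all_len)
    av[names(a)] <- a; av[names(b)] <- av[names(b)] + b; av
  }, lapply(per, function(p) p$length_dist * p$n_clean))
  list(cm = count_matrix(counts), stats = stats,
       length_dist = pooled / sum(pooled))
}

#' Apply the detection filter
#'
#' Retains miRNAs with a read count of at least \code{min_count} in at least
#' \code{min_samples} samples; library sizes are recomputed over the
#' retained rows.
#'
#' @param cm a [count_matrix()].
#' @param min_count minimum count (default 3).
#' @param min_samples minimum number of samples reaching it (default 1).
#' @return filtered [count_matrix()].
#' @export
detection_filter <- function(cm, min_count = 3L, min_samples = 1L) {
  stopifnot(min_count >= 1, min_samples >= 1)
  keep <- rowSums(cm$counts >= min_count) >= min_samples
  count_matrix(cm$counts[keep, , drop = FALSE])
}

#' Reads-per-million normalization
#'
#' @param cm a [count_matrix()]; every library size must be positive.
#' @return numeric matrix of RPM values (columns sum to 1e6).
#' @export
rpm_normalize <- function(cm) {
  zero <- cm$lib_sizes == 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(names(cm$lib_sizes)[zero], collapse = ", "))
  }
  sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6
}
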