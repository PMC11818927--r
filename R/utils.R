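# Small shared helpers: sequence alphabet normalization, reverse complement,
# percentage formatting and coordinate conversion.

#' Normalize an RNA/DNA sequence to the uppercase DNA alphabet
#'
#' Mature miRNA sequences are conventionally written in the RNA alphabet
#' (with U); all internal machinery works on DNA (with T). Every sequence
#' entering the package passes through this converter.
#'
#' @param x character vector of sequences.
#' @return uppercase character vector with U replaced by T.
#' @export
normalize_seq <- function(x) {
  gsub("U", "T", toupper(x), fixed = TRUE)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero
#'
#' Base \code{round()} uses banker's rounding; report percentages are rounded
#' half-up so that e.g. 20.125 renders as 20.13.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count over a denominator, rounded half-up to 2 decimals
#'
#' @param num numerator count(s).
#' @param den denominator count.
#' @return numeric percentage(s).
#' @export
percent_value <- function(num, den) {
  stopifnot(den > 0)
  round_half_up(100 * num / den, 2)
}

#' Format a percentage the way census tables print it
#'
#' Two decimals, trailing zeros trimmed ("53.14", "13.9", "0.1").
#'
#' @param num numerator count(s).
#' @param den denominator count.
#' @return character vector.
#' @export
format_percent <- function(num, den) {
  v <- sprintf("%.2f", percent_value(num, den))
  v <- sub("0+$", "", v)
  sub("\\.$", "", v)
}

# Disk coordinates are GFF-style 1-based inclusive; in-memory intervals are
# 0-based half-open. The two converters below are the only crossing points.

#' Convert 0-based half-open interval columns to 1-based inclusive
#' @param start0,end0 integer vectors, start0 < end0.
#' @return data.frame with columns start, end (1-based inclusive).
#' @export
interval_to_gff <- function(start0, end0) {
  stopifnot(all(start0 < end0))
  data.frame(start = start0 + 1L, end = end0)
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#' @param start,end integer vectors, start <= end.
#' @return data.frame with columns start0, end0.
#' @export
gff_to_interval <- function(start, end) {
  stopifnot(all(start <= end))
  data.frame(start0 = start - 1L, end0 = end)
}

# internal: stop() with a consistent configuration-error prefix naming the field
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# internal: largest-remainder apportionment of n items to proportions p.
# Guarantees the result sums to n and each count is within 1 of n*p.
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
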