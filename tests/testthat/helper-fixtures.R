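# Shared fixtures and independent brute-force oracles used across tests.

tiny_config <- function(seed = 11, ...) {
  synthetic_config(seed = seed, n_mirnas = 40,
                   libsize_range = c(2000, 4000), junk_frac = 0, ...)
}

# deterministic NB count fixture: n genes, two groups of size n_per,
# optional true log2 fold changes on the first genes
nb_fixture <- function(seed, n = 200, n_per = 3, mu_mean = 100, phi = 0.1,
                       lfc = numeric(0), lib_spread = c(0.9, 1.1)) {
  set.seed(seed)
  mu <- exp(stats::rnorm(n, log(mu_mean), 1))
  libs <- stats::runif(2 * n_per, lib_spread[1], lib_spread[2])
  grp <- rep(c("pre", "post"), each = n_per)
  cts <- sapply(seq_len(2 * n_per), function(j) {
    m <- mu * libs[j]
    if (grp[j] == "post" && length(lfc)) {
      m[seq_along(lfc)] <- m[seq_along(lfc)] * 2^lfc
    }
    if (phi > 0) stats::rnbinom(n, mu = m, size = 1 / phi)
    else stats::rpois(n, m)
  })
  rownames(cts) <- paste0("g", seq_len(n))
  colnames(cts) <- paste0("s", seq_len(2 * n_per))
  list(cm = count_matrix(cts), groups = grp)
}

# per-base membership oracle for genomic context
naive_context <- function(prec_row, genes) {
  bases <- seq(prec_row$start0, prec_row$end0 - 1)
  genes <- genes[genes$feature == "exon" & genes$chrom == prec_row$chrom, ]
  calls <- character(0)
  for (g in unique(genes$gene_id)) {
    ex <- genes[genes$gene_id == g, ]
    ex <- ex[order(ex$start0), ]
    exon_bases <- unlist(Map(function(s, e) seq(s, e - 1), ex$start0, ex$end0))
    span <- seq(min(ex$start0), max(ex$end0) - 1)
    intron_bases <- setdiff(span, exon_bases)
    in_ex <- any(bases %in% exon_bases)
    in_in <- any(bases %in% intron_bases)
    if (in_ex && in_in) calls <- c(calls, "intron_exon")
    else if (in_ex) calls <- c(calls, "exonic")
    else if (in_in) calls <- c(calls, "intronic")
  }
  if (!length(calls)) return("intergenic")
  pri <- c("intron_exon", "exonic", "intronic")
  pri[min(match(calls, pri))]
}

# naive position-by-position motif scan for seed sites
naive_seed_scan <- function(mirna_seq, utr) {
  sq <- normalize_seq(mirna_seq)
  core <- revcomp(seed_of(sq))
  motifs <- list(`8mer` = paste0(core, "A"),
                 `7mer-m8` = core,
                 `7mer-A1` = paste0(revcomp(substr(sq, 2, 7)), "A"))
  sites <- data.frame(start0 = integer(0), end0 = integer(0),
                      site_type = character(0))
  for (ty in names(motifs)) {
    m <- motifs[[ty]]; w <- nchar(m)
    for (i in seq_len(max(0, nchar(utr) - w + 1))) {
      if (substr(utr, i, i + w - 1) == m) {
        sites <- rbind(sites, data.frame(start0 = i - 1L, end0 = i - 1L + w,
                                         site_type = ty))
      }
    }
  }
  if (!nrow(sites)) return(sites[c("start0", "site_type")])
  sites <- sites[order(match(sites$site_type, names(motifs)), sites$start0), ]
  kept <- integer(0)
  for (i in seq_len(nrow(sites))) {
    if (!any(sites$start0[i] < sites$end0[kept] &
               sites$end0[i] > sites$start0[kept])) kept <- c(kept, i)
  }
  out <- sites[kept, c("start0", "site_type")]
  out[order(out$start0), , drop = FALSE]
}

# exhaustive 3'-variant matcher for read assignment
naive_assign <- function(insert, mature_ref, hairpins, precursor_of, tol) {
  hits <- character(0)
  for (id in names(mature_ref)) {
    m <- mature_ref[[id]]
    vars <- m
    if (tol > 0) {
      for (k in seq_len(tol)) vars <- c(vars, substr(m, 1, nchar(m) - k))
      h <- hairpins[[precursor_of[[id]]]]
      p <- regexpr(m, h, fixed = TRUE)
      if (p > 0) {
        for (k in seq_len(tol)) {
          e <- p + nchar(m) - 1 + k
          if (e <= nchar(h)) vars <- c(vars, substr(h, p, e))
        }
      }
    }
    if (insert %in% vars) hits <- c(hits, id)
  }
  hits
}

# exhaustive hypergeometric upper tail by enumeration (universe <= 25)
enum_hyper_p <- function(k_obs, set_size, universe_size, list_size) {
  total <- choose(universe_size, list_size)
  p <- 0
  for (k in k_obs:min(set_size, list_size)) {
    p <- p + choose(set_size, k) *
      choose(universe_size - set_size, list_size - k) / total
  }
  p
}
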