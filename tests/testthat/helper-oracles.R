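# Independent brute-force oracles and fixture builders shared by the tests.

# Exact HWE p-value by direct enumeration of the conditional distribution:
# P(h | n, n1) = n! / (nAA! h! naa!) * 2^h * n1! * n2! / (2n)!
hwe_brute <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n1 <- 2 * min(n_AA, n_aa) + n_Aa
  n2 <- 2 * n - n1
  if (n1 == 0) return(1)
  hets <- seq(n1 %% 2, min(n1, n2), by = 2)
  logp <- vapply(hets, function(h) {
    rare_hom <- (n1 - h) / 2
    com_hom <- n - h - rare_hom
    lfactorial(n) - lfactorial(com_hom) - lfactorial(h) -
      lfactorial(rare_hom) + h * log(2) +
      lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Sliding-window IUPAC matcher: every position where the pattern matches,
# returning 0-based cut coordinates (start + offset), interior cuts only.
iupac_brute <- function(seq, site, offset) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  s <- strsplit(toupper(seq), "")[[1]]
  pat <- strsplit(toupper(site), "")[[1]]
  L <- length(s); m <- length(pat)
  cuts <- integer(0)
  if (L >= m) for (i in seq_len(L - m + 1)) {
    if (all(mapply(function(b, p) b %in% iupac[[p]], s[i:(i + m - 1)], pat)))
      cuts <- c(cuts, i - 1L + offset)
  }
  sort(cuts[cuts > 0 & cuts < L])
}

# genotype_matrix from a dosage matrix (rows = samples), biallelic sites
make_gm <- function(dos, sample_ids = paste0("S", seq_len(nrow(dos))),
                    chrom = rep("Chr01", ncol(dos)),
                    pos = seq(1000, by = 1000, length.out = ncol(dos)),
                    ref = rep("A", ncol(dos)), alt = rep("T", ncol(dos))) {
  a1 <- (dos == 2L) * 1L
  a2 <- (dos >= 1L) * 1L
  genotype_matrix(a1, a2, sample_ids, chrom, pos, ref, alt)
}

# small VCF text fixture on disk; returns the path
write_vcf_fixture <- function(records, samples) {
  path <- file.path(tempdir(), paste0("fix", as.integer(stats::runif(1, 1, 1e8)),
                                      ".vcf"))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}
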