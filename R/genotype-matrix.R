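#' Diploid genotype matrix
#'
#' The central container of the package: an ordered set of samples genotyped
#' at an ordered set of variant sites. Genotypes are stored as two
#' samples-by-loci matrices of 0-based allele indices (`a1`, `a2`), so that
#' multiallelic sites are representable; `NA` in both slots marks a missing
#' call (half-missing calls such as `./1` are treated as missing).
#'
#' @param a1,a2 integer matrices (samples x loci) of allele indices, 0 = REF.
#' @param sample_ids character vector of unique sample identifiers.
#' @param chrom character vector of chromosome names, one per locus.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference alleles.
#' @param alt character vector of comma-separated alternate alleles.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, sample_ids, chrom, pos, ref, alt) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(sample_ids); L <- length(pos)
  stopifnot(nrow(a1) == n, ncol(a1) == L, all(dim(a1) == dim(a2)),
            length(chrom) == L, length(ref) == L, length(alt) == L,
            !anyDuplicated(sample_ids), all(pos >= 1, na.rm = TRUE))
  # a call is missing iff both slots are NA; enforce jointly
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  n_alt <- ifelse(alt == "" | is.na(alt), 0L,
                  lengths(strsplit(as.character(alt), ",", fixed = TRUE)))
  amax <- suppressWarnings(pmax(apply(a1, 2, max, na.rm = TRUE),
                                apply(a2, 2, max, na.rm = TRUE)))
  bad <- which(is.finite(amax) & amax > n_alt)
  if (length(bad))
    stop("allele index exceeds REF+ALT allele count at site ", bad[1])
  structure(list(sample_ids = as.character(sample_ids),
                 chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_sites(x), "sites\n")
  cat("  chromosomes:", paste(unique(x$chrom)[seq_len(min(6, length(unique(x$chrom))))],
                              collapse = ", "),
      if (length(unique(x$chrom)) > 6) "..." else "", "\n")
  cat("  missing calls:", sum(is.na(x$a1)), "\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname genotype_matrix
#' @export
n_sites <- function(x) length(x$pos)

#' Allele dosage view
#'
#' Counts of non-reference alleles per call (0, 1 or 2; `NA` missing). For
#' biallelic sites this is the usual alternate-allele dosage.
#'
#' @param x a `genotype_matrix`.
#' @return integer matrix, samples x loci, dimnames set.
#' @export
dosage <- function(x) {
  d <- (x$a1 > 0L) + (x$a2 > 0L)
  dimnames(d) <- list(x$sample_ids, paste0(x$chrom, ":", x$pos))
  d
}

#' Per-site locus integrity (INT)
#'
#' Fraction of samples with a non-missing call at each site.
#'
#' @param x a `genotype_matrix`.
#' @return numeric vector in \[0, 1\], one value per site.
#' @export
site_integrity <- function(x) colMeans(!is.na(x$a1))

#' Number of alleles in the site definition (REF + ALT)
#' @param x a `genotype_matrix`.
#' @return integer vector per site.
#' @export
site_n_alleles <- function(x) {
  1L + ifelse(x$alt == "" | is.na(x$alt), 0L,
              lengths(strsplit(x$alt, ",", fixed = TRUE)))
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples sample index/logical/id vector (default: all).
#' @param sites site index or logical vector (default: all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, sites = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(x)) else {
    if (is.character(samples)) match(samples, x$sample_ids) else
      seq_len(n_samples(x))[samples]
  }
  if (anyNA(si)) stop("unknown sample id(s)")
  li <- if (is.null(sites)) seq_len(n_sites(x)) else seq_len(n_sites(x))[sites]
  genotype_matrix(x$a1[si, li, drop = FALSE], x$a2[si, li, drop = FALSE],
                  x$sample_ids[si], x$chrom[li], x$pos[li],
                  x$ref[li], x$alt[li])
}

# per-site allele counts over a row subset: (max alleles) x loci matrix
allele_counts <- function(x, rows = seq_len(n_samples(x))) {
  a1 <- x$a1[rows, , drop = FALSE]; a2 <- x$a2[rows, , drop = FALSE]
  amax <- max(1L, suppressWarnings(max(a1, a2, na.rm = TRUE)))
  cnt <- matrix(0, nrow = amax + 1L, ncol = n_sites(x))
  for (a in 0:amax)
    cnt[a + 1L, ] <- colSums(a1 == a, na.rm = TRUE) + colSums(a2 == a, na.rm = TRUE)
  cnt
}
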