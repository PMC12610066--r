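#' Read a VCF file into a genotype matrix
#'
#' Imports diploid GT calls from a VCF 4.x file. Phased (`|`) and unphased
#' (`/`) separators are treated identically; half-missing calls (`./1`) are
#' treated as fully missing; multiallelic records are retained with their
#' full allele complement.
#'
#' @param path path to a (plain or bgzipped) VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no GT genotype data: ", path)
  gt <- t(gt)                                   # samples x loci
  ok <- is.na(gt) | grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed GT call at record ", bad[2], " (sample ",
         rownames(gt)[bad[1]], "): '", gt[!ok][1], "'")
  }
  a1 <- sub("^([^/|]+).*$", "\\1", gt)
  a2 <- ifelse(grepl("[/|]", gt), sub("^.*[/|]([^/|]+)$", "\\1", gt), a1)
  a1 <- suppressWarnings(as.integer(ifelse(a1 == ".", NA, a1)))
  a2 <- suppressWarnings(as.integer(ifelse(a2 == ".", NA, a2)))
  dim(a1) <- dim(gt); dim(a2) <- dim(gt)
  genotype_matrix(a1, a2, rownames(gt),
                  chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"],
                  alt = ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]))
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a minimal deterministic VCF with GT-only genotype columns.
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (n_samples(x) < 1L) stop("cannot write a VCF with zero samples")
  gts <- matrix(paste(ifelse(is.na(x$a1), ".", x$a1),
                      ifelse(is.na(x$a2), ".", x$a2), sep = "/"),
                nrow = n_samples(x))
  recs <- paste(x$chrom, x$pos, ".", x$ref,
                ifelse(x$alt == "", ".", x$alt), ".", "PASS", ".", "GT",
                apply(gts, 2, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=germsnp_", utils::packageVersion("germsnp")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$sample_ids), collapse = "\t"),
               recs), con)
  invisible(path)
}

#' Minor allele frequency of one site
#'
#' Allele frequencies are computed over non-missing gene copies. For a
#' biallelic site this is `min(p, 1 - p)`; in general it is the frequency of
#' the second-most-frequent allele, which keeps the definition meaningful
#' for multiallelic records.
#'
#' @param x a [genotype_matrix()].
#' @param site site index.
#' @param rows optional sample-row subset.
#' @return frequency in \[0, 0.5\] (biallelic).
#' @export
minor_allele_frequency <- function(x, site, rows = seq_len(n_samples(x))) {
  a <- c(x$a1[rows, site], x$a2[rows, site])
  a <- a[!is.na(a)]
  if (!length(a)) stop("MAF undefined: all calls missing at site ", site)
  cnt <- tabulate(a + 1L, nbins = max(a) + 1L)
  if (sum(cnt > 0) < 2) return(0)
  sort(cnt, decreasing = TRUE)[2] / sum(cnt)
}

# vectorized per-site MAF (second-most-frequent allele) over a row subset
site_maf <- function(x, rows = seq_len(n_samples(x))) {
  cnt <- allele_counts(x, rows)
  tot <- colSums(cnt)
  second <- apply(cnt, 2, function(v) sort(v, decreasing = TRUE)[2])
  second[is.na(second)] <- 0
  ifelse(tot > 0, second / tot, NA_real_)
}

#' Filter sites on MAF and locus integrity
#'
#' Retains sites with minor allele frequency `>= maf_min` and locus
#' integrity (fraction of non-missing calls) `>= int_min`, both inclusive.
#' Sample set and site order are preserved; the operation is idempotent.
#' Sites where every call is missing are always removed.
#'
#' @param x a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param int_min minimum locus integrity (default 0.3).
#' @return a filtered [genotype_matrix()] (possibly with zero sites).
#' @export
filter_sites <- function(x, maf_min = 0.05, int_min = 0.3) {
  int <- site_integrity(x)
  maf <- site_maf(x)
  keep <- !is.na(maf) & maf >= maf_min & int >= int_min
  subset_genotypes(x, sites = keep)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic locus: given the observed allele
#' counts, the heterozygote count follows a hypergeometric-type distribution
#' over all configurations of matching parity; the p-value is the total
#' probability of configurations no more probable than the observed one
#' (two-sided, not mid-p). Computed by the standard stable recurrence from
#' the distribution mode.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual required")
  n1 <- 2 * min(n_AA, n_aa) + n_Aa          # copies of the rarer allele
  if (n1 == 0) return(1)                    # monomorphic: single configuration
  hets <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  # unnormalized probabilities by recurrence around the expected het count
  h0 <- hets[which.min(abs(hets - n1 * (2 * n - n1) / (2 * n)))]
  lp <- stats::setNames(numeric(length(hets)), hets)
  up <- function(h) {         # P(h+2)/P(h) with rare-hom = (n1-h)/2
    raa <- (n1 - h) / 2; rAA <- n - h - raa
    4 * raa * rAA / ((h + 2) * (h + 1))
  }
  i0 <- match(h0, hets)
  lp[i0] <- 0
  if (i0 < length(hets))
    for (i in (i0 + 1):length(hets)) lp[i] <- lp[i - 1] + log(up(hets[i - 1]))
  if (i0 > 1)
    for (i in (i0 - 1):1) lp[i] <- lp[i + 1] - log(up(hets[i]))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit alternative to the exact test,
#' without continuity correction.
#'
#' @inheritParams hwe_exact_test
#' @return p-value in (0, 1\].
#' @export
hwe_chisq_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual required")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p %in% c(0, 1)) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Read a population map
#'
#' Two-column TSV (`sample_id`, `pop`) mapping each sample to a population
#' code.
#'
#' @param path path to the TSV file (header optional, detected).
#' @return data.frame with columns `sample_id` and `pop`.
#' @export
read_popmap <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("sample", tolower(first))
  pm <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE,
                          col.names = c("sample_id", "pop"))
  if (anyDuplicated(pm$sample_id)) stop("duplicated sample ids in population map")
  pm
}

# validate pop map against matrix; returns factor of pops aligned to samples
align_popmap <- function(x, pop_map) {
  if (is.null(pop_map$sample_id) || is.null(pop_map$pop))
    stop("population map needs columns sample_id and pop")
  i <- match(x$sample_ids, pop_map$sample_id)
  if (anyNA(i))
    stop("samples missing from population map: ",
         paste(utils::head(x$sample_ids[is.na(i)], 5), collapse = ", "))
  factor(pop_map$pop[i], levels = unique(pop_map$pop))
}
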