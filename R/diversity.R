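#' Genetic diversity indices for allele-frequency vectors
#'
#' Scalar estimators evaluated on a vector of allele frequencies at one
#' locus. All of them are label-permutation invariant and zero (or one, for
#' allele numbers) at a monomorphic locus.
#'
#' * `compute_he()` — expected heterozygosity, He = 1 - sum(p_i^2).
#' * `compute_nei_h()` — Nei's gene diversity with the small-sample
#'   correction, H = 2n/(2n - 1) * (1 - sum(p_i^2)), where `n_typed` is the
#'   number of diploid individuals with data at the locus.
#' * `compute_ne()` — effective (expected) allele number, Ne = 1/sum(p_i^2).
#' * `compute_shannon()` — Shannon-Wiener index, I = -sum(p_i * ln p_i),
#'   natural logarithm, zero-frequency terms contributing 0.
#' * `compute_pic()` — polymorphism information content (Botstein
#'   estimator), PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2; bounded by
#'   0.375 for a biallelic locus.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @param n_typed number of diploid individuals genotyped (for `compute_nei_h`).
#' @return a single numeric value.
#' @name diversity_indices
NULL

check_freqs <- function(freqs) {
  if (any(freqs < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  freqs
}

#' @rdname diversity_indices
#' @export
compute_he <- function(freqs) 1 - sum(check_freqs(freqs)^2)

#' @rdname diversity_indices
#' @export
compute_nei_h <- function(freqs, n_typed) {
  if (n_typed < 1) stop("n_typed must be >= 1")
  2 * n_typed / (2 * n_typed - 1) * compute_he(freqs)
}

#' @rdname diversity_indices
#' @export
compute_ne <- function(freqs) 1 / sum(check_freqs(freqs)^2)

#' @rdname diversity_indices
#' @export
compute_shannon <- function(freqs) {
  p <- check_freqs(freqs)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname diversity_indices
#' @export
compute_pic <- function(freqs) {
  p <- check_freqs(freqs)
  s2 <- sum(p^2); s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)     # s2^2 - s4 = 2 * sum_{i<j} p_i^2 p_j^2
}

#' Observed heterozygosity at one site
#'
#' Fraction of heterozygous calls among non-missing calls, optionally over a
#' sample subset.
#'
#' @param x a [genotype_matrix()].
#' @param site site index.
#' @param rows optional sample-row subset (indices or ids).
#' @return value in \[0, 1\].
#' @export
compute_ho <- function(x, site, rows = seq_len(n_samples(x))) {
  if (is.character(rows)) rows <- match(rows, x$sample_ids)
  a1 <- x$a1[rows, site]; a2 <- x$a2[rows, site]
  ok <- !is.na(a1)
  if (!sum(ok)) stop("Ho undefined: no genotyped individuals at site ", site)
  mean(a1[ok] != a2[ok])
}

# per-locus index bundle for a sample subset; loci with no data dropped.
# Returns a data.frame with one row per retained locus.
locus_stats <- function(x, rows = seq_len(n_samples(x))) {
  cnt <- allele_counts(x, rows)
  tot <- colSums(cnt)
  keep <- tot > 0
  cnt <- cnt[, keep, drop = FALSE]; tot <- tot[keep]
  p <- sweep(cnt, 2, tot, "/")
  s2 <- colSums(p^2); s4 <- colSums(p^4)
  plog <- p; plog[plog == 0] <- 1
  n_typed <- tot / 2
  a1 <- x$a1[rows, keep, drop = FALSE]; a2 <- x$a2[rows, keep, drop = FALSE]
  het <- colSums(a1 != a2, na.rm = TRUE)
  second <- apply(cnt, 2, function(v) sort(v, decreasing = TRUE)[2])
  second[is.na(second)] <- 0
  data.frame(site = which(keep),
             chrom = x$chrom[keep], pos = x$pos[keep],
             n_typed = n_typed,
             maf = second / tot,
             na = colSums(cnt > 0),
             ne = 1 / s2,
             he = 1 - s2,
             h = 2 * n_typed / (2 * n_typed - 1) * (1 - s2),
             ho = het / n_typed,
             pic = 1 - s2 - (s2^2 - s4),
             i = -colSums(p * log(plog)))
}

#' Per-population diversity summary
#'
#' Computes the per-locus indices over the members of one population and
#' summarizes each index by its minimum, maximum and mean across loci.
#' Loci with no genotype data inside the population are skipped. `A` counts
#' loci at which at least two alleles are observed within the population.
#'
#' @param x a [genotype_matrix()].
#' @param pop_map data.frame (`sample_id`, `pop`), as from [read_popmap()].
#' @param code the population code to summarize.
#' @return an object of class `diversity_summary`: a list with the
#'   population `code`, sample size `n`, locus count `n_loci`, polymorphic
#'   locus count `A`, and a `stats` data.frame (row per index, columns
#'   min/max/mean).
#' @export
summarize_population <- function(x, pop_map, code) {
  pops <- align_popmap(x, pop_map)
  rows <- which(pops == code)
  if (!length(rows)) stop("unknown or empty population code: ", code)
  ls <- locus_stats(x, rows)
  idx <- c("maf", "ne", "he", "h", "na", "ho", "pic", "i")
  stats <- data.frame(index = idx,
                      min  = vapply(ls[idx], min,  numeric(1)),
                      max  = vapply(ls[idx], max,  numeric(1)),
                      mean = vapply(ls[idx], mean, numeric(1)),
                      row.names = idx)
  structure(list(code = code, n = length(rows), n_loci = nrow(ls),
                 A = sum(ls$na >= 2), stats = stats),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Population", x$code, "-", x$n, "samples,", x$n_loci, "loci, A =",
      x$A, "polymorphic\n")
  s <- x$stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %s\n", toupper(s$index[i]),
                render_range_mean(s$min[i], s$max[i], s$mean[i])))
  invisible(x)
}

#' Render and parse the "min-max(mean)" cell format
#'
#' Diversity tables report each index as a range followed by the mean in
#' brackets, all with three decimals (en dash between min and max).
#'
#' @param min,max,mean the three summary numbers.
#' @return `render_range_mean()`: a string; `parse_range_mean()`: a named
#'   numeric vector `c(min, max, mean)`.
#' @export
render_range_mean <- function(min, max, mean) {
  sprintf("%.3f–%.3f(%.3f)", min, max, mean)
}

#' @rdname render_range_mean
#' @param s a string produced by `render_range_mean()`.
#' @export
parse_range_mean <- function(s) {
  m <- regmatches(s, regexec(
    "^([0-9.]+)–([0-9.]+)\\(([0-9.]+)\\)$", s))[[1]]
  if (length(m) != 4) stop("not a min–max(mean) cell: ", s)
  stats::setNames(as.numeric(m[2:4]), c("min", "max", "mean"))
}

#' Population-wise diversity table
#'
#' One [summarize_population()] row per population plus a `Mean` row formed
#' as the unweighted arithmetic mean of the per-population means (and of the
#' polymorphic-locus counts `A`, rounded to the nearest integer).
#'
#' @param x a [genotype_matrix()].
#' @param pop_map data.frame (`sample_id`, `pop`).
#' @return a data.frame with columns `pop, MAF, Ne, He, H, A, Na, Ho, PIC, I`
#'   holding the per-population means, with the per-index min/max kept in
#'   `attr(, "summaries")` (the list of `diversity_summary` objects).
#' @export
diversity_table <- function(x, pop_map) {
  pops <- levels(align_popmap(x, pop_map))
  sums <- lapply(pops, function(p) summarize_population(x, pop_map, p))
  names(sums) <- pops
  mean_of <- function(s, ix) s$stats[ix, "mean"]
  tab <- data.frame(pop = pops,
                    MAF = vapply(sums, mean_of, numeric(1), "maf"),
                    Ne  = vapply(sums, mean_of, numeric(1), "ne"),
                    He  = vapply(sums, mean_of, numeric(1), "he"),
                    H   = vapply(sums, mean_of, numeric(1), "h"),
                    A   = vapply(sums, function(s) s$A, numeric(1)),
                    Na  = vapply(sums, mean_of, numeric(1), "na"),
                    Ho  = vapply(sums, mean_of, numeric(1), "ho"),
                    PIC = vapply(sums, mean_of, numeric(1), "pic"),
                    I   = vapply(sums, mean_of, numeric(1), "i"),
                    row.names = NULL)
  mean_row <- data.frame(pop = "Mean", t(colMeans(tab[, -1])))
  mean_row$A <- round(mean_row$A)
  out <- rbind(tab, mean_row)
  attr(out, "summaries") <- sums
  out
}

#' Write a diversity table as TSV
#'
#' Renders range cells as `min-max(mean)` with three decimals and `A` as an
#' integer with a thousands separator, mirroring the conventional layout of
#' germplasm diversity reports.
#'
#' @param tab result of [diversity_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(tab, path) {
  sums <- attr(tab, "summaries")
  cell <- function(code, ix, mean) {
    if (is.null(sums[[code]])) sprintf("%.3f", mean)
    else {
      s <- sums[[code]]$stats
      render_range_mean(s[ix, "min"], s[ix, "max"], s[ix, "mean"])
    }
  }
  rows <- vapply(seq_len(nrow(tab)), function(r) {
    code <- tab$pop[r]
    paste(code, sprintf("%.3f", tab$MAF[r]),
          cell(code, "ne", tab$Ne[r]), cell(code, "he", tab$He[r]),
          cell(code, "h", tab$H[r]),
          formatC(tab$A[r], format = "d", big.mark = ","),
          cell(code, "na", tab$Na[r]), cell(code, "ho", tab$Ho[r]),
          cell(code, "pic", tab$PIC[r]), cell(code, "i", tab$I[r]),
          sep = "\t")
  }, character(1))
  writeLines(c(paste("Pop", "MAF", "Ne", "He", "H", "A", "Na", "Ho", "PIC",
                     "I", sep = "\t"), rows), path)
  invisible(path)
}
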