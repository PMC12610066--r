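#' Simulation configuration for a structured germplasm panel
#'
#' Defines the generative model for synthetic diploid SNP genotypes: `K`
#' ancestral populations diverged from a common pool under per-population
#' drift `fst_per_pop` (Balding-Nichols beta model), labeled collection
#' populations whose members draw individual ancestry proportions from a
#' Dirichlet distribution, binomial genotype sampling from the mixed
#' per-sample allele frequency, and independent per-call missingness.
#'
#' The default `pop_sizes` mirror an eight-population germplasm panel of
#' 213 accessions (codes B, E, ES, ED, EY, G, X, Q with 29, 29, 10, 9, 11,
#' 29, 35, 61 members).
#'
#' @param n_ancestral_pops number of ancestral clusters K (default 3).
#' @param fst_per_pop divergence parameter(s) in (0, 1), recycled to K
#'   (default 0.1).
#' @param pop_sizes named integer vector of labeled-population sizes.
#' @param admixture_alpha Dirichlet concentration for per-sample ancestry
#'   (default 30; larger = purer samples).
#' @param n_loci number of SNP loci (default 5000).
#' @param n_chromosomes chromosomes the loci are spread over (default 12).
#' @param chrom_length chromosome length in bp used for positions (default 1e7).
#' @param missing_rate per-call missing probability in \[0, 1) (default 0.05).
#' @param maf_floor minimum ancestral allele frequency (default 0.05).
#' @param seed integer seed; the same config is guaranteed to reproduce the
#'   same dataset byte for byte.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_ancestral_pops = 3, fst_per_pop = 0.1,
                       pop_sizes = c(B = 29, E = 29, ES = 10, ED = 9,
                                     EY = 11, G = 29, X = 35, Q = 61),
                       admixture_alpha = 30, n_loci = 5000,
                       n_chromosomes = 12, chrom_length = 1e7,
                       missing_rate = 0.05, maf_floor = 0.05, seed = 1) {
  if (n_ancestral_pops < 1) stop("need at least one ancestral population")
  if (any(fst_per_pop <= 0) || any(fst_per_pop >= 1))
    stop("fst_per_pop must lie in (0, 1)")
  if (sum(pop_sizes) < 1) stop("pop_sizes must sum to a positive count")
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (maf_floor < 0 || maf_floor >= 0.5)
    stop("maf_floor must lie in [0, 0.5)")
  if (admixture_alpha <= 0) stop("admixture_alpha must be positive")
  if (is.null(names(pop_sizes)))
    names(pop_sizes) <- paste0("P", seq_along(pop_sizes))
  structure(list(n_ancestral_pops = as.integer(n_ancestral_pops),
                 fst_per_pop = rep_len(fst_per_pop, n_ancestral_pops),
                 pop_sizes = pop_sizes,
                 admixture_alpha = admixture_alpha,
                 n_loci = as.integer(n_loci),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 missing_rate = missing_rate, maf_floor = maf_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a structured, admixed genotype panel
#'
#' Ancestral per-cluster allele frequencies follow the Balding-Nichols
#' model: p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F) around a shared ancestral
#' frequency p drawn uniformly above `maf_floor`. Each labeled population
#' is anchored to a primary ancestral cluster (round-robin) with base
#' ancestry 0.9 on that cluster; samples draw their individual ancestry
#' from Dirichlet(alpha * base) and genotypes are Binomial(2, q) at each
#' locus, q being the ancestry-mixed frequency. Missing calls are
#' independent Bernoulli. Monomorphic loci are retained (filtering is the
#' downstream MAF filter's job).
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`: `ancestral_freqs` K x L, `ancestry` n x K,
#'   `population_labels`, `ancestral_cluster` = per-sample argmax ancestry).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_ancestral_pops; L <- config$n_loci
  n <- sum(config$pop_sizes)
  p_anc <- stats::runif(L, config$maf_floor, 1 - config$maf_floor)
  pk <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    f <- config$fst_per_pop[k]
    if (f < 1e-9) pk[k, ] <- p_anc
    else pk[k, ] <- stats::rbeta(L, p_anc * (1 - f) / f,
                                 (1 - p_anc) * (1 - f) / f)
  }
  codes <- names(config$pop_sizes)
  pop_of <- rep(codes, config$pop_sizes)
  ids <- unlist(lapply(seq_along(codes), function(j)
    paste0(codes[j], seq_len(config$pop_sizes[j]))), use.names = FALSE)
  primary <- ((seq_along(codes) - 1L) %% K) + 1L
  theta <- vapply(seq_len(n), function(s) {
    j <- match(pop_of[s], codes)
    base <- rep((1 - 0.9) / K, K)
    base[primary[j]] <- base[primary[j]] + 0.9
    rdirichlet1(config$admixture_alpha * base)
  }, numeric(K))
  theta <- matrix(theta, nrow = K)   # K x n even when K = 1
  theta <- t(theta)
  q <- theta %*% pk
  G <- matrix(stats::rbinom(n * L, 2L, as.vector(q)), n, L)
  if (config$missing_rate > 0)
    G[stats::runif(n * L) < config$missing_rate] <- NA_integer_
  # genomic coordinates: loci spread over chromosomes, sorted positions
  chrom_id <- sort(rep_len(seq_len(config$n_chromosomes), L))
  pos <- unlist(lapply(split(seq_len(L), chrom_id), function(ix)
    sort(sample.int(config$chrom_length, length(ix)))), use.names = FALSE)
  chrom <- sprintf("Chr%02d", chrom_id)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  a1 <- (G == 2L) * 1L
  a2 <- (G >= 1L) * 1L
  gm <- genotype_matrix(a1, a2, ids, chrom, pos, ref, unname(alt))
  truth <- structure(list(ancestral_freqs = pk, ancestry = theta,
                          population_labels = stats::setNames(pop_of, ids),
                          ancestral_cluster = stats::setNames(
                            paste0("K", max.col(theta)), ids),
                          mixed_freqs = q),
                     class = "sim_truth")
  list(matrix = gm, truth = truth)
}

#' Simulate a soft-masked genome sequence
#'
#' Uniform-random A/C/G/T sequence with a target fraction of bases
#' soft-masked (lowercased) in contiguous blocks, emulating a
#' repeat-masked plant genome for digestion experiments.
#'
#' @param length sequence length in bp (>= 1).
#' @param repeat_fraction target soft-masked fraction in \[0, 1).
#' @param seed optional integer seed.
#' @param block_size mean masked-block length in bp (default 500).
#' @return a single character string; lowercase letters are masked.
#' @export
simulate_genome <- function(length, repeat_fraction = 0, seed = NULL,
                            block_size = 500) {
  if (length < 1) stop("length must be >= 1")
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    stop("repeat_fraction must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  target <- round(length * repeat_fraction)
  masked <- logical(length)
  guard <- 0L
  while (sum(masked) < target && guard < 100L * max(1, target %/% block_size)) {
    guard <- guard + 1L
    b <- min(block_size, target - sum(masked) + block_size %/% 2)
    start <- sample.int(length, 1)
    idx <- start:min(length, start + b - 1L)
    masked[idx] <- TRUE
  }
  # trim overshoot from the tail of the last block placed
  over <- sum(masked) - target
  if (over > 0) masked[which(masked)[seq_len(over)]] <- FALSE
  s[masked] <- tolower(s[masked])
  paste(s, collapse = "")
}

#' Read / write soft-masked FASTA genomes
#'
#' Thin wrappers over \pkg{seqinr} that keep case (soft-masking) intact and
#' represent the genome as a named character vector of sequences.
#'
#' @param genome named character vector of sequences.
#' @param path FASTA file path.
#' @return `write_genome_fasta()`: `path` invisibly; `read_genome_fasta()`:
#'   named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  seqinr::write.fasta(lapply(genome, seqinr::s2c), names(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, forceDNAtolower = FALSE, as.string = TRUE)
  stats::setNames(vapply(fa, function(s) as.character(s)[1], character(1)),
                  names(fa))
}

#' Write a simulated dataset to disk
#'
#' Emits the genotype matrix as VCF 4.2, the population map as TSV, and the
#' simulation truth (per-sample ancestry proportions and per-cluster
#' ancestral allele frequencies) as TSV tables. All writers are
#' deterministic in content and ordering; the VCF round-trips through
#' [read_vcf()] losslessly at the dosage level.
#'
#' @param x a [genotype_matrix()].
#' @param truth a `sim_truth` object (or NULL to skip truth tables).
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_dataset <- function(x, truth, out_dir) {
  if (n_samples(x) < 1) stop("refusing to write a dataset with zero samples")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             popmap = file.path(out_dir, "popmap.tsv"))
  write_vcf(x, files["vcf"])
  if (!is.null(truth)) {
    pm <- data.frame(sample_id = x$sample_ids,
                     pop = unname(truth$population_labels[x$sample_ids]))
  } else {
    pm <- data.frame(sample_id = x$sample_ids, pop = "ALL")
  }
  utils::write.table(pm, files["popmap"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth)) {
    files["ancestry"] <- file.path(out_dir, "truth_ancestry.tsv")
    anc <- data.frame(sample_id = x$sample_ids,
                      cluster = unname(truth$ancestral_cluster[x$sample_ids]),
                      round(truth$ancestry, 6))
    names(anc)[-(1:2)] <- paste0("K", seq_len(ncol(truth$ancestry)))
    utils::write.table(anc, files["ancestry"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["freqs"] <- file.path(out_dir, "truth_ancestral_freqs.tsv")
    fq <- data.frame(chrom = x$chrom, pos = x$pos,
                     t(round(truth$ancestral_freqs, 6)))
    names(fq)[-(1:2)] <- paste0("K", seq_len(nrow(truth$ancestral_freqs)))
    utils::write.table(fq, files["freqs"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  files
}
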