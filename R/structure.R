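#' Pairwise p-distance between diploid samples
#'
#' For two samples at one locus the distance is half the number of allele
#' mismatches between the two unordered diploid genotypes (so `0/0` vs `1/1`
#' contributes 1, `0/0` vs `0/1` contributes 0.5). The pairwise distance is
#' the mean contribution over loci typed in both samples; loci missing in
#' either sample are excluded pairwise. Computed on the dosage view, i.e.
#' sites are treated as biallelic.
#'
#' @param x a [genotype_matrix()].
#' @return symmetric numeric matrix with zero diagonal and sample-id
#'   dimnames, entries in \[0, 1\].
#' @export
p_distance <- function(x) {
  if (n_samples(x) < 2) stop("p_distance needs at least 2 samples")
  d <- dosage(x)
  M  <- (!is.na(d)) * 1
  I0 <- (d == 0L) & !is.na(d); I1 <- (d == 1L) & !is.na(d)
  I2 <- (d == 2L) & !is.na(d)
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  shared <- tcrossprod(M)
  A1 <- I1 %*% t(I0 + I2)        # one-allele mismatches
  A2 <- I0 %*% t(I2)             # two-allele mismatches
  num <- A1 + t(A1) + 2 * (A2 + t(A2))
  zero <- which(shared == 0 & row(shared) < col(shared), arr.ind = TRUE)
  if (nrow(zero))
    stop("no shared typed loci for pair ", x$sample_ids[zero[1, 1]], " / ",
         x$sample_ids[zero[1, 2]])
  D <- num / (2 * shared)
  diag(D) <- 0
  dimnames(D) <- list(x$sample_ids, x$sample_ids)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration (via \pkg{ape}); negative branch
#' lengths arising from non-additive inputs are clamped to zero. On an
#' additive distance matrix the tree's path lengths reproduce the input
#' exactly.
#'
#' @param D symmetric distance matrix with dimnames.
#' @return an \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8,
                                              check.attributes = FALSE)))
    stop("distance matrix must be square and symmetric")
  n <- nrow(D)
  if (n < 2) stop("need at least 2 samples")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (n == 2) {
    tr <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                         edge.length = rep(D[1, 2] / 2, 2),
                         tip.label = ids, Nnode = 1L), class = "phylo")
    return(tr)
  }
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the reference NJ tree on the full matrix, then resamples loci with
#' replacement `replicates` times; the support of an internal edge is the
#' fraction of replicate trees containing the same leaf bipartition.
#'
#' @param x a [genotype_matrix()] with at least 3 samples.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed optional integer seed for reproducible resampling.
#' @return the reference `phylo` tree with `node.label` set to support
#'   fractions in \[0, 1\] (NA at the root).
#' @export
bootstrap_support <- function(x, replicates = 1000, seed = NULL) {
  if (n_samples(x) < 3) stop("bootstrap_support needs at least 3 samples")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ref <- neighbor_joining(p_distance(x))
  L <- n_sites(x)
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    trees[[r]] <- neighbor_joining(p_distance(subset_genotypes(x, sites = idx)))
  }
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  sup <- counts / replicates
  sup[1] <- NA  # root of the unrooted representation carries no bipartition
  ref$node.label <- sup
  ref
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed; each locus is centered by twice its
#' sample allele frequency and scaled by `sqrt(2p(1-p))` (monomorphic loci
#' dropped); coordinates and variance fractions come from the
#' eigendecomposition of the resulting sample covariance.
#'
#' @param x a [genotype_matrix()] with >= 2 samples and >= 1 polymorphic locus.
#' @param n_components number of components to return (default 10).
#' @return object of class `genotype_pca`: list with `coords` (samples x
#'   components), `var_frac` (non-increasing fractions summing to <= 1) and
#'   `n_loci` used.
#' @export
pca_genotypes <- function(x, n_components = 10) {
  if (n_samples(x) < 2) stop("PCA needs at least 2 samples")
  X <- standardized_dosage(x)
  k <- min(n_components, nrow(X) - 1, ncol(X))
  sv <- svd(X, nu = k, nv = 0)
  tot <- sum(sv$d^2)
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(coords) <- list(x$sample_ids, paste0("PC", seq_len(k)))
  structure(list(coords = coords, var_frac = sv$d[seq_len(k)]^2 / tot,
                 n_loci = ncol(X)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("genotype PCA:", nrow(x$coords), "samples,", x$n_loci,
      "polymorphic loci\n")
  cat("  variance fractions:",
      paste(sprintf("%.2f%%", 100 * utils::head(x$var_frac, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

# centered/scaled dosage matrix used by PCA and the GRM
standardized_dosage <- function(x) {
  d <- dosage(x)
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1 & apply(d, 2, function(v)
    length(unique(v[!is.na(v)]))) > 1
  if (!any(keep)) stop("no polymorphic loci")
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- 2 * p[j]
  sweep(sweep(d, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
}

#' Genomic relationship matrix
#'
#' VanRaden-style GRM on the same standardized dosages as
#' [pca_genotypes()]: `G = X X' / L`. Symmetric; on Hardy-Weinberg
#' simulated data the mean diagonal is about 1 and off-diagonals of
#' unrelated samples are about 0.
#'
#' @param x a [genotype_matrix()].
#' @return symmetric numeric matrix with sample-id dimnames.
#' @export
grm <- function(x) {
  X <- standardized_dosage(x)
  G <- tcrossprod(X) / ncol(X)
  dimnames(G) <- list(x$sample_ids, x$sample_ids)
  G
}

#' Cut a tree into k leaf groups
#'
#' Cuts the longest edges first (internal edges preferred over terminal
#' ones), keeping a cut only if it increases the number of leaf groups,
#' until `k` groups exist. Groups are labeled `C1..Ck` in order of first
#' appearance along the tree's tip ordering.
#'
#' @param tree a `phylo` tree.
#' @param k number of groups (1 <= k <= leaf count).
#' @return named character vector: sample -> group label (a partition).
#' @export
cut_tree <- function(tree, k) {
  ntip <- length(tree$tip.label)
  if (k < 1) stop("k must be >= 1")
  if (k > ntip) stop("k exceeds the number of leaves")
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  tips <- as.character(seq_len(ntip))
  leaf_groups <- function(gr) {
    comp <- igraph::components(gr)$membership
    length(unique(comp[tips]))
  }
  internal <- tree$edge[, 2] > ntip
  ord <- order(!internal, -tree$edge.length)  # internal first, longest first
  cur <- g
  for (e in ord) {
    if (leaf_groups(cur) >= k) break
    cand <- igraph::delete_edges(
      cur, igraph::get_edge_ids(cur, as.character(tree$edge[e, ])))
    if (leaf_groups(cand) > leaf_groups(cur)) cur <- cand
  }
  comp <- igraph::components(cur)$membership[tips]
  lab <- stats::setNames(paste0("C", seq_along(unique(comp))), unique(comp))
  stats::setNames(unname(lab[as.character(comp)]), tree$tip.label)
}

#' Concordance rate between two partitions
#'
#' Matches the labels of `p2` to those of `p1` by the maximum-agreement
#' label bijection (exact search over label injections of the smaller label
#' set into the larger) and returns the fraction of samples on which the
#' matched partitions agree. Invariant under relabeling either partition.
#'
#' @param p1,p2 named vectors (sample -> cluster label) over the same samples.
#' @return agreement rate in \[0, 1\].
#' @export
partition_concordance <- function(p1, p2) {
  if (is.null(names(p1)) || is.null(names(p2)))
    stop("partitions must be named by sample id")
  if (!setequal(names(p1), names(p2)))
    stop("partitions cover different sample sets")
  p2 <- p2[names(p1)]
  tab <- table(factor(p1), factor(p2))
  if (nrow(tab) > ncol(tab)) tab <- t(tab)
  k <- nrow(tab)
  if (k > 8) stop("exact label matching supported for up to 8 clusters")
  best <- 0
  rec <- function(row, used, acc) {
    if (row > k) { best <<- max(best, acc); return() }
    if (acc + sum(apply(tab[seq(row, k), , drop = FALSE], 1, max)) <= best)
      return()
    for (col in seq_len(ncol(tab))[!used]) {
      used[col] <- TRUE
      rec(row + 1, used, acc + tab[row, col])
      used[col] <- FALSE
    }
  }
  rec(1, rep(FALSE, ncol(tab)), 0)
  best / length(p1)
}

#' Cross-tabulate a partition against sample origins
#'
#' Counts samples per (cluster, origin) cell and appends an `All` totals
#' column, a totals row, and the per-cluster percentage of all samples.
#'
#' @param partition named vector sample -> cluster label.
#' @param pop_map data.frame (`sample_id`, `pop`).
#' @return data.frame: one row per cluster plus `All`; origin columns in
#'   population-map order, then `All` and `Ratio` (percent, 2 decimals).
#' @export
cross_tabulate <- function(partition, pop_map) {
  i <- match(names(partition), pop_map$sample_id)
  if (anyNA(i)) stop("samples missing from population map: ",
                     paste(utils::head(names(partition)[is.na(i)], 5),
                           collapse = ", "))
  origin <- factor(pop_map$pop[i], levels = unique(pop_map$pop))
  cl <- if (is.factor(partition)) partition else factor(partition)
  tab <- table(cl, origin)
  counts <- rbind(unclass(tab), All = colSums(tab))
  all_col <- rowSums(counts)
  out <- data.frame(cluster = rownames(counts), counts, All = all_col,
                    Ratio = round(100 * all_col / length(partition), 2),
                    row.names = NULL, check.names = FALSE)
  out$Ratio[out$cluster == "All"] <- 100
  out
}
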