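test_that("p-distance matches hand counts and pairwise deletion", {
  gm <- make_gm(rbind(c(0, 0), c(1, 0)))     # 0/0 vs 0/1, 0/0 vs 0/0
  D <- p_distance(gm)
  expect_equal(D["S1", "S2"], 0.25)
  gm2 <- make_gm(rbind(c(0, 0, 0), c(2, 2, 2)))
  expect_equal(p_distance(gm2)["S1", "S2"], 1)
  gm3 <- make_gm(rbind(c(0, 0), c(0, 0)))
  expect_equal(p_distance(gm3)["S1", "S2"], 0)
  # missing loci excluded pairwise
  gm4 <- make_gm(rbind(c(0, NA, 2), c(2, 1, NA)))
  expect_equal(p_distance(gm4)["S1", "S2"], 1)   # only locus 1 shared
  gm5 <- make_gm(rbind(c(NA, 0), c(2, NA)))
  expect_error(p_distance(gm5), "shared")
})

test_that("p-distance is a symmetric metric on complete data", {
  set.seed(6)
  gm <- make_gm(matrix(sample(0:2, 8 * 40, replace = TRUE), 8, 40))
  D <- p_distance(gm)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 8))
  expect_true(all(D >= 0 & D <= 1))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("neighbor joining recovers closed forms and additive trees", {
  # two taxa: one edge of total length d
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- neighbor_joining(D2)
  expect_equal(sum(t2$edge.length), 0.4)
  # three taxa: v_i = (d_ij + d_ik - d_jk) / 2, exact
  D3 <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- neighbor_joining(D3)
  pl <- as.matrix(ape::cophenetic.phylo(t3))[letters[1:3], letters[1:3]]
  expect_equal(pl, D3, tolerance = 1e-12)
  va <- (0.3 + 0.5 - 0.6) / 2
  expect_equal(t3$edge.length[t3$edge[, 2] == which(t3$tip.label == "a")], va)
  # additive matrices from random trees: topology and lengths recovered
  set.seed(17)
  for (k in 4:8) {
    tr <- ape::rtree(k, br = function(n) runif(n, 0.1, 1))
    tr <- ape::unroot(tr)
    D <- as.matrix(ape::cophenetic.phylo(tr))
    rec <- neighbor_joining(D)
    expect_equal(ape::dist.topo(rec, tr), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_equal(as.matrix(ape::cophenetic.phylo(rec))[rownames(D), rownames(D)],
                 D, tolerance = 1e-8)
  }
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("bootstrap supports are deterministic and saturate on clean splits", {
  # two clades with many fixed differences
  dos <- rbind(matrix(0L, 5, 60), matrix(2L, 5, 60))
  gm <- make_gm(dos, sample_ids = paste0("t", 1:10))
  # perturb within-clade so distances are not all ties
  gm$a2[1, 1:6] <- 1L; gm$a1[6, 7:12] <- 0L
  tr1 <- bootstrap_support(gm, replicates = 50, seed = 101)
  tr2 <- bootstrap_support(gm, replicates = 50, seed = 101)
  expect_identical(tr1$node.label, tr2$node.label)
  sup <- tr1$node.label[-1]
  expect_true(all(sup >= 0 & sup <= 1))
  # the clade split {t1..t5} vs {t6..t10} is supported in every replicate
  part <- cut_tree(tr1, 2)
  expect_equal(unname(part[paste0("t", 1:5)]), rep(part[["t1"]], 5))
  bp <- ape::prop.part(tr1)
  expect_error(bootstrap_support(gm, replicates = 0), "replicates")
})

test_that("bootstrap support of the true split rises with divergence", {
  support_of_split <- function(delta, seed) {
    set.seed(seed)
    n <- 6; L <- 80
    base <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
    shift <- matrix(rbinom(n / 2 * L, 2, delta), n / 2, L)
    base[(n / 2 + 1):n, ] <- pmin(2, base[(n / 2 + 1):n, ] + shift)
    gm <- make_gm(base, sample_ids = paste0("t", 1:n))
    tr <- bootstrap_support(gm, replicates = 80, seed = seed)
    # support of the bipartition separating t1..t3 from t4..t6, if present
    parts <- ape::prop.part(tr)
    labs <- tr$node.label
    target <- sort(match(paste0("t", 4:6), tr$tip.label))
    hit <- which(vapply(parts, function(p) setequal(p, target) ||
                          setequal(p, setdiff(1:n, target)), logical(1)))
    if (!length(hit)) return(0)
    labs[hit[1]]
  }
  s <- vapply(c(0.05, 0.25, 0.6), support_of_split, numeric(1), seed = 55)
  expect_true(all(diff(s) >= 0))
  expect_gt(s[3], s[1])
})

test_that("PCA orders components, bounds fractions, and separates groups", {
  dos <- rbind(matrix(0L, 6, 30), matrix(2L, 6, 30))
  set.seed(9)
  noise <- matrix(sample(0:2, 12 * 30, replace = TRUE), 12, 30)
  dos <- cbind(dos, noise)
  gm <- make_gm(dos, sample_ids = paste0("s", 1:12))
  pc <- pca_genotypes(gm, 5)
  expect_true(all(diff(pc$var_frac) <= 1e-12))
  expect_lte(sum(pc$var_frac), 1 + 1e-12)
  expect_gt(pc$var_frac[1], pc$var_frac[2])
  # PC1 separates the two duplicated groups
  g1 <- pc$coords[1:6, 1]; g2 <- pc$coords[7:12, 1]
  expect_true(max(g1) < min(g2) || min(g1) > max(g2))
  # all-identical samples: no polymorphic loci
  gm_flat <- make_gm(matrix(1L, 4, 10))
  expect_error(pca_genotypes(gm_flat), "polymorphic")
})

test_that("GRM is symmetric PSD with duplicate and unrelated structure", {
  set.seed(23)
  sim <- simulate_population(sim_config(n_ancestral_pops = 1,
                                        fst_per_pop = 0.2, n_loci = 2000,
                                        pop_sizes = c(A = 40),
                                        missing_rate = 0, seed = 23))
  G <- grm(sim$matrix)
  expect_equal(G, t(G))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(mean(diag(G)), 1, tolerance = 0.1)
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.05)
  # duplicated sample: off-diagonal equals the diagonal entries
  gm <- sim$matrix
  rows <- c(1, 1, 2:10)
  dup <- genotype_matrix(gm$a1[rows, ], gm$a2[rows, ],
                         c("dupA", "dupB", gm$sample_ids[2:10]),
                         gm$chrom, gm$pos, gm$ref, gm$alt)
  G2 <- grm(dup)
  expect_equal(G2["dupA", "dupB"], G2["dupA", "dupA"])
})

test_that("cut_tree yields the requested number of leaf groups", {
  set.seed(3)
  tr <- ape::rtree(8)
  expect_equal(length(unique(cut_tree(tr, 1))), 1)
  expect_equal(length(unique(cut_tree(tr, 8))), 8)
  expect_error(cut_tree(tr, 0), "k")
  expect_error(cut_tree(tr, 9), "leaves")
  # three well-separated simulated clades are recovered
  dos <- rbind(matrix(0L, 4, 60),
               matrix(2L, 4, 60),
               cbind(matrix(0L, 4, 30), matrix(2L, 4, 30)))
  set.seed(14)
  dos <- cbind(dos, matrix(sample(0:2, 12 * 20, replace = TRUE), 12, 20))
  gm <- make_gm(dos, sample_ids = paste0("x", 1:12))
  part <- cut_tree(neighbor_joining(p_distance(gm)), 3)
  truth <- setNames(rep(c("a", "b", "c"), each = 4), paste0("x", 1:12))
  expect_equal(partition_concordance(part, truth), 1)
})

test_that("partition concordance uses optimal label matching", {
  p1 <- setNames(c("A", "A", "A", "B", "B", "B"), paste0("s", 1:6))
  expect_equal(partition_concordance(p1, p1), 1)
  # one sample swapped between two 3-clusters, arbitrary labels
  p2 <- setNames(c("x", "x", "y", "y", "y", "x"), paste0("s", 1:6))
  expect_equal(partition_concordance(p1, p2), 4 / 6)
  # relabeling invariance
  relab <- setNames(c(A = "G7", B = "G2")[p1], names(p1))
  expect_equal(partition_concordance(relab, p2), 4 / 6)
  expect_equal(partition_concordance(p2, p1), 4 / 6)
  # mismatched sample sets rejected
  expect_error(partition_concordance(p1, p2[-1]), "sample")
  # unequal cluster counts allowed (A->u matches 3, B->v or w matches 1)
  p3 <- setNames(c("u", "u", "u", "u", "v", "w"), paste0("s", 1:6))
  expect_equal(partition_concordance(p1, p3), 4 / 6)
})

test_that("cross_tabulate reproduces printed-style contingency rows", {
  # a cluster of 39 samples drawn 14/2/23 from three origins of 213 total
  origins <- c(rep("B", 29), rep("E", 31), rep("Q", 61), rep("X", 92))
  ids <- paste0("a", seq_along(origins))
  pm <- data.frame(sample_id = ids, pop = origins)
  part <- setNames(rep("G3", length(ids)), ids)
  part[c(1:14, 30:31, 61:83)] <- "G1"          # 14 B + 2 E + 23 Q
  tab <- cross_tabulate(part, pm)
  g1 <- tab[tab$cluster == "G1", ]
  expect_equal(g1$All, 39)
  expect_equal(g1$Ratio, 18.31)
  expect_equal(g1$B, 14); expect_equal(g1$E, 2); expect_equal(g1$Q, 23)
  # totals row equals column sums; empty clusters give zero rows
  all_row <- tab[tab$cluster == "All", ]
  expect_equal(unlist(all_row[c("B", "E", "Q", "X")]),
               c(B = 29, E = 31, Q = 61, X = 92))
  part2 <- factor(part, levels = c("G1", "G2", "G3"))
  tab2 <- cross_tabulate(setNames(part2, ids), pm)
  expect_equal(tab2[tab2$cluster == "G2", "All"], 0)
})
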