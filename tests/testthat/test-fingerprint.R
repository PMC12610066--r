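# builds a 20-site candidate panel where exactly 2 sites satisfy every
# core-marker criterion and each other site violates a known one
make_core_fixture <- function() {
  n <- 40
  hw <- function(p) {                     # HWE-proportioned dosages
    nAA <- round(n * (1 - p)^2); naa <- round(n * p^2)
    c(rep(0L, nAA), rep(1L, n - nAA - naa), rep(2L, naa))
  }
  good <- hw(0.5)
  dos <- matrix(rep(good, 20), n, 20)
  reasons <- rep("ok", 20)
  dos[1, 2] <- NA; reasons[2] <- "integrity"
  dos[, 3] <- hw(0.15); reasons[3] <- "maf"       # MAF .15 < .20
  dos[, 4] <- hw(0.25); reasons[4] <- "pic"       # MAF .25 -> PIC .305 < .35
  dos[, 5] <- c(rep(0L, 20), rep(2L, 20)); reasons[5] <- "hwe"
  reasons[6:7] <- "adjacent"                       # placed 60 bp apart below
  reasons[8:19] <- "window_quota"                  # same 1 Mb window as site 1
  pos <- c(100, 5000, 10000, 15000, 20000,         # sites 1-5
           30000, 30060,                           # adjacent pair
           seq(40000, by = 2000, length.out = 12), # same window as site 1
           2e6 + 500)                              # site 20: its own window
  reasons[20] <- "ok"
  ref <- rep("C", 20); alt <- rep("G", 20)
  gm <- make_gm(dos, sample_ids = sprintf("q%02d", 1:n),
                chrom = rep("Chr01", 20), pos = pos, ref = ref, alt = alt)
  list(gm = gm, reasons = reasons)
}

test_that("core-marker selection applies the filter chain with audit trail", {
  fx <- make_core_fixture()
  cms <- select_core_markers(fx$gm)
  expect_equal(nrow(cms$markers), 2)
  expect_equal(sort(cms$markers$pos), c(100, 2000500))
  audit <- fx$reasons[fx$reasons != "ok"]
  got <- cms$audit$reason[order(cms$audit$site)]
  expect_equal(got, audit[order(which(fx$reasons != "ok"))])
  # every selected marker individually satisfies the scalar criteria
  for (r in seq_len(nrow(cms$markers))) {
    j <- cms$markers$site[r]
    expect_equal(site_integrity(fx$gm)[j], 1)
    expect_gte(cms$markers$maf[r], 0.20)
    expect_gte(cms$markers$pic[r], 0.35)
    expect_gt(cms$markers$hwe_p[r], 0.01)
  }
  # selected markers are isolated and sorted
  expect_true(all(diff(cms$markers$pos) > 100))
  expect_identical(cms$markers$pos, sort(cms$markers$pos))
})

test_that("MAF boundary is inclusive at 0.20 and PIC at 0.35", {
  n <- 40
  hw <- function(p) {
    nAA <- round(n * (1 - p)^2); naa <- round(n * p^2)
    c(rep(0L, nAA), rep(1L, n - nAA - naa), rep(2L, naa))
  }
  # dosages with exactly 16/80 = 0.20 minor copies, HWE-balanced enough
  dos <- cbind(hw(0.2), hw(0.19))
  gm <- make_gm(dos, chrom = c("Chr01", "Chr02"), pos = c(1e6, 1e6),
                ref = c("C", "C"), alt = c("G", "G"))
  crit <- core_marker_criteria(pic_min = 0, maf_min = 0.20)
  cms <- select_core_markers(gm, crit)
  expect_true(1 %in% cms$markers$site)
  expect_equal(cms$audit$reason[cms$audit$site == 2], "maf")
})

test_that("relaxing thresholds never shrinks the selected set", {
  fx <- make_core_fixture()
  strict <- select_core_markers(fx$gm)
  relaxed <- select_core_markers(fx$gm, core_marker_criteria(
    maf_min = 0.1, pic_min = 0.1, hwe_p_min = 0.001, exclusion_radius = 10,
    per_window_quota = 50))
  strict_keys <- paste(strict$markers$chrom, strict$markers$pos)
  relaxed_keys <- paste(relaxed$markers$chrom, relaxed$markers$pos)
  expect_true(all(strict_keys %in% relaxed_keys))
  expect_gt(nrow(relaxed$markers), nrow(strict$markers))
})

test_that("fingerprints encode the documented color scheme", {
  dos <- rbind(c(0L, 1L, 2L, NA), c(0L, 0L, 0L, 0L))
  gm <- make_gm(dos, sample_ids = c("acc1", "acc2"),
                chrom = rep("Chr01", 4), pos = c(1e5, 2e6, 4e6, 6e6),
                ref = c("C", "A", "T", "G"), alt = c("G", "T", "G", "A"))
  cms <- list(markers = data.frame(site = 1:4, chrom = gm$chrom, pos = gm$pos,
                                   ref = gm$ref, alt = gm$alt))
  card <- encode_fingerprint("acc1", cms, gm)
  expect_equal(card$states, c("C", "H", "G", "N"))
  expect_equal(card$colors, c("yellow", "white", "purple", "gray"))
  expect_equal(card$payload, "acc1|CHGN")
  card2 <- encode_fingerprint("acc2", cms, gm)
  expect_equal(card2$colors, c("yellow", "green", "blue", "purple"))
  expect_false(card$payload == card2$payload)
  expect_error(encode_fingerprint("ghost", cms, gm), "sample")
})

test_that("decode inverts encode up to the lossy heterozygous state", {
  sim <- simulate_population(sim_config(n_loci = 600,
                                        pop_sizes = c(A = 30, B = 30),
                                        missing_rate = 0.01, seed = 77))
  gm <- sim$matrix
  cms <- select_core_markers(gm, core_marker_criteria(
    integrity_min = 0.9, maf_min = 0.3, pic_min = 0.3,
    window_size = 1e5, per_window_quota = 3))
  expect_gt(nrow(cms$markers), 5)
  card <- encode_fingerprint(gm$sample_ids[1], cms, gm)
  dec <- decode_fingerprint(card, cms)
  expect_equal(dec$sample_id, gm$sample_ids[1])
  expect_equal(length(dec$states), nrow(cms$markers))
  hom <- card$states %in% c("A", "C", "G", "T")
  expect_equal(dec$states[hom], paste0(card$states[hom], "/",
                                       card$states[hom]))
  expect_equal(dec$states[card$states == "H"],
               rep("het", sum(card$states == "H")))
  expect_error(decode_fingerprint(substr(card$payload, 1,
                                         nchar(card$payload) - 2), cms),
               "length")
  expect_error(decode_fingerprint("nosep", cms), "payload")
})

test_that("duplicated samples share payloads; distinct panels are unique", {
  sim <- simulate_population(sim_config(n_loci = 2000,
                                        pop_sizes = c(A = 50, B = 50),
                                        missing_rate = 0, seed = 91))
  gm <- sim$matrix
  cms <- select_core_markers(gm, core_marker_criteria(
    maf_min = 0.25, pic_min = 0.3, window_size = 2e5, per_window_quota = 2))
  expect_gte(nrow(cms$markers), 50)
  ft <- fingerprint_table(gm, cms)
  expect_false(any(ft$duplicated))
  # clone the first accession under a new id
  rows <- c(1, seq_len(n_samples(gm)))
  dup <- genotype_matrix(gm$a1[rows, ], gm$a2[rows, ],
                         c("clone", gm$sample_ids),
                         gm$chrom, gm$pos, gm$ref, gm$alt)
  ft2 <- fingerprint_table(dup, cms)
  expect_true(all(ft2$duplicated[ft2$sample_id %in% c("clone",
                                                      gm$sample_ids[1])]))
})
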