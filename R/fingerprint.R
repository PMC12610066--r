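#' Core-marker selection criteria
#'
#' Thresholds for the fingerprint core-marker filter chain: complete
#' genotyping (integrity 1.0), common and informative markers (MAF >= 0.20,
#' PIC >= 0.35), Hardy-Weinberg consistency (exact-test p > 0.01), no other
#' variant within `exclusion_radius` bp, and at most `per_window_quota`
#' markers (highest PIC) per `window_size`-bp genomic window.
#'
#' @param integrity_min minimum locus integrity (default 1.0 = no missing data).
#' @param maf_min minimum minor allele frequency (default 0.20).
#' @param pic_min minimum PIC (default 0.35).
#' @param hwe_p_min markers retained when HWE p-value exceeds this (default 0.01).
#' @param exclusion_radius flanking exclusion distance in bp (default 100).
#' @param window_size uniformity window in bp (default 1e6).
#' @param per_window_quota markers kept per window (default 1).
#' @param hwe_test `"exact"` (default) or `"chisq"`.
#' @return list of class `core_marker_criteria`.
#' @export
core_marker_criteria <- function(integrity_min = 1.0, maf_min = 0.20,
                                 pic_min = 0.35, hwe_p_min = 0.01,
                                 exclusion_radius = 100, window_size = 1e6,
                                 per_window_quota = 1,
                                 hwe_test = c("exact", "chisq")) {
  stopifnot(integrity_min >= 0, integrity_min <= 1, maf_min >= 0,
            maf_min <= 0.5, pic_min >= 0, hwe_p_min >= 0, hwe_p_min <= 1,
            exclusion_radius >= 0, window_size > 0, per_window_quota >= 1)
  structure(list(integrity_min = integrity_min, maf_min = maf_min,
                 pic_min = pic_min, hwe_p_min = hwe_p_min,
                 exclusion_radius = exclusion_radius,
                 window_size = window_size,
                 per_window_quota = per_window_quota,
                 hwe_test = match.arg(hwe_test)),
            class = "core_marker_criteria")
}

#' Select core fingerprint markers
#'
#' Applies the filter chain in order: biallelic only, then integrity, MAF,
#' PIC, HWE, adjacency exclusion (any other variant of the *unfiltered*
#' input set within the exclusion radius disqualifies a candidate), and
#' finally per-window thinning keeping the highest-PIC markers. The audit
#' trail records the first failing criterion for every rejected site.
#'
#' @param x a [genotype_matrix()] with positions and alleles.
#' @param criteria a [core_marker_criteria()] object.
#' @return object of class `core_marker_set`: list with `markers` (data.frame
#'   `site, chrom, pos, ref, alt, maf, pic, hwe_p`, sorted by chrom/pos) and
#'   `audit` (data.frame `site, chrom, pos, reason`).
#' @export
select_core_markers <- function(x, criteria = core_marker_criteria()) {
  L <- n_sites(x)
  reason <- rep(NA_character_, L)
  fail <- function(cond, why) {
    hit <- cond & is.na(reason)
    reason[hit] <<- why
  }
  d <- dosage(x)
  fail(site_n_alleles(x) != 2, "multiallelic")
  fail(site_integrity(x) < criteria$integrity_min, "integrity")
  maf <- site_maf(x)
  fail(is.na(maf) | maf < criteria$maf_min, "maf")
  pic <- vapply(seq_len(L), function(j) {
    p <- mean(d[, j], na.rm = TRUE) / 2
    if (is.nan(p)) return(NA_real_)
    compute_pic(c(1 - p, p))
  }, numeric(1))
  fail(is.na(pic) | pic < criteria$pic_min, "pic")
  hwe_fun <- if (criteria$hwe_test == "exact") hwe_exact_test else hwe_chisq_test
  hwe_p <- rep(NA_real_, L)
  todo <- which(is.na(reason))
  hwe_p[todo] <- vapply(todo, function(j) {
    g <- d[, j]
    hwe_fun(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
            sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  fail(!is.na(hwe_p) & hwe_p <= criteria$hwe_p_min, "hwe")
  # adjacency against the full pre-filter variant set
  ord <- order(x$chrom, x$pos)
  crowded <- logical(L)
  pos <- x$pos[ord]; chr <- x$chrom[ord]
  if (L > 1) {
    near_prev <- c(FALSE, chr[-1] == chr[-L] & diff(pos) <= criteria$exclusion_radius)
    crowded[ord] <- near_prev | c(near_prev[-1], FALSE)
  }
  fail(crowded, "adjacent")
  # per-window uniformity thinning: keep the highest-PIC quota per window
  cand <- which(is.na(reason))
  if (length(cand)) {
    win <- paste0(x$chrom[cand], ":", x$pos[cand] %/% criteria$window_size)
    keep <- unlist(lapply(split(cand, win), function(ix) {
      ix[order(-pic[ix], x$pos[ix])][seq_len(min(criteria$per_window_quota,
                                                 length(ix)))]
    }), use.names = FALSE)
    fail(!(seq_len(L) %in% keep) & is.na(reason), "window_quota")
  }
  sel <- which(is.na(reason))
  sel <- sel[order(x$chrom[sel], x$pos[sel])]
  markers <- data.frame(site = sel, chrom = x$chrom[sel], pos = x$pos[sel],
                        ref = x$ref[sel], alt = x$alt[sel],
                        maf = maf[sel], pic = pic[sel], hwe_p = hwe_p[sel],
                        row.names = NULL)
  rej <- which(!is.na(reason))
  audit <- data.frame(site = rej, chrom = x$chrom[rej], pos = x$pos[rej],
                      reason = reason[rej], row.names = NULL)
  structure(list(markers = markers, audit = audit, criteria = criteria),
            class = "core_marker_set")
}

#' @export
print.core_marker_set <- function(x, ...) {
  cat("core_marker_set:", nrow(x$markers), "markers selected,",
      nrow(x$audit), "candidates rejected\n")
  if (nrow(x$audit))
    print(table(x$audit$reason))
  invisible(x)
}

# genotype state characters for the color barcode
fingerprint_colors <- c(C = "yellow", A = "green", T = "blue", G = "purple",
                        H = "white", N = "gray")

#' Encode a sample's DNA fingerprint card
#'
#' Maps each core marker to a one-character genotype state: the base letter
#' for a homozygous call (colored yellow C/C, green A/A, blue T/T, purple
#' G/G), `H` (white) for heterozygous, `N` (gray) for missing. The payload
#' string is `sample_id|states` and is deterministic.
#'
#' @param sample a sample id present in `x`.
#' @param markers a `core_marker_set`.
#' @param x the [genotype_matrix()] the markers were selected from.
#' @return object of class `fingerprint_card`: list with `sample_id`,
#'   `states` (character vector), `colors` and `payload`.
#' @export
encode_fingerprint <- function(sample, markers, x) {
  row <- match(sample, x$sample_ids)
  if (is.na(row)) stop("sample not in genotype matrix: ", sample)
  m <- markers$markers
  site_key <- paste0(x$chrom, ":", x$pos)
  idx <- match(paste0(m$chrom, ":", m$pos), site_key)
  if (anyNA(idx)) stop("marker absent from genotype matrix: ",
                       paste0(m$chrom, ":", m$pos)[is.na(idx)][1])
  a1 <- x$a1[row, idx]; a2 <- x$a2[row, idx]
  alleles <- function(j) c(x$ref[j], strsplit(x$alt[j], ",")[[1]])
  states <- vapply(seq_along(idx), function(k) {
    j <- idx[k]
    if (is.na(a1[k])) "N"
    else if (a1[k] != a2[k]) "H"
    else alleles(j)[a1[k] + 1L]
  }, character(1))
  if (!all(states %in% names(fingerprint_colors)))
    stop("non-SNP allele state at a core marker")
  structure(list(sample_id = sample, states = states,
                 colors = unname(fingerprint_colors[states]),
                 payload = paste0(sample, "|", paste(states, collapse = ""))),
            class = "fingerprint_card")
}

#' @export
print.fingerprint_card <- function(x, ...) {
  cat("fingerprint_card:", x$sample_id, "-", length(x$states), "markers\n")
  cat(" ", x$payload, "\n")
  invisible(x)
}

#' Decode a fingerprint payload
#'
#' Inverse of [encode_fingerprint()] up to the scheme's known loss:
#' heterozygous sites are all rendered white (`H`), so the heterozygous base
#' identities are not recoverable.
#'
#' @param card a `fingerprint_card` or a payload string.
#' @param markers the `core_marker_set` the card was encoded against.
#' @return list with `sample_id` and `states` (character vector of
#'   `X/X` homozygous states, `"het"` or `"missing"`).
#' @export
decode_fingerprint <- function(card, markers) {
  payload <- if (inherits(card, "fingerprint_card")) card$payload else card
  parts <- strsplit(payload, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed payload: expected 'sample|states'")
  states <- strsplit(parts[2], "")[[1]]
  if (length(states) != nrow(markers$markers))
    stop("payload length ", length(states), " does not match marker count ",
         nrow(markers$markers))
  if (!all(states %in% names(fingerprint_colors)))
    stop("invalid state character in payload")
  list(sample_id = parts[1],
       states = ifelse(states == "H", "het",
                       ifelse(states == "N", "missing",
                              paste0(states, "/", states))))
}

#' Fingerprint all samples
#'
#' @param x a [genotype_matrix()].
#' @param markers a `core_marker_set`.
#' @return data.frame (`sample_id`, `payload`), one row per sample, with a
#'   `duplicated` flag for payloads shared by more than one sample.
#' @export
fingerprint_table <- function(x, markers) {
  payloads <- vapply(x$sample_ids, function(s)
    encode_fingerprint(s, markers, x)$payload, character(1))
  states <- sub("^[^|]*\\|", "", payloads)
  data.frame(sample_id = x$sample_ids, payload = unname(payloads),
             duplicated = duplicated(states) | duplicated(states, fromLast = TRUE),
             row.names = NULL)
}
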