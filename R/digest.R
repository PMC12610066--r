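#' Restriction enzyme definition
#'
#' An enzyme is a recognition sequence over IUPAC ambiguity codes plus the
#' cut offset in bp from the 5' end of the recognition site. The two
#' enzymes used for SLAF-style double digestion are provided as
#' `slaf_enzymes()`: HaeIII (GG^CC, blunt, offset 2) and Hpy166II
#' (GTN^NAC, blunt, offset 3).
#'
#' @param name enzyme name.
#' @param site recognition sequence (IUPAC letters).
#' @param offset cut offset, 0 <= offset <= nchar(site).
#' @return list of class `enzyme`.
#' @export
enzyme <- function(name, site, offset) {
  site <- toupper(site)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site))
    stop("recognition site contains non-IUPAC letters: ", site)
  if (offset < 0 || offset > nchar(site))
    stop("cut offset must lie within the recognition site")
  structure(list(name = name, site = site, offset = as.integer(offset)),
            class = "enzyme")
}

#' @rdname enzyme
#' @export
slaf_enzymes <- function() {
  list(enzyme("HaeIII", "GGCC", 2), enzyme("Hpy166II", "GTNNAC", 3))
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("enzyme %s: %s^%s\n", x$name,
              substr(x$site, 1, x$offset),
              substr(x$site, x$offset + 1, nchar(x$site))))
  invisible(x)
}

#' Find restriction cut sites in a sequence
#'
#' Matches the enzyme's IUPAC recognition pattern (case-insensitively,
#' overlapping matches allowed) and returns the 0-based cut coordinates
#' (match start + cut offset). Cuts falling on the sequence ends are
#' dropped, since they produce no new fragment boundary.
#'
#' @param seq a single DNA string over A/C/G/T (either case; soft-masked
#'   lowercase is allowed and ignored for matching).
#' @param enz an [enzyme()].
#' @return sorted integer vector of 0-based cut coordinates.
#' @export
find_cut_sites <- function(seq, enz) {
  if (length(seq) != 1) stop("seq must be a single string")
  if (!grepl("^[ACGTacgt]*$", seq))
    stop("sequence contains characters outside A/C/G/T")
  if (nchar(seq) < nchar(enz$site)) return(integer(0))
  hits <- Biostrings::matchPattern(enz$site,
                                   Biostrings::DNAString(toupper(seq)),
                                   fixed = FALSE)
  cuts <- Biostrings::start(hits) - 1L + enz$offset
  sort(cuts[cuts > 0L & cuts < nchar(seq)])
}

#' Double (or single) digest of a sequence
#'
#' Pools the cut sites of all enzymes and returns the fragments between
#' consecutive cuts, plus the two sequence-end fragments. Fragments tile
#' the sequence without gaps or overlap; each records the enzyme providing
#' each flank (`"end"` for sequence ends) and the fraction of soft-masked
#' (lowercase) bases it contains.
#'
#' @param seq a single DNA string (lowercase = soft-masked repeat).
#' @param enzymes list of [enzyme()] objects (>= 1).
#' @param chrom chromosome/sequence name recorded on the fragments.
#' @return data.frame with columns `chrom, start, end` (0-based half-open),
#'   `length, left_enzyme, right_enzyme, masked_fraction`.
#' @export
double_digest <- function(seq, enzymes, chrom = "seq1") {
  if (!length(enzymes)) stop("at least one enzyme required")
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  cuts <- data.frame(pos = integer(0), enz = character(0))
  for (e in enzymes) {
    p <- find_cut_sites(seq, e)
    if (length(p)) cuts <- rbind(cuts, data.frame(pos = p, enz = e$name))
  }
  cuts <- cuts[order(cuts$pos, cuts$enz), , drop = FALSE]
  cuts <- cuts[!duplicated(cuts$pos), , drop = FALSE]   # co-cutting: first name
  L <- nchar(seq)
  bounds <- c(0L, cuts$pos, L)
  prov <- c("end", cuts$enz, "end")
  start <- bounds[-length(bounds)]; end <- bounds[-1]
  is_mask <- charToRaw(seq) %in% charToRaw("acgt")
  cum <- c(0, cumsum(is_mask))
  data.frame(chrom = chrom, start = start, end = end, length = end - start,
             left_enzyme = prov[-length(prov)], right_enzyme = prov[-1],
             masked_fraction = (cum[end + 1] - cum[start + 1]) / (end - start),
             row.names = NULL)
}

#' Size-select double-flanked tags
#'
#' Keeps fragments whose both flanks are enzymatic (not sequence ends) and
#' whose length lies in `[window_min, window_max]`, inclusive — the
#' candidate sequencing tags of a reduced-representation library.
#'
#' @param fragments data.frame from [double_digest()].
#' @param window_min,window_max tag length window in bp (defaults 364, 394).
#' @return the selected subset of `fragments`.
#' @export
select_tags <- function(fragments, window_min = 364, window_max = 394) {
  if (window_min > window_max) stop("window_min must be <= window_max")
  fragments[fragments$left_enzyme != "end" & fragments$right_enzyme != "end" &
              fragments$length >= window_min & fragments$length <= window_max,
            , drop = FALSE]
}

#' Score a digestion scheme on a genome
#'
#' Digests every sequence of the genome with the enzyme set, size-selects
#' tags, and summarizes the scheme by tag yield, duplication rate (tags
#' whose uppercase sequence occurs more than once among the tags, or whose
#' soft-masked fraction exceeds `mask_cutoff`) and genomic uniformity (the
#' coefficient of variation of tag counts across fixed-size bins).
#' Good schemes have low duplication, low CV and a yield near the design
#' target.
#'
#' @param genome named character vector of sequences (lowercase =
#'   soft-masked), e.g. from [read_genome_fasta()].
#' @param enzymes list of [enzyme()] objects.
#' @param window_min,window_max tag length window (defaults 364, 394).
#' @param bin_size uniformity bin width in bp (default 1e6).
#' @param mask_cutoff masked-fraction above which a tag counts as repeat-
#'   derived (default 0.5).
#' @return object of class `digest_scheme`: list with `enzymes`, `window`,
#'   `n_fragments`, `n_tags`, `duplication_rate`, `uniformity_cv` and the
#'   tag data.frame.
#' @export
score_scheme <- function(genome, enzymes, window_min = 364, window_max = 394,
                         bin_size = 1e6, mask_cutoff = 0.5) {
  if (!length(genome) || all(!nchar(genome))) stop("empty genome")
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  frags <- do.call(rbind, lapply(names(genome), function(ch)
    double_digest(genome[[ch]], enzymes, chrom = ch)))
  tags <- select_tags(frags, window_min, window_max)
  dup_rate <- NA_real_
  if (nrow(tags)) {
    tag_seq <- toupper(substring(genome[tags$chrom], tags$start + 1, tags$end))
    multi <- duplicated(tag_seq) | duplicated(tag_seq, fromLast = TRUE)
    dup_rate <- mean(multi | tags$masked_fraction > mask_cutoff)
  }
  counts <- unlist(lapply(names(genome), function(ch) {
    nb <- max(1L, ceiling(nchar(genome[[ch]]) / bin_size))
    tabulate(tags$start[tags$chrom == ch] %/% bin_size + 1L, nbins = nb)
  }), use.names = FALSE)
  cv <- if (mean(counts) > 0) stats::sd(counts) / mean(counts) else NA_real_
  structure(list(enzymes = vapply(enzymes, `[[`, character(1), "name"),
                 window = c(window_min, window_max),
                 n_fragments = nrow(frags), n_tags = nrow(tags),
                 duplication_rate = dup_rate, uniformity_cv = cv,
                 tags = tags),
            class = "digest_scheme")
}

#' @export
print.digest_scheme <- function(x, ...) {
  cat("digest_scheme:", paste(x$enzymes, collapse = " + "), "\n")
  cat(sprintf("  tags %d-%d bp: %d (of %d fragments)\n", x$window[1],
              x$window[2], x$n_tags, x$n_fragments))
  cat(sprintf("  duplication rate: %.3f; uniformity CV: %.3f\n",
              x$duplication_rate, x$uniformity_cv))
  invisible(x)
}
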