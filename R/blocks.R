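# Haplotype-block detection via the Gabriel D'-confidence-interval
# criteria, and proxy-SNP assignment of prioritized loci.

classify_pair <- function(ci, strong_low, strong_high, recomb_high) {
  if (!ci$informative || is.na(ci$ci_low)) return("uninformative")
  if (ci$ci_low >= strong_low && ci$ci_high >= strong_high) return("strong")
  if (ci$ci_high < recomb_high) return("recomb")
  "other"
}

#' Detect haplotype blocks from unphased genotypes
#'
#' Pairwise |D'| confidence intervals are computed for all marker pairs
#' within `max_span_kb`; a pair is in "strong LD" when `ci_low >=
#' strong_low` and `ci_high >= strong_high`, and shows "strong
#' recombination" when `ci_high < recomb_high`.  A candidate block is a
#' marker run whose outermost pair is in strong LD and in which at least
#' `informative_fraction` of informative pairs (strong LD or strong
#' recombination) are in strong LD.  Candidates are ranked by bp span and
#' accepted greedily, longest first, without overlap.
#'
#' @param genotypes Subjects x markers matrix of 0/1/2 (NA allowed),
#'   columns ordered as in `map`.
#' @param map Tibble with `chrom`, `rsid`, `pos` (1-based), one row per
#'   marker, sorted by position within chromosome.
#' @param strong_low,strong_high,recomb_high,informative_fraction,
#'   max_span_kb Gabriel parameters (defaults 0.70, 0.98, 0.90, 0.95,
#'   200).
#' @return Tibble of blocks: `chrom`, `first_idx`, `last_idx` (column
#'   indices into `genotypes`), `start`, `end` (marker positions),
#'   `span_bp`, `n_snps`.
#' @export
find_blocks <- function(genotypes, map, strong_low = 0.70,
                        strong_high = 0.98, recomb_high = 0.90,
                        informative_fraction = 0.95, max_span_kb = 200) {
  stopifnot(ncol(genotypes) == nrow(map))
  blocks <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    pos <- map$pos[idx]
    if (is.unsorted(pos, strictly = FALSE)) {
      abort(paste0("markers on ", chr, " are not position-sorted"))
    }
    m <- length(idx)
    if (m < 2L) next
    status <- matrix(NA_character_, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (pos[j] - pos[i] > max_span_kb * 1000) {
          status[i, j] <- "far"
          next
        }
        tab <- tryCatch(
          em_haplotypes(genotypes[, idx[i]], genotypes[, idx[j]]),
          error = function(e) NULL
        )
        status[i, j] <- if (is.null(tab)) "uninformative" else {
          classify_pair(dprime_ci(tab), strong_low, strong_high,
                        recomb_high)
        }
      }
    }
    # candidate blocks: outermost pair strong, informative fraction strong
    cand <- list()
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (!identical(status[i, j], "strong")) next
        sub <- status[i:j, i:j]
        s <- sum(sub == "strong", na.rm = TRUE)
        r <- sum(sub == "recomb", na.rm = TRUE)
        if (s + r == 0L) next
        if (s / (s + r) < informative_fraction) next
        cand[[length(cand) + 1L]] <- tibble(
          chrom = chr, first_idx = idx[i], last_idx = idx[j],
          start = pos[i], end = pos[j],
          span_bp = pos[j] - pos[i], n_snps = j - i + 1L
        )
      }
    }
    if (length(cand) == 0L) next
    cand <- arrange(list_rbind(cand), desc(.data$span_bp), .data$start)
    taken <- rep(FALSE, m)
    for (k in seq_len(nrow(cand))) {
      i <- match(cand$first_idx[k], idx)
      j <- match(cand$last_idx[k], idx)
      if (any(taken[i:j])) next
      taken[i:j] <- TRUE
      blocks[[length(blocks) + 1L]] <- cand[k, ]
    }
  }
  if (length(blocks) == 0L) {
    return(tibble(chrom = character(), first_idx = integer(),
                  last_idx = integer(), start = integer(), end = integer(),
                  span_bp = integer(), n_snps = integer()))
  }
  arrange(list_rbind(blocks), .data$chrom, .data$start)
}

#' Median haplotype-block span
#'
#' @param blocks Block tibble from [find_blocks()].
#' @return Median `span_bp` over all detected blocks (NA if none).
#' @export
median_block_span <- function(blocks) {
  if (nrow(blocks) == 0) return(NA_real_)
  median(blocks$span_bp)
}

#' Assign each prioritized locus a proxy SNP
#'
#' The proxy is the nearest known SNP by absolute distance (distance 0
#' when the SNP lies inside the locus; ties broken by lower coordinate).
#' Loci sharing a proxy are merged, so each proxy SNP appears once with
#' all represented loci listed.  `within_median_block` flags distances
#' strictly smaller than the median detected block span.
#'
#' @param loci Tibble with `locus_id`, `chrom`, `start`, `end`.
#' @param snp_map Tibble of known SNPs: `rsid`, `chrom`, `pos`.
#' @param blocks Block tibble from [find_blocks()] (used for the median
#'   span), or a single numeric median span.
#' @return Tibble with one row per unique proxy SNP: `rsid`, `chrom`,
#'   `pos`, `represented_loci` (comma-joined locus ids), `n_loci`,
#'   `distance_bp` (minimum over represented loci),
#'   `within_median_block`.  Loci on chromosomes without known SNPs are
#'   dropped with a warning.
#' @export
assign_proxies <- function(loci, snp_map, blocks) {
  med <- if (is.numeric(blocks)) blocks else median_block_span(blocks)
  rows <- map(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    s <- filter(snp_map, .data$chrom == l$chrom)
    if (nrow(s) == 0) {
      warn(paste0("locus ", l$locus_id, ": no known SNP on ", l$chrom,
                  "; unassigned"))
      return(NULL)
    }
    s <- mutate(s, dist = pmax(0L, pmax(l$start - .data$pos,
                                        .data$pos - l$end)))
    s <- arrange(s, .data$dist, .data$pos)
    tibble(locus_id = l$locus_id, rsid = s$rsid[1], chrom = s$chrom[1],
           pos = s$pos[1], distance_bp = s$dist[1])
  })
  rows <- list_rbind(discard(rows, is.null))
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(rsid = character(), chrom = character(), pos = integer(),
                  represented_loci = character(), n_loci = integer(),
                  distance_bp = integer(),
                  within_median_block = logical()))
  }
  rows |>
    group_by(.data$rsid, .data$chrom, .data$pos) |>
    summarise(represented_loci = paste(.data$locus_id, collapse = ","),
              n_loci = dplyr::n(),
              distance_bp = min(.data$distance_bp), .groups = "drop") |>
    mutate(within_median_block = !is.na(med) & .data$distance_bp < med) |>
    arrange(.data$chrom, .data$pos)
}
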