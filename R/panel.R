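# Panel target emission: design windows around each selected SNP and a
# machine-readable target manifest.

#' Build panel targets from proxy and literature SNPs
#'
#' One target per unique SNP (proxy set plus literature set, deduplicated
#' on position).  Each design window spans at most `window_bp` bases
#' nominally centered on the SNP, truncated at chromosome ends.  SNPs
#' falling outside the genome are emitted with status `"failed"`; an
#' optional external design-result table can mark further failures.
#'
#' @param proxies Proxy tibble from [assign_proxies()] (`rsid`, `chrom`,
#'   `pos`, optionally `represented_loci`).
#' @param literature_snps Tibble of target-species literature SNPs
#'   (`rsid`, `chrom`, `pos`), or NULL.
#' @param genome Named character vector / `DNAStringSet` of target
#'   sequences.
#' @param window_bp Maximum design-window length (default 120).
#' @param design_result Optional tibble (`rsid`, `status`) from an
#'   external primer-design tool; rows with status `"failed"` mark the
#'   matching targets failed.
#' @return List: `targets` (tibble `target_id`, `rsid`, `chrom`, `pos`,
#'   `start` (0-based), `end`, `snp_offset`, `represented_loci`,
#'   `status`) and `summary` (list: `n_targets`, `n_designed`,
#'   `n_failed`, `total_bases`, `per_chrom` tibble).
#' @export
build_panel <- function(proxies, literature_snps = NULL, genome,
                        window_bp = 120L, design_result = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  snps <- bind_rows(
    select(proxies, any_of(c("rsid", "chrom", "pos",
                             "represented_loci"))),
    if (!is.null(literature_snps)) {
      select(literature_snps, any_of(c("rsid", "chrom", "pos")))
    }
  ) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
  if (!"represented_loci" %in% names(snps)) {
    snps$represented_loci <- NA_character_
  }
  left <- window_bp %/% 2L
  right <- window_bp - left - 1L
  rows <- map(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    len <- if (s$chrom %in% names(genome)) nchar(genome[[s$chrom]]) else NA
    ok <- !is.na(len) && s$pos >= 1L && s$pos <= len
    if (!ok) {
      warn(paste0("SNP ", s$rsid, " at ", s$chrom, ":", s$pos,
                  " is off-genome; target marked failed"))
      return(tibble(rsid = s$rsid, chrom = s$chrom, pos = s$pos,
                    start = NA_integer_, end = NA_integer_,
                    snp_offset = NA_integer_,
                    represented_loci = s$represented_loci,
                    status = "failed"))
    }
    start <- max(0L, s$pos - 1L - left)
    end <- min(len, s$pos - 1L + right + 1L)
    tibble(rsid = s$rsid, chrom = s$chrom, pos = s$pos,
           start = as.integer(start), end = as.integer(end),
           snp_offset = as.integer(s$pos - 1L - start),
           represented_loci = s$represented_loci, status = "designed")
  })
  targets <- list_rbind(rows)
  targets <- mutate(targets,
                    target_id = sprintf("t%03d", seq_len(nrow(targets))),
                    .before = 1)
  if (!is.null(design_result)) {
    failed <- design_result$rsid[design_result$status == "failed"]
    targets$status[targets$rsid %in% failed] <- "failed"
  }
  designed <- filter(targets, .data$status == "designed")
  summary <- list(
    n_targets = nrow(targets),
    n_designed = nrow(designed),
    n_failed = sum(targets$status == "failed"),
    total_bases = sum(designed$end - designed$start),
    per_chrom = count(designed, .data$chrom)
  )
  list(targets = targets, summary = summary)
}

#' Write panel targets as BED
#'
#' 0-based half-open BED with the target id as name; failed targets are
#' skipped.
#'
#' @param targets Target tibble from [build_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(targets, path) {
  t <- filter(targets, .data$status == "designed")
  writeLines(paste(t$chrom, t$start, t$end, t$target_id, sep = "\t"),
             path)
  invisible(path)
}

#' Read a panel BED back into a target tibble
#'
#' @param path BED path written by [write_panel_bed()].
#' @return Tibble `chrom`, `start`, `end`, `target_id`.
#' @export
read_panel_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                      "target_id"),
                  show_col_types = FALSE, progress = FALSE)
}
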