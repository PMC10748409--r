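# Gene annotation handling: GTF import into a flat feature tibble and the
# short-feature filter applied before any overlap computation.

#' Read gene models from a GTF file
#'
#' Imports a GTF (via [rtracklayer::import()]) into a flat feature tibble,
#' the package's gene-model representation.
#'
#' @param path GTF file path.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `type`, `gene_id`, `transcript_id`, `gene_name`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(S4Vectors::mcols(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id %||% NA),
    transcript_id = as.character(md$transcript_id %||% NA),
    gene_name = as.character(md$gene_name %||% md$gene_id %||% NA)
  )
}

#' Write gene models to a GTF file
#'
#' @param features Gene-model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @param source_tag Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(features, path, source_tag = "panelsnp") {
  attrs <- paste0(
    "gene_id \"", features$gene_id, "\"; ",
    ifelse(is.na(features$transcript_id), "",
           paste0("transcript_id \"", features$transcript_id, "\"; ")),
    "gene_name \"", features$gene_name, "\";"
  )
  lines <- paste(features$chrom, source_tag, features$type,
                 features$start, features$end, ".", features$strand, ".",
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Filter annotation features by length
#'
#' Removes features of 50 bp or less (length below `min_feature_len`)
#' before overlap computation.  The direction is configurable:
#' `"drop_short"` (default) removes the short features; `"keep_short"`
#' restricts the annotation to them instead.
#'
#' @param features Gene-model tibble.
#' @param min_feature_len Minimum retained feature length in bp
#'   (default 51).
#' @param direction `"drop_short"` or `"keep_short"`.
#' @return The filtered feature tibble.
#' @export
filter_annotation <- function(features, min_feature_len = 51L,
                              direction = c("drop_short", "keep_short")) {
  direction <- match.arg(direction)
  len <- features$end - features$start + 1L
  keep <- if (direction == "drop_short") len >= min_feature_len else
    len < min_feature_len
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(paste0("filter_annotation (", direction, "): removed ", dropped,
                  " feature(s)"))
  }
  features[keep, , drop = FALSE]
}

# Transcription start sites: the 5' end of each transcript respecting
# strand.  Uses transcript rows when present, else the exon span.
gene_tss <- function(features) {
  tx <- filter(features, .data$type == "transcript")
  if (nrow(tx) == 0) {
    tx <- features |>
      filter(.data$type == "exon") |>
      group_by(.data$chrom, .data$strand, .data$gene_id,
               .data$transcript_id) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
  }
  transmute(tx,
    chrom = .data$chrom, gene_id = .data$gene_id,
    transcript_id = .data$transcript_id,
    tss = ifelse(.data$strand == "-", .data$end, .data$start))
}
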