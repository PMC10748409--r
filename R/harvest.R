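# SNP harvest: merge curated association tables into a non-redundant SNP set
# and restrict it to a reference SNP catalog.

#' Read a curated SNP association table
#'
#' Expected tab-separated columns: `rsid chrom pos ref alt source species p`.
#' `ref`, `alt` and `p` may be empty (literature entries often lack them).
#'
#' @param path Path to a TSV file.
#' @return A tibble of SNP records.
#' @export
read_snp_table <- function(path) {
  x <- read_tsv_checked(path, required = c("rsid", "chrom", "pos", "source"))
  x <- mutate(x,
    rsid = as.character(.data$rsid),
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos)
  )
  bad <- which(is.na(x$rsid) | x$rsid == "")
  if (length(bad) > 0) {
    abort(paste0("unparseable SNP table ", path, ": empty rsid at data line ",
                 bad[1]))
  }
  if (!"ref" %in% names(x)) x$ref <- NA_character_
  if (!"alt" %in% names(x)) x$alt <- NA_character_
  if (!"species" %in% names(x)) x$species <- NA_character_
  if (!"p" %in% names(x)) x$p <- NA_real_
  x$p <- as.numeric(x$p)
  x
}

canonical_rsid <- function(rsid) {
  out <- str_to_lower(trimws(rsid))
  nonrs <- !str_detect(out, "^rs[0-9]+$")
  if (any(nonrs)) {
    warn(paste0(sum(nonrs), " identifier(s) without an rs prefix passed ",
                "through unchanged (e.g. ", rsid[nonrs][1], ")"))
  }
  out
}

#' Merge SNP source tables into a non-redundant record set
#'
#' One output record per rsID (case-insensitive); the `sources` column is the
#' comma-joined union of contributing source tags.  Records that report an
#' association p-value are kept only if it is below `max_p`; records without
#' a p-value (e.g. manually curated entries) are always retained.
#'
#' @param tables A list of SNP record tibbles (see [read_snp_table()]), or a
#'   single tibble.
#' @param max_p Association p-value threshold applied to records carrying a
#'   p-value (strict `<`, default `1e-5`).
#' @return A tibble with one row per rsID, sorted by rsID, with a `sources`
#'   column holding the union of source tags.
#' @export
merge_snp_sources <- function(tables, max_p = 1e-5) {
  if (is.data.frame(tables)) tables <- list(tables)
  x <- list_rbind(map(tables, as_tibble))
  if (nrow(x) == 0) {
    return(tibble(rsid = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(),
                  sources = character(), species = character(),
                  p = numeric()))
  }
  x$rsid <- canonical_rsid(x$rsid)
  # p filter only where a p-value is reported
  x <- filter(x, is.na(.data$p) | .data$p < max_p)
  x |>
    group_by(.data$rsid) |>
    summarise(
      chrom = .data$chrom[1],
      pos = .data$pos[1],
      ref = .data$ref[!is.na(.data$ref)][1] %||% NA_character_,
      alt = .data$alt[!is.na(.data$alt)][1] %||% NA_character_,
      sources = paste(sort(unique(unlist(
        str_split(.data$source, ",")
      ))), collapse = ","),
      species = .data$species[1],
      p = suppressWarnings(min(.data$p, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    mutate(p = ifelse(is.finite(.data$p), .data$p, NA_real_)) |>
    arrange(.data$rsid)
}

#' Filter a SNP set against a reference catalog
#'
#' Drops records whose rsID is absent from the catalog, emulating the
#' exclusion of SNPs missing from a dbSNP build.
#'
#' @param snps A merged SNP tibble (see [merge_snp_sources()]).
#' @param catalog Character vector of known rsIDs, or a tibble/data.frame
#'   with an `rsid` column.
#' @return The subset of `snps` present in the catalog.
#' @export
filter_by_catalog <- function(snps, catalog) {
  if (is.data.frame(catalog)) catalog <- catalog$rsid
  catalog <- unique(str_to_lower(trimws(as.character(catalog))))
  if (length(catalog) == 0) {
    warn("empty SNP catalog: all records filtered out")
    return(snps[0, , drop = FALSE])
  }
  filter(snps, str_to_lower(.data$rsid) %in% catalog)
}
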