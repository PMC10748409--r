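# Three-caller consensus genotyping: per-sample intersection of
# quality-filtered, normalized calls; pooling across samples; cohort
# polymorphism and duplicate-pattern filters.

#' Read per-sample, per-caller VCFs into a call table
#'
#' Expects one VCF per sample and caller named `{sample}.{caller}.vcf`.
#'
#' @param dir Directory holding the VCFs.
#' @param samples Character vector of sample ids.
#' @param callers Character vector of caller ids (default
#'   `caller1..caller3`).
#' @return Tibble: `sample`, `caller`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `gt` (0/1/2).
#' @export
read_caller_calls <- function(dir, samples,
                              callers = paste0("caller", 1:3)) {
  combos <- tidyr::expand_grid(sample = samples, caller = callers)
  missing <- combos |>
    mutate(path = file.path(dir, paste0(.data$sample, ".", .data$caller,
                                        ".vcf"))) |>
    filter(!file.exists(.data$path))
  if (nrow(missing) > 0) {
    abort(paste0("missing caller VCF(s): ",
                 paste(paste0(missing$sample, ".", missing$caller),
                       collapse = ", ")))
  }
  list_rbind(pmap(combos, function(sample, caller) {
    path <- file.path(dir, paste0(sample, ".", caller, ".vcf"))
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    if (nrow(v@fix) == 0) {
      return(tibble(sample = character(), caller = character(),
                    chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    qual = numeric(), gt = integer()))
    }
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (any(str_detect(fix$ALT, ","))) {
      abort(paste0("multiallelic records in ", path,
                   " are not supported; split them first"))
    }
    gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
    gt <- str_count_alt(gt_raw)
    tibble(sample = sample, caller = caller, chrom = fix$CHROM,
           pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
           qual = as.numeric(fix$QUAL), gt = gt)
  }))
}

str_count_alt <- function(gt_raw) {
  as.integer(stringr::str_count(gt_raw, "1"))
}

#' Per-sample three-caller consensus and pooled variant set
#'
#' Within each sample, a normalized variant (matched on
#' chrom+pos+ref+alt, SNPs and indels alike) is a consensus call iff it is
#' present with `QUAL >= min_qual` in all callers.  The pooled set
#' contains every variant that is a consensus call in at least one
#' sample.  The consensus genotype is the one all callers agree on;
#' under 2-vs-1 disagreement the majority genotype is taken, and a
#' three-way disagreement yields a heterozygous call.
#'
#' @param calls Normalized call tibble (see [read_caller_calls()] and
#'   [normalize_calls()]).
#' @param min_qual Phred quality threshold (default 20, `>=`).
#' @param callers Caller ids required for consensus (default the callers
#'   present in `calls`).
#' @return List: `consensus` (per-sample consensus calls with `gt`),
#'   `pooled` (unique pooled variants: `chrom`, `pos`, `ref`, `alt`),
#'   `filtered` (the quality-filtered call table).
#' @export
consensus_calls <- function(calls, min_qual = 20, callers = NULL) {
  callers <- callers %||% sort(unique(calls$caller))
  k <- length(callers)
  filtered <- filter(calls, .data$qual >= min_qual,
                     .data$caller %in% callers)
  cons <- filtered |>
    group_by(.data$sample, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(n_callers = dplyr::n_distinct(.data$caller),
              gt = majority_gt(.data$gt), .groups = "drop") |>
    filter(.data$n_callers == k) |>
    select(-"n_callers")
  pooled <- cons |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  list(consensus = cons, pooled = pooled, filtered = filtered)
}

majority_gt <- function(g) {
  tab <- sort(table(g), decreasing = TRUE)
  if (length(tab) == length(g) && length(g) > 1L) return(1L)  # no majority
  as.integer(names(tab)[1])
}

#' Build the cohort genotype matrix for pooled variants
#'
#' For each pooled variant and sample: the consensus genotype where the
#' sample has a three-caller consensus; homozygous reference (0) where no
#' caller called the variant; otherwise the carrier rule applies —
#' `"strict"` (default) marks the genotype missing, `"any"` treats a
#' site called by any caller as a carrier (majority genotype of the
#' calling callers).
#'
#' @param cons Result of [consensus_calls()].
#' @param samples Character vector of all cohort sample ids.
#' @param carrier_rule `"strict"` or `"any"`.
#' @return A wide tibble: `chrom`, `pos`, `ref`, `alt`, `variant_id`,
#'   then one integer column per sample (0/1/2, NA = missing).
#' @export
genotype_matrix <- function(cons, samples,
                            carrier_rule = c("strict", "any")) {
  carrier_rule <- match.arg(carrier_rule)
  pooled <- cons$pooled
  if (nrow(pooled) == 0) {
    return(bind_cols(
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), variant_id = character()),
      as_tibble(setNames(rep(list(integer()), length(samples)), samples))
    ))
  }
  key <- c("chrom", "pos", "ref", "alt")
  partial <- cons$filtered |>
    group_by(.data$sample, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(any_gt = majority_gt(.data$gt), .groups = "drop")
  grid <- tidyr::expand_grid(pooled, sample = samples) |>
    left_join(rename(cons$consensus, cons_gt = "gt"),
              by = c(key, "sample")) |>
    left_join(partial, by = c(key, "sample"))
  grid <- mutate(grid, gt = case_when(
    !is.na(.data$cons_gt) ~ .data$cons_gt,
    is.na(.data$any_gt) ~ 0L,
    carrier_rule == "any" ~ .data$any_gt,
    TRUE ~ NA_integer_
  ))
  grid |>
    select(all_of(key), "sample", "gt") |>
    pivot_wider(names_from = "sample", values_from = "gt") |>
    mutate(variant_id = paste0(.data$chrom, ":", .data$pos, .data$ref,
                               ">", .data$alt),
           .after = "alt") |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
}

sample_cols <- function(gm) {
  setdiff(names(gm), c("chrom", "pos", "ref", "alt", "variant_id",
                       "target_id"))
}

#' Assign pooled variants to panel targets
#'
#' @param gm Genotype matrix tibble (or any variant tibble with `chrom`,
#'   `pos`).
#' @param targets Panel target tibble with `target_id`, `chrom`, `start`
#'   (0-based), `end`.
#' @return `gm` with a `target_id` column (NA where off-target).
#' @export
assign_targets <- function(gm, targets) {
  tid <- map_chr(seq_len(nrow(gm)), function(i) {
    hit <- which(targets$chrom == gm$chrom[i] &
                   targets$start < gm$pos[i] &
                   targets$end >= gm$pos[i])
    if (length(hit) == 0) NA_character_ else targets$target_id[hit[1]]
  })
  mutate(gm, target_id = tid)
}

#' Cohort polymorphism filter
#'
#' Keeps variants carried (genotype > 0) by `min_carriers` to
#' `max_carriers` samples with every remaining sample homozygous
#' reference (no missing genotypes).
#'
#' @param gm Genotype matrix tibble.
#' @param min_carriers,max_carriers Carrier-count bounds (defaults 11
#'   and 18).
#' @return The filtered genotype matrix.
#' @export
cohort_filter <- function(gm, min_carriers = 11L, max_carriers = 18L) {
  sc <- sample_cols(gm)
  g <- as.matrix(gm[, sc])
  carriers <- rowSums(g > 0, na.rm = TRUE)
  complete <- rowSums(is.na(g)) == 0L
  gm[complete & carriers >= min_carriers & carriers <= max_carriers, ,
     drop = FALSE]
}

#' Remove duplicate genotype patterns within a target
#'
#' Among variants on the same target with identical per-sample genotype
#' vectors, only the one with the smallest coordinate is kept; the others
#' are recorded as its pattern duplicates.
#'
#' @param gm Genotype matrix tibble with a `target_id` column.
#' @return `gm` reduced to pattern-unique variants, with a
#'   `pattern_duplicates` column listing removed variant ids.
#' @export
dedup_patterns <- function(gm) {
  if (!"target_id" %in% names(gm)) {
    abort("dedup_patterns requires a target_id column (see assign_targets)")
  }
  sc <- sample_cols(gm)
  pattern <- apply(as.matrix(gm[, sc]), 1L, paste, collapse = ",")
  # an off-target variant (NA target) is never merged with another
  tgt <- ifelse(is.na(gm$target_id),
                paste0(".orphan", seq_len(nrow(gm))), gm$target_id)
  gm |>
    mutate(.pattern = pattern, .tgt = tgt) |>
    group_by(.data$.tgt, .data$.pattern) |>
    arrange(.data$chrom, .data$pos, .by_group = TRUE) |>
    mutate(.rank = dplyr::row_number(),
           pattern_duplicates = paste(.data$variant_id[-1],
                                      collapse = ",")) |>
    ungroup() |>
    filter(.data$.rank == 1L) |>
    select(-".pattern", -".tgt", -".rank") |>
    arrange(.data$chrom, .data$pos)
}
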