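# Emulation of three discordant variant callers: per-caller false-negative
# dropouts, per-caller decoy false positives, sub-threshold QUAL values,
# and right-shifted (non-parsimonious) indel representations.

#' Simulate cohort truth variants on panel targets
#'
#' Draws `n_variants` variant sites (SNVs and short indels) inside the
#' target windows, with Hardy-Weinberg genotypes at moderate allele
#' frequencies and at least one carrier per variant.  Truth
#' representations are left-aligned and parsimonious.
#'
#' @param genome Named character vector of target-genome sequences.
#' @param targets Target tibble with `target_id`, `chrom`, `start`
#'   (0-based), `end`.
#' @param config A [sim_config()] (uses `seed`).
#' @param n_samples Cohort size (default 29).
#' @param n_variants Number of truth variants (default 40).
#' @param indel_fraction Fraction of indel variants (default 0.25).
#' @return List: `variants` (tibble `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `class`, `target_id`), `gt` (samples x variants 0/1/2
#'   matrix), `sample_ids`.
#' @export
simulate_cohort_variants <- function(genome, targets, config,
                                     n_samples = 29L, n_variants = 40L,
                                     indel_fraction = 0.25) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 11L), {
    sample_ids <- sprintf("D%02d", seq_len(n_samples))
    vars <- list()
    used <- character(0)
    tries <- 0L
    while (length(vars) < n_variants && tries < n_variants * 50L) {
      tries <- tries + 1L
      t <- targets[sample.int(nrow(targets), 1L), ]
      # stay clear of window edges so indel normalization has context
      lo <- t$start + 6L
      hi <- t$end - 6L
      if (hi <= lo) next
      pos <- lo + sample.int(hi - lo, 1L)
      key <- paste0(t$chrom, ":", pos)
      if (key %in% used) next
      is_indel <- runif(1) < indel_fraction
      refbase <- genome_base(genome, t$chrom, pos)
      if (!is_indel) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), refbase), 1L)
        v <- tibble(chrom = t$chrom, pos = pos, ref = refbase, alt = alt)
      } else if (runif(1) < 0.5) {  # deletion of 1-3 bases
        k <- sample.int(3L, 1L)
        ref <- substring(genome[[t$chrom]], pos, pos + k)
        v <- normalize_variant(genome, t$chrom, pos, ref, refbase)
      } else {  # insertion of 1-3 bases
        ins <- random_dna(sample.int(3L, 1L))
        v <- normalize_variant(genome, t$chrom, pos, refbase,
                               paste0(refbase, ins))
      }
      key <- paste0(v$chrom, ":", v$pos)
      if (key %in% used) next
      used <- c(used, key)
      v$class <- if (is_indel) "indel" else "snp"
      v$target_id <- t$target_id
      vars[[length(vars) + 1L]] <- v
    }
    variants <- arrange(list_rbind(vars), .data$chrom, .data$pos)
    variants$variant_id <- paste0(variants$chrom, ":", variants$pos,
                                  variants$ref, ">", variants$alt)
    nv <- nrow(variants)
    gt <- matrix(0L, n_samples, nv,
                 dimnames = list(sample_ids, variants$variant_id))
    for (j in seq_len(nv)) {
      q <- runif(1, 0.15, 0.55)
      g <- rbinom(n_samples, 2L, q)
      if (all(g == 0L)) g[sample.int(n_samples, 1L)] <- 1L
      gt[, j] <- g
    }
    list(variants = variants, gt = gt, sample_ids = sample_ids)
  })
}

#' Emit three callers' VCFs per sample from truth genotypes
#'
#' Each caller's calls are the sample's truth carrier sites minus
#' false-negative dropouts plus decoy false positives; QUAL values are
#' drawn so that a known subset of true calls falls below 20, and a
#' fraction of indels is emitted right-shifted and non-parsimonious.
#'
#' @param truth Result of [simulate_cohort_variants()].
#' @param genome Named character vector of reference sequences.
#' @param config A [sim_config()]; uses `caller_fn_rate`,
#'   `caller_fp_rate`, `low_qual_rate`, `indel_jitter_rate`, `seed`.
#' @param dir Output directory for `{sample}.{caller}.vcf` files.
#' @param callers Caller ids (default `caller1..caller3`).
#' @return List: `calls` (emitted call tibble with `sample`, `caller`,
#'   site, `qual`, `gt`, plus truth flags `is_fp`, `low_qual`,
#'   `jittered`), `decoys` (decoy site tibble), `dir`.
#' @export
simulate_caller_vcfs <- function(truth, genome, config, dir,
                                 callers = paste0("caller", 1:3)) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  variants <- truth$variants
  with_seed(sub_seed(config$seed, 13L), {
    # decoy FP sites: SNVs at fresh positions near truth sites
    n_decoys <- max(3L, ceiling(nrow(variants) / 2))
    decoys <- list()
    used <- paste0(variants$chrom, ":", variants$pos)
    k <- 0L
    while (length(decoys) < n_decoys && k < n_decoys * 50L) {
      k <- k + 1L
      v <- variants[sample.int(nrow(variants), 1L), ]
      pos <- v$pos + sample(c(-20L:-5L, 5L:20L), 1L)
      if (pos < 2L || pos > nchar(genome[[v$chrom]]) - 2L) next
      key <- paste0(v$chrom, ":", pos)
      if (key %in% used) next
      used <- c(used, key)
      refbase <- genome_base(genome, v$chrom, pos)
      decoys[[length(decoys) + 1L]] <- tibble(
        chrom = v$chrom, pos = pos, ref = refbase,
        alt = sample(setdiff(c("A", "C", "G", "T"), refbase), 1L))
    }
    decoys <- arrange(list_rbind(decoys), .data$chrom, .data$pos)

    all_calls <- list()
    for (s in truth$sample_ids) {
      for (cl in callers) {
        carried <- which(truth$gt[s, ] > 0L)
        keep <- carried[runif(length(carried)) >= config$caller_fn_rate]
        rec <- variants[keep, , drop = FALSE]
        rec$gt <- unname(truth$gt[s, keep])
        rec$low_qual <- runif(nrow(rec)) < config$low_qual_rate
        rec$qual <- ifelse(rec$low_qual, runif(nrow(rec), 5, 19.5),
                           runif(nrow(rec), 25, 60))
        rec$is_fp <- FALSE
        rec$jittered <- rec$class == "indel" &
          runif(nrow(rec)) < config$indel_jitter_rate
        if (any(rec$jittered)) {
          for (i in which(rec$jittered)) {
            d <- denormalize_variant(genome, rec$chrom[i], rec$pos[i],
                                     rec$ref[i], rec$alt[i],
                                     steps = sample.int(2L, 1L))
            rec$pos[i] <- d$pos
            rec$ref[i] <- d$ref
            rec$alt[i] <- d$alt
          }
        }
        fp <- decoys[runif(nrow(decoys)) < config$caller_fp_rate, ,
                     drop = FALSE]
        if (nrow(fp) > 0) {
          fp$class <- "snp"
          fp$target_id <- NA_character_
          fp$variant_id <- paste0(fp$chrom, ":", fp$pos, fp$ref, ">",
                                  fp$alt)
          fp$gt <- 1L
          fp$low_qual <- FALSE
          fp$qual <- runif(nrow(fp), 25, 60)
          fp$is_fp <- TRUE
          fp$jittered <- FALSE
        }
        rec <- bind_rows(rec, fp) |> arrange(.data$chrom, .data$pos)
        rec$sample <- s
        rec$caller <- cl
        write_caller_vcf(rec, s, file.path(dir, paste0(s, ".", cl,
                                                       ".vcf")),
                         contigs = names(genome))
        all_calls[[length(all_calls) + 1L]] <- rec
      }
    }
    list(calls = list_rbind(all_calls), decoys = decoys, dir = dir)
  })
}

#' Build a cohort-polymorphism / duplicate-pattern fixture
#'
#' A genotype matrix of twelve cohort-polymorphic variants (each carried
#' by 11-18 of the samples, no missing genotypes) containing two
#' same-target pairs with identical per-sample genotype vectors — one
#' indel/SNV pair and one SNV pair — so duplicate-pattern removal
#' retains ten variants.
#'
#' @param n_samples Cohort size (default 29).
#' @param seed Seed for the genotype patterns.
#' @return A genotype-matrix tibble (as from [genotype_matrix()] plus
#'   `target_id`).
#' @export
make_cohort_pattern_fixture <- function(n_samples = 29L, seed = 1L) {
  with_seed(seed, {
    sites <- tibble(
      chrom = c("chr30", "chr30", "chr2", "chr2",
                sprintf("chr%d", c(1, 4, 7, 11, 14, 18, 22, 26))),
      pos = c(7335099L, 7335189L, 64656696L, 64656755L,
              sort(sample.int(5e7, 8))),
      ref = c("GGT", "G", "G", "G",
              sample(c("A", "C", "G", "T"), 8, replace = TRUE)),
      alt = c("TGG", "C", "A", "A", rep("X", 8)),
      target_id = c("t01", "t01", "t02", "t02",
                    sprintf("t%02d", 3:10))
    )
    sites$alt[5:12] <- map_chr(sites$ref[5:12], function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    })
    sites$variant_id <- paste0(sites$chrom, ":", sites$pos, sites$ref,
                               ">", sites$alt)
    pat <- function() {
      carriers <- sample(11:18, 1)
      g <- c(sample(1:2, carriers, replace = TRUE),
             rep(0L, n_samples - carriers))
      as.integer(sample(g))
    }
    g <- matrix(0L, nrow = 12, ncol = n_samples)
    for (i in seq_len(12)) g[i, ] <- pat()
    g[2, ] <- g[1, ]  # duplicate patterns within each shared target
    g[4, ] <- g[3, ]
    # remaining patterns must be pairwise distinct
    while (anyDuplicated(apply(g[c(1, 3, 5:12), ], 1, paste,
                               collapse = ","))) {
      g[5:12, ] <- t(vapply(1:8, function(i) pat(),
                            integer(n_samples)))
    }
    gm <- bind_cols(sites,
                    as_tibble(setNames(as.data.frame(g),
                                       sprintf("D%02d",
                                               seq_len(n_samples)))))
    gm
  })
}

write_caller_vcf <- function(rec, sample_id, path, contigs) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", contigs, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_id), collapse = "\t"))
  body <- if (nrow(rec) == 0) character(0) else {
    paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt,
          sprintf("%.2f", rec$qual), ".", ".", "GT",
          c("0/0", "0/1", "1/1")[rec$gt + 1L], sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
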