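# LD-block-structured genotype panel: within a planted block every
# haplotype is a copy of one of a small set of founder haplotypes (so
# within-block |D'| = 1 for two founders); between blocks, founder
# assignment is redrawn with the configured recombination probability
# (1 = linkage equilibrium between blocks).

#' Simulate an LD-structured genotype panel
#'
#' @param config A [sim_config()]; uses `n_subjects`, `block_spec`,
#'   `n_founders`, `block_gap_bp`, `seed`.
#' @param dir Optional output directory; writes PLINK text `panel.ped` /
#'   `panel.map`, a `panel.vcf`, and `truth.json`.
#' @return List: `genotypes` (subjects x markers matrix of 0/1/2), `map`
#'   (tibble `chrom`, `rsid`, `pos`, `ref`, `alt`), `truth_blocks`
#'   (tibble `chrom`, `first_idx`, `last_idx`, `start`, `end`, `span_bp`,
#'   `n_snps`), `haplotypes` (2n x markers 0/1 matrix), `sample_ids`, and
#'   `paths` when `dir` is given.
#' @export
simulate_genotypes_ld <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$block_spec
  if (nrow(spec) == 0) abort("block_spec must be non-empty")
  n <- config$n_subjects
  nf <- config$n_founders
  with_seed(config$seed, {
    # marker positions and founder haplotypes per block
    pos <- integer(0)
    founders <- list()
    truth <- vector("list", nrow(spec))
    cursor <- 10000L
    for (b in seq_len(nrow(spec))) {
      m <- spec$n_markers[b]
      span <- spec$span_bp[b]
      p <- cursor + as.integer(round(seq(0, span, length.out = m)))
      fh <- matrix(rbinom(nf * m, 1L, 0.5), nrow = nf)
      # every marker polymorphic across founders
      for (j in seq_len(m)) {
        if (length(unique(fh[, j])) == 1L) {
          k <- sample.int(nf, 1L)
          fh[k, j] <- 1L - fh[k, j]
        }
      }
      founders[[b]] <- fh
      truth[[b]] <- tibble(chrom = "chr1",
                           first_idx = length(pos) + 1L,
                           last_idx = length(pos) + m,
                           start = p[1], end = p[m],
                           span_bp = p[m] - p[1], n_snps = m)
      pos <- c(pos, p)
      cursor <- p[m] + config$block_gap_bp
    }
    truth <- list_rbind(truth)
    m_total <- length(pos)

    # 2n haplotypes: founder index per block with between-block redraw
    haps <- matrix(0L, nrow = 2L * n, ncol = m_total)
    for (h in seq_len(2L * n)) {
      f <- sample.int(nf, 1L)
      for (b in seq_len(nrow(spec))) {
        if (b > 1L && runif(1) < spec$recomb_rate_between[b]) {
          f <- sample.int(nf, 1L)
        }
        cols <- truth$first_idx[b]:truth$last_idx[b]
        haps[h, cols] <- founders[[b]][f, ]
      }
    }
    genotypes <- haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
      haps[seq(2, 2 * n, by = 2), , drop = FALSE]
    sample_ids <- sprintf("S%03d", seq_len(n))
    rownames(genotypes) <- sample_ids

    map <- tibble(chrom = "chr1", rsid = sprintf("snp%05d", seq_len(m_total)),
                  pos = pos, ref = "A", alt = "C")

    out <- list(genotypes = genotypes, map = map, truth_blocks = truth,
                haplotypes = haps, sample_ids = sample_ids)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(ped = file.path(dir, "panel.ped"),
                    map = file.path(dir, "panel.map"),
                    vcf = file.path(dir, "panel.vcf"),
                    truth = file.path(dir, "truth.json"))
      write_ped_map(genotypes, map, paths$ped, paths$map)
      write_genotype_vcf(genotypes, map, paths$vcf)
      jsonlite::write_json(truth, paths$truth, dataframe = "rows")
      out$paths <- paths
    }
    out
  })
}

#' Write genotypes as PLINK text PED/MAP
#'
#' Genotypes are emitted unphased; allele letters come from the map's
#' `ref`/`alt` columns.  Phenotype is written as 0 (missing).
#'
#' @param genotypes Subjects x markers 0/1/2 matrix (NA allowed).
#' @param map Marker tibble (`chrom`, `rsid`, `pos`, `ref`, `alt`).
#' @param ped_path,map_path Output paths.
#' @return `ped_path`, invisibly.
#' @export
write_ped_map <- function(genotypes, map, ped_path, map_path) {
  n <- nrow(genotypes)
  ids <- rownames(genotypes) %||% sprintf("S%03d", seq_len(n))
  allele_pairs <- function(g, ref, alt) {
    out <- character(length(g))
    out[is.na(g)] <- "0 0"
    out[!is.na(g) & g == 0L] <- paste(ref, ref)[!is.na(g) & g == 0L]
    out[!is.na(g) & g == 1L] <- paste(ref, alt)[!is.na(g) & g == 1L]
    out[!is.na(g) & g == 2L] <- paste(alt, alt)[!is.na(g) & g == 2L]
    out
  }
  lines <- map_chr(seq_len(n), function(i) {
    paste(c(ids[i], ids[i], 0, 0, 0, 0,
            allele_pairs(genotypes[i, ], map$ref, map$alt)),
          collapse = " ")
  })
  writeLines(lines, ped_path)
  chrom_num <- sub("^chr", "", map$chrom)
  writeLines(paste(chrom_num, map$rsid, 0, map$pos, sep = "\t"), map_path)
  invisible(ped_path)
}

#' Read PLINK text PED/MAP genotypes
#'
#' Genotype codes count copies of the alternate allele.  Plain PED files
#' carry no ref/alt designation, so the alternate allele is taken from
#' `alleles` when supplied and otherwise defaults to the minor
#' (less frequent) allele at each marker.
#'
#' @param ped_path,map_path PLINK text file paths.
#' @param alleles Optional tibble with `ref`, `alt` letters per marker
#'   (map order).
#' @return List: `genotypes` (0/1/2 matrix, NA for missing), `map` tibble.
#' @export
read_ped_map <- function(ped_path, map_path, alleles = NULL) {
  mp <- readr::read_tsv(map_path,
                        col_names = c("chrom", "rsid", "cm", "pos"),
                        show_col_types = FALSE, progress = FALSE)
  m <- nrow(mp)
  lines <- readLines(ped_path)
  a1 <- matrix(NA_character_, nrow = length(lines), ncol = m)
  a2 <- a1
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m) {
      abort(paste0("PED line ", i, " has ", length(f),
                   " fields; expected ", 6L + 2L * m))
    }
    ids[i] <- f[2]
    a1[i, ] <- f[seq(7L, by = 2L, length.out = m)]
    a2[i, ] <- f[seq(8L, by = 2L, length.out = m)]
  }
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  alt <- if (!is.null(alleles)) alleles$alt else {
    map_chr(seq_len(m), function(j) {
      tab <- sort(table(c(a1[, j], a2[, j])))
      if (length(tab) == 0) NA_character_ else names(tab)[1]
    })
  }
  geno <- matrix(NA_integer_, nrow = length(lines), ncol = m)
  for (j in seq_len(m)) {
    ok <- !is.na(a1[, j]) & !is.na(a2[, j])
    geno[ok, j] <- (a1[ok, j] == alt[j]) + (a2[ok, j] == alt[j])
  }
  rownames(geno) <- ids
  list(genotypes = geno,
       map = tibble(chrom = paste0("chr", mp$chrom), rsid = mp$rsid,
                    pos = mp$pos))
}

#' Write genotypes as a minimal VCF v4.2
#'
#' @param genotypes Subjects x markers 0/1/2 matrix.
#' @param map Marker tibble (`chrom`, `rsid`, `pos`, `ref`, `alt`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, map, path) {
  ids <- rownames(genotypes) %||% sprintf("S%03d", seq_len(nrow(genotypes)))
  gt_str <- function(g) {
    out <- rep("./.", length(g))
    out[!is.na(g)] <- c("0/0", "0/1", "1/1")[g[!is.na(g)] + 1L]
    out
  }
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(map$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- map_chr(seq_len(nrow(map)), function(j) {
    paste(c(map$chrom[j], map$pos[j], map$rsid[j], map$ref[j], map$alt[j],
            ".", "PASS", ".", "GT", gt_str(genotypes[, j])),
          collapse = "\t")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Build a proxy-assignment fixture
#'
#' Lays out `n_loci` prioritized loci on one chromosome, each with a known
#' SNP a short distance away, with `n_shared` adjacent locus pairs sharing
#' their nearest SNP (so the expected number of unique proxies is
#' `n_loci - n_shared`), plus a detected-block table with a realistic
#' kilobase-scale median span.
#'
#' @param n_loci Number of loci (default 101).
#' @param n_shared Number of locus pairs sharing one SNP (default 1).
#' @param seed Seed for distance jitter.
#' @return List: `loci`, `snp_map`, `blocks`, `expected_proxies`.
#' @export
make_proxy_fixture <- function(n_loci = 101L, n_shared = 1L, seed = 1L) {
  if (2L * n_shared > n_loci) abort("n_shared too large for n_loci")
  with_seed(seed, {
    base <- seq_len(n_loci) * 10000L
    loci <- tibble(locus_id = sprintf("L%04d", seq_len(n_loci)),
                   chrom = "chr1", start = base, end = base + 99L)
    # one SNP near each locus; shared pairs use the midpoint between two
    # consecutive loci... they must be adjacent, so shrink the pair gap
    snp_pos <- base + 100L + sample.int(400L, n_loci, replace = TRUE)
    rsid <- sprintf("known%04d", seq_len(n_loci))
    drop <- integer(0)
    for (s in seq_len(n_shared)) {
      i <- 2L * s - 1L
      # locus i and i+1 share SNP i: move locus i+1 next to SNP i
      loci$start[i + 1L] <- snp_pos[i] + 120L
      loci$end[i + 1L] <- snp_pos[i] + 219L
      drop <- c(drop, i + 1L)
    }
    snp_map <- tibble(rsid = rsid, chrom = "chr1", pos = snp_pos)[
      -drop, , drop = FALSE]
    blocks <- tibble(chrom = "chr1",
                     first_idx = NA_integer_, last_idx = NA_integer_,
                     start = 0L, end = 0L,
                     span_bp = as.integer(
                       round(runif(40, 2000, 10000))),
                     n_snps = NA_integer_)
    list(loci = loci, snp_map = snp_map, blocks = blocks,
         expected_proxies = n_loci - n_shared)
  })
}
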