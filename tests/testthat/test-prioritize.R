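toy_features <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 1000L, 1000L, 1000L, 1100L, 1400L),
    end = c(1699L, 1699L, 1699L, 1099L, 1399L, 1699L),
    strand = "+",
    type = c("gene", "transcript", "exon", "five_prime_utr", "CDS",
             "three_prime_utr"),
    gene_id = "G1", transcript_id = c(NA, rep("T1", 5)),
    gene_name = "G1")
}

test_that("short-feature filter is strict at 50 bp and configurable", {
  f <- tibble::tibble(chrom = "chr1", start = c(1L, 1L, 1L),
                      end = c(50L, 51L, 200L), strand = "+",
                      type = "exon", gene_id = "G", transcript_id = "T",
                      gene_name = "G")
  out <- suppressMessages(filter_annotation(f))
  expect_equal(out$end, c(51L, 200L))
  kept <- suppressMessages(filter_annotation(f, direction = "keep_short"))
  expect_equal(kept$end, 50L)
  long <- toy_features()
  expect_equal(suppressMessages(filter_annotation(long)), long)
  # brute-force length filter oracle
  for (seed in 1:20) {
    ff <- panelsnp:::with_seed(seed, {
      st <- sample(1:500, 15)
      tibble::tibble(chrom = "chr1", start = st,
                     end = st + sample(0:120, 15, replace = TRUE),
                     strand = "+", type = "exon", gene_id = "G",
                     transcript_id = "T", gene_name = "G")
    })
    out <- suppressMessages(filter_annotation(ff))
    expect_equal(out, ff[ff$end - ff$start + 1 >= 51, ])
  }
})

test_that("UTR overlap honors the strict two-thirds coding rule", {
  f <- toy_features()
  inside <- tibble::tibble(chrom = "chr1", start = 1450L, end = 1549L)
  expect_true(overlaps_utr(inside, f))
  # 99-bp locus overlapping UTR with exactly 66 bp of coding overlap
  f2 <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 1000L, 1066L), end = c(1799L, 1065L, 1799L),
    strand = "+", type = c("gene", "five_prime_utr", "CDS"),
    gene_id = "G2", transcript_id = c(NA, "T2", "T2"), gene_name = "G2")
  locus66 <- tibble::tibble(chrom = "chr1", start = 1033L, end = 1131L)
  expect_equal(locus66$end - locus66$start + 1L, 99L)
  expect_false(overlaps_utr(locus66, f2))      # overlap = 66 = 2/3 * 99
  locus65 <- tibble::tibble(chrom = "chr1", start = 1032L, end = 1130L)
  expect_true(overlaps_utr(locus65, f2))       # overlap = 65 < 2/3 * 99
  # randomized loci against the per-base oracle
  for (seed in 1:60) {
    l <- panelsnp:::with_seed(seed, {
      s <- sample(900:1800, 1)
      tibble::tibble(chrom = "chr1", start = s,
                     end = s + sample(20:150, 1))
    })
    expect_equal(overlaps_utr(l, f2), oracle_overlaps_utr(l, f2),
                 info = seed)
    expect_equal(overlaps_utr(l, f), oracle_overlaps_utr(l, f),
                 info = seed)
  }
})

test_that("nearest TSS matches the brute-force scan, with flagged gaps", {
  f <- dplyr::bind_rows(
    toy_features(),
    dplyr::mutate(toy_features(), start = start + 5000L,
                  end = end + 5000L, gene_id = "G9", gene_name = "G9",
                  transcript_id = ifelse(is.na(transcript_id), NA, "T9")))
  # locus between the two TSSs (6000 and 1000): distances 100 and 300
  l <- tibble::tibble(chrom = "chr1", start = 1100L, end = 5700L)
  nt <- nearest_tss(l, f)
  expect_equal(nt$up_gene, "G1")
  expect_equal(nt$up_dist, 100L)
  expect_equal(nt$down_gene, "G9")
  expect_equal(nt$down_dist, 300L)
  inside <- tibble::tibble(chrom = "chr1", start = 900L, end = 1200L)
  expect_equal(nearest_tss(inside, f)$nearest_dist, 0L)
  expect_warning(bad <- nearest_tss(
    tibble::tibble(chrom = "chrZ", start = 1L, end = 10L), f), "no TSS")
  expect_true(is.na(bad$nearest_gene))
  tss <- panelsnp:::gene_tss(f)
  for (seed in 1:50) {
    l <- panelsnp:::with_seed(seed, {
      s <- sample(1:8000, 1)
      tibble::tibble(chrom = "chr1", start = s, end = s + 50L)
    })
    got <- nearest_tss(l, f)
    want <- oracle_nearest_tss(l, tss)
    expect_equal(got$up_gene, want$up$gene, info = seed)
    expect_equal(got$down_gene, want$down$gene, info = seed)
    expect_equal(got$nearest_dist, want$near$dist, info = seed)
  }
})

test_that("hub detection uses strict thresholds and ignores duplicates", {
  mk <- function(n, score = 0.8) {
    tibble::tibble(gene_a = "HUB", gene_b = sprintf("P%02d", seq_len(n)),
                   dscore = score)
  }
  expect_equal(hub_genes(mk(10)), character(0))
  expect_equal(hub_genes(mk(11)), "HUB")
  expect_equal(hub_genes(mk(11, score = 0.5)), character(0))  # strict >
  dup <- dplyr::bind_rows(mk(11), mk(11),
                          tibble::tibble(gene_a = sprintf("P%02d", 1:11),
                                         gene_b = "HUB", dscore = 0.8))
  expect_equal(hub_genes(dup), "HUB")
  expect_equal(hub_genes(tibble::tibble(gene_a = "A", gene_b = "A",
                                        dscore = 0.9)), character(0))
  for (seed in 1:30) {
    e <- panelsnp:::with_seed(seed, {
      g <- sprintf("g%02d", 1:14)
      tibble::tibble(gene_a = sample(g, 120, replace = TRUE),
                     gene_b = sample(g, 120, replace = TRUE),
                     dscore = round(runif(120), 2))
    })
    expect_equal(hub_genes(e), oracle_hub_genes(e), info = seed)
  }
})

test_that("prioritization unions the four criteria with full reason tags", {
  px <- simulate_prioritization_inputs(n_utr = 6, n_tf = 7, n_keyreg = 2,
                                       n_deghub = 5,
                                       n_overlap_utr_tf = 2,
                                       n_deg_nonhub = 3,
                                       n_background = 3)
  sel <- suppressMessages(prioritize_loci(
    px$loci, filter_annotation(px$gene_models), px$tf_classes,
    px$deg_list, px$key_regulators, px$edges))
  expect_equal(nrow(sel), px$n_expected_selected)
  expect_false(any(duplicated(sel$locus_id)))
  truth <- px$loci$truth[match(sel$locus_id, px$loci$locus_id)]
  expect_setequal(sel$locus_id,
                  px$loci$locus_id[!px$loci$truth %in%
                                     c("degnonhub", "background")])
  # overlap loci carry both reasons
  both <- sel$reasons[truth == "utr_tf"]
  expect_true(all(grepl("utr", both) & grepl("tf_proximal", both)))
  expect_true(all(sel$reasons[truth == "deghub"] == "deg_hub"))
  expect_true(all(grepl("key_regulator",
                        sel$reasons[truth == "keyreg"])))
  # re-derive tags independently
  is_utr <- overlaps_utr(sel[, c("chrom", "start", "end")],
                         px$gene_models)
  expect_equal(grepl("utr", sel$reasons), is_utr)
  # no qualifying loci -> empty set
  none <- suppressWarnings(prioritize_loci(
    px$loci[px$loci$truth == "background", ], px$gene_models,
    px$tf_classes, character(0), character(0), px$edges))
  expect_equal(nrow(none), 0)
})

test_that("selection is monotone when edges are added", {
  px <- simulate_prioritization_inputs(n_utr = 3, n_tf = 3, n_keyreg = 1,
                                       n_deghub = 3,
                                       n_overlap_utr_tf = 1,
                                       n_deg_nonhub = 2,
                                       n_background = 2)
  base <- suppressMessages(prioritize_loci(
    px$loci, px$gene_models, px$tf_classes, px$deg_list,
    px$key_regulators, px$edges))
  # promote one non-hub DEG to a hub by adding edges
  nonhub <- setdiff(px$deg_list, hub_genes(px$edges))[1]
  extra <- tibble::tibble(gene_a = nonhub,
                          gene_b = sprintf("X%02d", 1:12), dscore = 0.9)
  more <- suppressMessages(prioritize_loci(
    px$loci, px$gene_models, px$tf_classes, px$deg_list,
    px$key_regulators, dplyr::bind_rows(px$edges, extra)))
  expect_true(all(base$locus_id %in% more$locus_id))
  expect_gt(nrow(more), nrow(base))
})

test_that("gene models survive a GTF round-trip", {
  px <- simulate_prioritization_inputs(n_utr = 2, n_tf = 2, n_keyreg = 1,
                                       n_deghub = 1,
                                       n_overlap_utr_tf = 1,
                                       n_deg_nonhub = 0,
                                       n_background = 0)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(px$gene_models, path)
  back <- read_gene_models(path)
  expect_equal(nrow(back), nrow(px$gene_models))
  expect_equal(back$start, px$gene_models$start)
  expect_equal(back$type, px$gene_models$type)
  expect_equal(back$gene_id, px$gene_models$gene_id)
})
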