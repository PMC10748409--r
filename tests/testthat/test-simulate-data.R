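test_that("sim_config validates probabilities, sizes and classes", {
  expect_error(sim_config(caller_fn_rate = 1.2), "probabilities")
  expect_error(sim_config(n_subjects = 1), "n_subjects")
  expect_error(sim_config(beta = c(1, Inf)), "finite")
  expect_error(sim_config(n_snps = 3, ortholog_classes = "conserved"),
               "length n_snps")
  expect_error(sim_config(n_snps = 1, ortholog_classes = "weird"),
               "unknown ortholog class")
  expect_error(sim_config(block_spec = tibble::tibble(
    n_markers = 10L, span_bp = 5L, recomb_rate_between = 1)),
    "span_bp")
})

test_that("configs round-trip through YAML", {
  cfg <- sim_config(seed = 42, beta = c(0.7, -0.7), n_snps = 33)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$seed, 42L)
  expect_equal(back$beta, c(0.7, -0.7))
  expect_equal(back$block_spec, cfg$block_spec)
})

test_that("zero-edit genome pairs give one identity chain and exact lifts", {
  sim <- simulate_genome_pair(sim_config(seed = 1, n_snps = 6,
                                         n_subs = 0))
  expect_identical(sim$source, sim$target)
  expect_equal(nrow(sim$chains), 1)
  expect_equal(nrow(sim$chains$blocks[[1]]), 1)
  cas <- run_ortholog_cascade(sim$snps, sim$source, sim$target,
                              sim$chains)
  expect_true(all(cas$status == "conserved"))
  expect_equal(cas$target_pos, cas$pos)
})

test_that("a planted insertion inflates the lifted window past 1 kb", {
  sim <- simulate_genome_pair(sim_config(
    seed = 2, n_snps = 3,
    ortholog_classes = c("conserved", "too_long", "conserved")))
  w <- window_around("chr1", sim$snps$pos[2])
  lift <- lift_interval(sim$chains, w)
  expect_equal(lift$status, "lifted")
  expect_gt(lift$end - lift$start, 1000)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 33, n_snps = 8,
                    ortholog_classes = c(rep("conserved", 5),
                                         "gap_at_snp", "no_ortholog",
                                         "unplaced"),
                    n_subjects = 20,
                    block_spec = tibble::tibble(
                      n_markers = c(4L, 4L), span_bp = c(800L, 900L),
                      recomb_rate_between = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_genome_pair(cfg, dir = d1)
  simulate_genome_pair(cfg, dir = d2)
  g1 <- simulate_genotypes_ld(cfg, dir = d1)
  g2 <- simulate_genotypes_ld(cfg, dir = d2)
  tr <- simulate_cohort_variants(
    c(chr1 = panelsnp:::with_seed(1, panelsnp:::random_dna(3000))),
    tibble::tibble(target_id = "t001", chrom = "chr1", start = 0L,
                   end = 3000L),
    cfg, n_samples = 4, n_variants = 6)
  simulate_caller_vcfs(tr, c(chr1 = panelsnp:::with_seed(
    1, panelsnp:::random_dna(3000))), cfg, file.path(d1, "vcf"))
  simulate_caller_vcfs(tr, c(chr1 = panelsnp:::with_seed(
    1, panelsnp:::random_dna(3000))), cfg, file.path(d2, "vcf"))
  files <- c("source.fa", "target.fa", "lift.chain", "snps.tsv",
             "panel.ped", "panel.map", "panel.vcf",
             file.path("vcf", "D01.caller1.vcf"),
             file.path("vcf", "D03.caller2.vcf"))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_identical(g1$genotypes, g2$genotypes)
})

test_that("emitted genotype formats conserve every genotype entry", {
  cfg <- sim_config(seed = 10, n_subjects = 15,
                    block_spec = tibble::tibble(
                      n_markers = c(5L, 3L), span_bp = c(1000L, 600L),
                      recomb_rate_between = 1))
  d <- withr::local_tempdir()
  g <- simulate_genotypes_ld(cfg, dir = d)
  expect_equal(dim(g$genotypes), c(15, 8))
  back <- read_ped_map(file.path(d, "panel.ped"),
                       file.path(d, "panel.map"),
                       alleles = g$map)
  expect_equal(unname(back$genotypes), unname(g$genotypes))
  expect_equal(back$map$pos, g$map$pos)
  v <- vcfR::read.vcfR(file.path(d, "panel.vcf"), verbose = FALSE)
  expect_equal(nrow(v@fix), 8)
  gt <- vcfR::extract.gt(v, element = "GT")
  expect_equal(sum(!is.na(gt)), 15 * 8)
})

test_that("accounting fixtures honor their composition exactly", {
  fx <- make_accounting_fixture(
    list(n_input = 10, n_no_ortholog = 2, n_gap_at_snp = 1), seed = 5)
  cas <- run_ortholog_cascade(fx$snps, fx$source, fx$target, fx$chains)
  cc <- cascade_counts(cas)
  expect_equal(cc$n[cc$status == "conserved"], 7)
  expect_equal(cc$n[cc$status == "no_ortholog"], 2)
  expect_equal(cc$n[cc$status == "gap_at_snp"], 1)
  # empty composition: empty outputs, no error
  fx0 <- make_accounting_fixture(list(n_input = 0), seed = 5)
  expect_equal(nrow(fx0$snps), 0)
  expect_equal(nrow(fx0$chains), 0)
  # contradictory composition
  expect_error(make_accounting_fixture(
    list(n_input = 3, n_no_ortholog = 4)), "exceed")
})

test_that("caller VCF union equals truth carrier sites plus planted FPs", {
  cfg <- sim_config(seed = 6, caller_fn_rate = 0.2, caller_fp_rate = 0.4,
                    low_qual_rate = 0, indel_jitter_rate = 0)
  genome <- c(chr1 = panelsnp:::with_seed(2, panelsnp:::random_dna(5000)))
  targets <- tibble::tibble(target_id = c("t001", "t002"), chrom = "chr1",
                            start = c(0L, 2500L), end = c(2400L, 5000L))
  tr <- simulate_cohort_variants(genome, targets, cfg, n_samples = 8,
                                 n_variants = 12)
  d <- withr::local_tempdir()
  sc <- simulate_caller_vcfs(tr, genome, cfg, d)
  calls <- read_caller_calls(d, tr$sample_ids)
  key <- function(x) unique(paste0(x$chrom, ":", x$pos, x$ref, ">", x$alt))
  emitted_fp_keys <- key(sc$calls[sc$calls$is_fp, ])
  truth_carried <- tr$variants$variant_id[colSums(tr$gt > 0) > 0]
  expect_setequal(key(calls),
                  union(key(sc$calls[!sc$calls$is_fp, ]),
                        emitted_fp_keys))
  # every non-FP call site normalizes back to a truth site
  norm <- normalize_calls(calls, genome)
  expect_true(all(key(norm) %in% union(tr$variants$variant_id,
                                       emitted_fp_keys)))
  expect_true(all(truth_carried %in% key(norm)))
})

test_that("a sub-threshold QUAL in one caller blocks consensus there", {
  cfg <- sim_config(seed = 14, caller_fn_rate = 0, caller_fp_rate = 0,
                    low_qual_rate = 0, indel_jitter_rate = 0)
  genome <- c(chr1 = panelsnp:::with_seed(3, panelsnp:::random_dna(2000)))
  targets <- tibble::tibble(target_id = "t001", chrom = "chr1",
                            start = 0L, end = 2000L)
  tr <- simulate_cohort_variants(genome, targets, cfg, n_samples = 4,
                                 n_variants = 5)
  d <- withr::local_tempdir()
  simulate_caller_vcfs(tr, genome, cfg, d)
  calls <- normalize_calls(read_caller_calls(d, tr$sample_ids), genome)
  # drop one caller's QUAL below 20 for one carried variant in one sample
  carrier <- which(tr$gt[, 1] > 0)[1]
  s <- tr$sample_ids[carrier]
  vid <- tr$variants$variant_id[1]
  hit <- calls$sample == s & calls$caller == "caller1" &
    paste0(calls$chrom, ":", calls$pos, calls$ref, ">", calls$alt) == vid
  expect_equal(sum(hit), 1)
  calls$qual[hit] <- 19
  cons <- consensus_calls(calls)
  in_sample <- cons$consensus[cons$consensus$sample == s, ]
  expect_false(vid %in% paste0(in_sample$chrom, ":", in_sample$pos,
                               in_sample$ref, ">", in_sample$alt))
})
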