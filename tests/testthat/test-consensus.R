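norm_genome <- function() {
  # a homopolymer-rich toy chromosome for normalization edge cases
  c(chr1 = "GATCCAAATGGCTTTTACGCATGCAAACCCGGGTTTAAACGT")
}

test_that("normalization leaves SNPs alone and is idempotent", {
  genome <- norm_genome()
  out <- normalize_variant(genome, "chr1", 2L, "A", "G")
  expect_equal(out, tibble::tibble(chrom = "chr1", pos = 2L, ref = "A",
                                   alt = "G"))
  # already-normalized deletion is a fixed point
  v <- normalize_variant(genome, "chr1", 5L, "CA", "C")
  expect_equal(normalize_variant(genome, v$chrom, v$pos, v$ref, v$alt), v)
  expect_error(normalize_variant(genome, "chr1", 2L, "T", "G"),
               "REF mismatch")
})

test_that("right-shifted homopolymer indels normalize to the oracle form", {
  genome <- norm_genome()
  # delete one A of the AAA run at 6-8, represented at the run's end
  got <- normalize_variant(genome, "chr1", 7L, "AA", "A")
  want <- oracle_normalize(genome, "chr1", 7L, "AA", "A")
  expect_equal(got, want)
  expect_equal(got$pos, 5L)  # anchored at the C before the run
  # randomized: denormalize a truth variant, then re-normalize
  g2 <- c(chr1 = panelsnp:::with_seed(5, paste0(
    panelsnp:::random_dna(30),
    paste(rep(c("A", "T", "C"), times = c(5, 4, 6)), collapse = ""),
    panelsnp:::random_dna(30))))
  for (seed in 1:100) {
    v <- panelsnp:::with_seed(seed, {
      pos <- sample(5:60, 1)
      if (runif(1) < 0.5) {
        k <- sample(1:3, 1)
        list(pos = pos,
             ref = substring(g2[["chr1"]], pos, pos + k),
             alt = substring(g2[["chr1"]], pos, pos))
      } else {
        list(pos = pos, ref = substring(g2[["chr1"]], pos, pos),
             alt = paste0(substring(g2[["chr1"]], pos, pos),
                          panelsnp:::random_dna(sample(1:3, 1))))
      }
    })
    base <- normalize_variant(g2, "chr1", v$pos, v$ref, v$alt)
    shifted <- panelsnp:::denormalize_variant(
      g2, "chr1", base$pos, base$ref, base$alt,
      steps = panelsnp:::with_seed(seed, sample(1:3, 1)))
    renorm <- normalize_variant(g2, "chr1", shifted$pos, shifted$ref,
                                shifted$alt)
    expect_equal(renorm, base, info = seed)
    expect_equal(renorm,
                 oracle_normalize(g2, "chr1", shifted$pos, shifted$ref,
                                  shifted$alt), info = seed)
  }
})

make_call <- function(sample, caller, pos, qual = 40, gt = 1L,
                      ref = "A", alt = "G") {
  tibble::tibble(sample = sample, caller = caller, chrom = "chr1",
                 pos = pos, ref = ref, alt = alt, qual = qual, gt = gt)
}

test_that("two of three callers never make a pooled variant", {
  calls <- dplyr::bind_rows(
    make_call("s1", "caller1", 100L), make_call("s1", "caller2", 100L),
    make_call("s2", "caller1", 100L), make_call("s2", "caller3", 100L))
  cons <- consensus_calls(calls, callers = paste0("caller", 1:3))
  expect_equal(nrow(cons$pooled), 0)
})

test_that("consensus genotypes follow majority with het fallback", {
  calls <- dplyr::bind_rows(
    make_call("s1", "caller1", 100L, gt = 2L),
    make_call("s1", "caller2", 100L, gt = 2L),
    make_call("s1", "caller3", 100L, gt = 1L),
    make_call("s1", "caller1", 200L, gt = 0L),
    make_call("s1", "caller2", 200L, gt = 1L),
    make_call("s1", "caller3", 200L, gt = 2L))
  cons <- consensus_calls(calls)
  expect_equal(cons$consensus$gt[cons$consensus$pos == 100L], 2L)
  expect_equal(cons$consensus$gt[cons$consensus$pos == 200L], 1L)
})

test_that("pooled set equals the set-algebra oracle and ignores order", {
  for (seed in 1:40) {
    calls <- panelsnp:::with_seed(seed, {
      grid <- expand.grid(sample = c("s1", "s2", "s3"),
                          caller = paste0("caller", 1:3),
                          pos = seq(100L, 600L, by = 100L),
                          stringsAsFactors = FALSE)
      keep <- runif(nrow(grid)) < 0.7
      g <- grid[keep, ]
      tibble::tibble(sample = g$sample, caller = g$caller,
                     chrom = "chr1", pos = g$pos, ref = "A", alt = "G",
                     qual = round(runif(nrow(g), 10, 60), 1),
                     gt = sample(1:2, nrow(g), replace = TRUE))
    })
    cons <- consensus_calls(calls, callers = paste0("caller", 1:3))
    got <- if (nrow(cons$pooled) == 0) character(0) else {
      paste0(cons$pooled$chrom, ":", cons$pooled$pos,
             cons$pooled$ref, ">", cons$pooled$alt)
    }
    expect_setequal(got, oracle_pooled(calls))
    shuffled <- calls[panelsnp:::with_seed(seed, sample(nrow(calls))), ]
    cons2 <- consensus_calls(shuffled, callers = paste0("caller", 1:3))
    expect_equal(cons2$pooled, cons$pooled)
    # consensus calls exist in every caller's qual-filtered set
    f <- calls[calls$qual >= 20, ]
    for (i in seq_len(nrow(cons$consensus))) {
      cc <- cons$consensus[i, ]
      for (cl in paste0("caller", 1:3)) {
        expect_true(any(f$sample == cc$sample & f$caller == cl &
                          f$pos == cc$pos))
      }
    }
  }
})

test_that("the carrier rule distinguishes strict and any-caller modes", {
  calls <- dplyr::bind_rows(
    # s1: full consensus hom-alt
    make_call("s1", "caller1", 100L, gt = 2L),
    make_call("s1", "caller2", 100L, gt = 2L),
    make_call("s1", "caller3", 100L, gt = 2L),
    # s2: only one caller saw it
    make_call("s2", "caller2", 100L, gt = 1L))
  cons <- consensus_calls(calls, callers = paste0("caller", 1:3))
  strict <- genotype_matrix(cons, c("s1", "s2", "s3"))
  expect_equal(strict$s1, 2L)
  expect_true(is.na(strict$s2))
  expect_equal(strict$s3, 0L)
  any_rule <- genotype_matrix(cons, c("s1", "s2", "s3"),
                              carrier_rule = "any")
  expect_equal(any_rule$s2, 1L)
})

test_that("cohort filter bounds carriers and bans missingness", {
  mk <- function(carriers, n = 29, nas = 0) {
    g <- c(rep(1L, carriers), rep(0L, n - carriers))
    if (nas > 0) g[(carriers + 1):(carriers + nas)] <- NA_integer_
    out <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                          variant_id = "v")
    out[sprintf("d%02d", 1:n)] <- as.list(g)
    out
  }
  expect_equal(nrow(cohort_filter(mk(10))), 0)
  expect_equal(nrow(cohort_filter(mk(11))), 1)
  expect_equal(nrow(cohort_filter(mk(18))), 1)
  expect_equal(nrow(cohort_filter(mk(19))), 0)
  expect_equal(nrow(cohort_filter(mk(12, nas = 1))), 0)
  # random matrices against a brute-force count filter
  for (seed in 1:30) {
    g <- panelsnp:::with_seed(seed,
      matrix(sample(c(0L, 0L, 1L, 2L, NA), 10 * 29, replace = TRUE),
             10, 29))
    gm <- tibble::tibble(chrom = "chr1", pos = seq_len(10), ref = "A",
                         alt = "G",
                         variant_id = sprintf("v%02d", 1:10))
    gm[sprintf("d%02d", 1:29)] <- as.data.frame(g)
    out <- cohort_filter(gm)
    want <- vapply(seq_len(10), function(i) {
      cc <- sum(g[i, ] > 0, na.rm = TRUE)
      cc >= 11 && cc <= 18 && !anyNA(g[i, ])
    }, logical(1))
    expect_equal(out$variant_id, gm$variant_id[want])
  }
})

test_that("pattern deduplication keeps the smallest coordinate per pattern", {
  gm <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    ref = "A", alt = "G",
    variant_id = sprintf("v%d", 1:4),
    target_id = c("t1", "t1", "t1", "t2"),
    s1 = c(1L, 1L, 0L, 1L), s2 = c(0L, 0L, 1L, 0L),
    s3 = c(2L, 2L, 0L, 2L))
  out <- dedup_patterns(gm)
  # v1/v2 share target+pattern -> keep v1; v4 matches v1's pattern but
  # on another target -> kept
  expect_setequal(out$variant_id, c("v1", "v3", "v4"))
  expect_equal(out$pattern_duplicates[out$variant_id == "v1"], "v2")
  expect_equal(dedup_patterns(out)$variant_id, out$variant_id)
  # three identical patterns on one target keep exactly one
  gm3 <- dplyr::mutate(gm, target_id = "t1",
                       s1 = 1L, s2 = 0L, s3 = 1L)
  expect_equal(nrow(dedup_patterns(gm3)), 1)
  # all-distinct patterns are untouched
  gm4 <- dplyr::mutate(gm, s2 = c(0L, 1L, 0L, 2L))
  expect_equal(nrow(dedup_patterns(gm4)), 4)
})

test_that("missing caller files are reported by sample and caller", {
  d <- withr::local_tempdir()
  expect_error(read_caller_calls(d, "sX"), "sX.caller1")
})
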