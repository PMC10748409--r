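# Central configuration for every synthetic-data generator.

#' Simulation configuration
#'
#' One validated configuration object drives all generators.  Fields not
#' supplied keep defaults chosen to emulate the study conditions the
#' pipeline was built for: a ~600-subject genotype panel with
#' kilobase-scale LD blocks, three moderately discordant variant callers,
#' and exponential proportional-hazards survival with roughly a quarter of
#' subjects censored.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-identical across runs.
#' @param n_snps Number of source-species SNPs for genome-pair simulation.
#' @param ortholog_classes Optional character vector (length `n_snps`) of
#'   intended per-SNP lift outcomes, drawn from `conserved`, `no_ortholog`,
#'   `too_long`, `unplaced`, `gap_at_snp`.  Default: all `conserved`.
#' @param seg_bp Source-genome bases allotted per SNP segment (default 300).
#' @param n_subs Substitutions planted per conserved segment (default 2).
#' @param del_len Deletion length at the SNP for `gap_at_snp` segments.
#' @param ins_len Insertion length for `too_long` segments (default 1500,
#'   inflating the lifted window well past 1 kb).
#' @param n_subjects Genotype-panel size (default 600, the scale of the
#'   reference panel the block map emulates).
#' @param block_spec Tibble with one row per planted LD block: `n_markers`,
#'   `span_bp`, `recomb_rate_between` (probability that linkage to the
#'   previous block is broken; 1 = linkage equilibrium between blocks).
#' @param n_founders Founder haplotypes per block (default 2, giving
#'   within-block |D'| = 1).
#' @param block_gap_bp Gap between consecutive blocks (default 4000).
#' @param caller_fn_rate Per-caller probability of dropping a true call.
#' @param caller_fp_rate Per-caller probability of emitting each decoy
#'   false-positive site in a sample.
#' @param low_qual_rate Probability that a true call is emitted with
#'   QUAL below 20.
#' @param indel_jitter_rate Probability that an indel call is emitted in a
#'   right-shifted, non-parsimonious representation.
#' @param beta Log-hazard coefficients for planted variant effects.
#' @param baseline_rate Exponential baseline hazard (per day).
#' @param censor_fraction Target fraction of censored subjects
#'   (default 7/29, a typical lost-to-follow-up fraction for a small
#'   clinical cohort).
#' @param survival_dist `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape Shape parameter when `survival_dist = "weibull"`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_snps = 10L,
                       ortholog_classes = NULL,
                       seg_bp = 300L,
                       n_subs = 2L,
                       del_len = 2L,
                       ins_len = 1500L,
                       n_subjects = 600L,
                       block_spec = NULL,
                       n_founders = 2L,
                       block_gap_bp = 4000L,
                       caller_fn_rate = 0.05,
                       caller_fp_rate = 0.02,
                       low_qual_rate = 0.05,
                       indel_jitter_rate = 0.3,
                       beta = numeric(0),
                       baseline_rate = 1 / 365,
                       censor_fraction = 7 / 29,
                       survival_dist = c("exponential", "weibull"),
                       weibull_shape = 1) {
  survival_dist <- match.arg(survival_dist)
  if (is.null(block_spec)) {
    block_spec <- tibble(
      n_markers = c(6L, 8L, 5L, 7L, 9L, 6L, 8L, 7L),
      span_bp = c(3000L, 4800L, 5600L, 6200L, 7400L, 5200L, 6800L, 4200L),
      recomb_rate_between = 1
    )
  }
  block_spec <- as_tibble(block_spec)
  probs <- c(caller_fn_rate, caller_fp_rate, low_qual_rate,
             indel_jitter_rate, censor_fraction,
             block_spec$recomb_rate_between)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all probabilities in a sim_config must lie in [0, 1]")
  }
  if (n_subjects < 2L) abort("n_subjects must be at least 2")
  if (any(!is.finite(beta))) abort("beta coefficients must be finite")
  if (any(block_spec$span_bp < block_spec$n_markers)) {
    abort("block span_bp too small to place distinct marker positions")
  }
  if (!is.null(ortholog_classes)) {
    ok <- ortholog_classes %in%
      c("conserved", "no_ortholog", "too_long", "unplaced", "gap_at_snp")
    if (!all(ok)) abort("unknown ortholog class in ortholog_classes")
    if (length(ortholog_classes) != n_snps) {
      abort("ortholog_classes must have length n_snps")
    }
  }
  out <- list(seed = as.integer(seed), n_snps = as.integer(n_snps),
              ortholog_classes = ortholog_classes,
              seg_bp = as.integer(seg_bp), n_subs = as.integer(n_subs),
              del_len = as.integer(del_len), ins_len = as.integer(ins_len),
              n_subjects = as.integer(n_subjects), block_spec = block_spec,
              n_founders = as.integer(n_founders),
              block_gap_bp = as.integer(block_gap_bp),
              caller_fn_rate = caller_fn_rate,
              caller_fp_rate = caller_fp_rate,
              low_qual_rate = low_qual_rate,
              indel_jitter_rate = indel_jitter_rate,
              beta = beta, baseline_rate = baseline_rate,
              censor_fraction = censor_fraction,
              survival_dist = survival_dist,
              weibull_shape = weibull_shape)
  class(out) <- "sim_config"
  out
}

#' Read or write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$block_spec)) x$block_spec <- as_tibble(x$block_spec)
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$block_spec <- as.list(x$block_spec)
  yaml::write_yaml(x, path)
  invisible(path)
}
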