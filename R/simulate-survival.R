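# Proportional-hazards survival simulation with planted variant effects.

#' Simulate a survival cohort from truth genotypes
#'
#' Event times follow an exponential baseline hazard (optionally Weibull)
#' scaled by `exp(sum(beta * carrier))`, with independent exponential
#' censoring calibrated to yield approximately `censor_fraction` censored
#' subjects.  Null clinical covariates (sex, neuter status, clinical
#' stage, protocol, age at diagnosis) are attached for screening tests.
#'
#' @param truth List with a `gt` samples x variants matrix (0/1/2); e.g.
#'   from [simulate_cohort_variants()], or a bare matrix.
#' @param config A [sim_config()]; `beta` gives log-hazard coefficients
#'   for the first `length(beta)` variant columns (or named columns).
#' @return Tibble: `sample_id`, `time` (days), `event` (1 = event, 0 =
#'   censored), clinical covariates, then one binary carrier column per
#'   variant.
#' @export
simulate_survival <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  gt <- if (is.matrix(truth)) truth else truth$gt
  n <- nrow(gt)
  nv <- ncol(gt)
  beta <- config$beta
  if (length(beta) > nv) abort("more beta coefficients than variants")
  b <- setNames(numeric(nv), colnames(gt))
  if (!is.null(names(beta)) && all(names(beta) %in% colnames(gt))) {
    b[names(beta)] <- beta
  } else if (length(beta) > 0) {
    b[seq_along(beta)] <- beta
  }
  carriers <- (gt > 0L) * 1L
  with_seed(sub_seed(config$seed, 17L), {
    lp <- as.numeric(carriers %*% b)
    rate <- config$baseline_rate * exp(lp)
    t_event <- if (config$survival_dist == "weibull") {
      (rexp(n) / rate)^(1 / config$weibull_shape)
    } else {
      rexp(n, rate)
    }
    f <- config$censor_fraction
    if (f > 0) {
      rate_c <- config$baseline_rate * mean(exp(lp)) * f / (1 - f)
      t_cens <- rexp(n, rate_c)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    age <- sample(2:11, n, replace = TRUE)
    covs <- tibble(
      sample_id = rownames(gt) %||% sprintf("D%02d", seq_len(n)),
      time = time, event = event,
      sex = sample(c("M", "F"), n, replace = TRUE),
      neuter = sample(c("yes", "no"), n, replace = TRUE),
      stage = sample(c("III", "IV", "V"), n, replace = TRUE,
                     prob = c(0.1, 0.55, 0.35)),
      protocol = sample(c("A", "B"), n, replace = TRUE,
                        prob = c(0.2, 0.8)),
      age_years = age,
      age_class = encode_age_class(age)
    )
    bind_cols(covs, as_tibble(carriers))
  })
}

#' Encode age at diagnosis as adult/senior
#'
#' Adults (2-7 years) are encoded 1, seniors (8 years and older) 0.
#'
#' @param years Age in years.
#' @return Integer vector of 0/1.
#' @export
encode_age_class <- function(years) {
  as.integer(years <= 7)
}
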