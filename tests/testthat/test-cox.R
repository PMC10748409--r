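# partial-likelihood oracle for untied data: grid search over beta
oracle_cox_beta <- function(time, event, x, grid = seq(-4, 4, 0.001)) {
  logpl <- vapply(grid, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }, numeric(1))
  grid[which.max(logpl)]
}

test_that("cox_fit maximizes the partial likelihood (grid oracle)", {
  rec <- tibble::tibble(time = c(2, 5, 7, 11), event = c(1, 1, 1, 1),
                        x = c(1, 0, 1, 0))
  fit <- cox_fit(rec, "x")
  expect_equal(fit$terms$beta, oracle_cox_beta(rec$time, rec$event,
                                               rec$x),
               tolerance = 5e-3)
  expect_equal(fit$aic, -2 * fit$loglik + 2)
  for (seed in 1:10) {
    rec <- panelsnp:::with_seed(seed, tibble::tibble(
      time = sort(rexp(12)) * 100, event = 1L,
      x = rbinom(12, 1, 0.5)))
    if (length(unique(rec$x)) < 2) next
    fit <- cox_fit(rec, "x")
    if (fit$flagged) next
    expect_equal(fit$terms$beta,
                 oracle_cox_beta(rec$time, rec$event, rec$x),
                 tolerance = 5e-3, info = seed)
  }
})

test_that("constant covariates and event-free data are rejected", {
  rec <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 0),
                        x = c(1, 1, 1))
  expect_error(cox_fit(rec, "x"), "constant")
  rec0 <- tibble::tibble(time = c(1, 2), event = c(0, 0), x = c(0, 1))
  expect_error(cox_fit(rec0, "x"), "event")
})

test_that("a planted hazard ratio of 2 is recovered at n = 500", {
  cfg <- sim_config(seed = 77, beta = log(2), censor_fraction = 0.2)
  gt <- panelsnp:::with_seed(78,
    matrix(rbinom(500, 2, 0.4), 500, 1, dimnames = list(NULL, "v01")))
  rec <- simulate_survival(gt, cfg)
  fit <- cox_fit(rec, "v01")
  expect_gt(fit$terms$hr, 1.6)
  expect_lt(fit$terms$hr, 2.5)
})

test_that("tidy and glance expose broom-style summaries", {
  rec <- panelsnp:::with_seed(1, tibble::tibble(
    time = rexp(40, 0.01), event = rbinom(40, 1, 0.8),
    x = rbinom(40, 1, 0.5)))
  fit <- cox_fit(rec, "x")
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "hazard_ratio", "std.error",
                     "p.value"))
  gl <- generics::glance(fit)
  expect_equal(gl$k, 1L)
  expect_equal(gl$n, 40L)
})

test_that("covariate screen encodes age classes and skips constants", {
  expect_equal(encode_age_class(c(2, 7, 8, 11)), c(1L, 1L, 0L, 0L))
  rec <- panelsnp:::with_seed(2, tibble::tibble(
    time = rexp(60, 0.01), event = 1L,
    sex = sample(c("M", "F"), 60, TRUE),
    mono = "onlylevel"))
  expect_warning(out <- covariate_screen(rec, c("sex", "mono")),
                 "single level")
  expect_equal(unique(out$covariate), "sex")
  expect_equal(nrow(covariate_screen(rec, character(0))), 0)
})

test_that("a single weak candidate yields an empty final model", {
  rec <- panelsnp:::with_seed(3, tibble::tibble(
    time = rexp(50, 0.01), event = 1L, v01 = rbinom(50, 1, 0.5)))
  p <- cox_fit(rec, "v01")$terms$p
  expect_gt(p, 0.5)
  out <- collett_select(rec, "v01")
  expect_equal(length(out$model_vars), 0)
  expect_equal(length(out$significant), 0)
  expect_equal(out$final$k, 0L)
})

test_that("backward-selection AIC never increases along the trace", {
  cfg <- sim_config(seed = 55, beta = c(0.6, -0.6))
  gt <- panelsnp:::with_seed(56,
    matrix(rbinom(200 * 6, 2, 0.4), 200, 6,
           dimnames = list(NULL, sprintf("v%02d", 1:6))))
  rec <- simulate_survival(gt, cfg)
  out <- collett_select(rec, sprintf("v%02d", 1:6))
  bt <- out$trace[out$trace$stage == "backward", ]
  if (nrow(bt) > 1) expect_true(all(diff(bt$aic) <= 1e-9))
  # each accepted drop is the AIC-minimal alternative at its step
  expect_true(all(c("v01", "v02") %in% out$model_vars))
})

test_that("backward elimination matches MASS::stepAIC on the same model", {
  skip_if_not_installed("MASS")
  for (seed in c(21, 22, 23)) {
    cfg <- sim_config(seed = seed, beta = c(0.8, -0.8))
    gt <- panelsnp:::with_seed(seed + 100,
      matrix(rbinom(200 * 5, 2, 0.4), 200, 5,
             dimnames = list(NULL, sprintf("v%02d", 1:5))))
    rec <- simulate_survival(gt, cfg)
    vars <- sprintf("v%02d", 1:5)
    tr <- local({
      rows <- list()
      list(add = function(...) NULL, table = function() NULL)
    })
    mine <- sort(panelsnp:::step_backward(rec, vars, "efron", tr))
    full <- survival::coxph(
      as.formula(paste("survival::Surv(time, event) ~",
                       paste(vars, collapse = "+"))), data = rec,
      ties = "efron")
    ref <- MASS::stepAIC(full, direction = "backward", trace = 0)
    expect_equal(mine, sort(names(coef(ref))), info = seed)
  }
})

test_that("selection is invariant to candidate order", {
  cfg <- sim_config(seed = 65, beta = c(0.7))
  gt <- panelsnp:::with_seed(66,
    matrix(rbinom(150 * 5, 2, 0.4), 150, 5,
           dimnames = list(NULL, sprintf("v%02d", 1:5))))
  rec <- simulate_survival(gt, cfg)
  a <- collett_select(rec, sprintf("v%02d", 1:5))
  b <- collett_select(rec, rev(sprintf("v%02d", 1:5)))
  expect_equal(sort(a$model_vars), sort(b$model_vars))
  expect_equal(a$final$aic, b$final$aic)
})

test_that("KM median follows the first-drop-to-half rule", {
  expect_equal(km_median(c(1, 2, 3, 4), c(1, 1, 1, 1)), 2)
  expect_equal(km_median(c(5, 6, 7), c(1, 1, 1)), 6)
  # heavy censoring can leave the median undefined
  expect_true(is.na(km_median(c(1, 2, 3, 4), c(1, 0, 0, 0))))
})

test_that("median risk split separates planted risk groups", {
  cfg <- sim_config(seed = 91, beta = c(1.2), censor_fraction = 0.1)
  gt <- panelsnp:::with_seed(92,
    matrix(rbinom(300, 2, 0.25), 300, 1, dimnames = list(NULL, "v01")))
  rec <- simulate_survival(gt, cfg)
  fit <- cox_fit(rec, "v01")
  st <- stratify(fit, rec)
  gm <- st$group_medians
  expect_setequal(gm$group, c("high", "low"))
  expect_lt(gm$km_median[gm$group == "high"],
            gm$km_median[gm$group == "low"])
  expect_equal(sum(gm$n), 300)
  td <- generics::tidy(st)
  expect_equal(nrow(td), 300)
  # degenerate: identical risk scores collapse to one group
  rec2 <- dplyr::mutate(rec, v01 = 1L)
  expect_warning(st2 <- stratify(fit, rec2), "identical")
  expect_true(st2$degenerate)
})

test_that("stratify refuses an empty final model", {
  rec <- panelsnp:::with_seed(3, tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    time = rexp(20, 0.01), event = 1L, x = rbinom(20, 1, 0.5)))
  empty <- cox_fit(rec, character(0))
  expect_error(stratify(empty, rec), "non-empty")
})
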