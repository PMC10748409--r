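# Risk-score stratification: linear predictor from a fitted Cox model,
# median split, and Kaplan-Meier group medians.

#' Kaplan-Meier median survival time
#'
#' The first observed time at which the Kaplan-Meier survival estimate
#' drops to 0.5 or below; NA when the curve never reaches 0.5.
#'
#' @param time,event Survival times and event indicators.
#' @return Median survival time (same units as `time`).
#' @export
km_median <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  i <- which(sf$surv <= 0.5 + 1e-12)
  if (length(i) == 0) NA_real_ else sf$time[i[1]]
}

#' Stratify subjects by median risk score
#'
#' Computes each subject's linear predictor under the final model,
#' splits at the median (ties assigned to the low-risk group) and
#' summarizes each group's Kaplan-Meier median survival.
#'
#' @param fit A [cox_fit()] or [collett_select()] result with a
#'   non-empty model.
#' @param records Survival tibble containing the model's covariate
#'   columns.
#' @return Object of class `risk_strat`: `scores` (tibble `sample_id`,
#'   `risk_score`, `group`), `group_medians` (tibble `group`, `n`,
#'   `n_events`, `km_median`), `degenerate` (TRUE when all risk scores
#'   are identical, collapsing to a single group).
#' @export
stratify <- function(fit, records) {
  if (inherits(fit, "collett_fit")) fit <- fit$final
  stopifnot(inherits(fit, "cox_fit"))
  if (nrow(fit$terms) == 0) {
    abort("stratify requires a non-empty final model")
  }
  X <- as.matrix(records[, fit$terms$term, drop = FALSE])
  lp <- as.numeric(X %*% fit$terms$beta)
  med <- median(lp)
  degenerate <- length(unique(lp)) == 1L
  if (degenerate) {
    warn("all risk scores identical: single-group stratification")
  }
  group <- ifelse(lp > med, "high", "low")
  scores <- tibble(
    sample_id = records$sample_id %||% sprintf("S%03d", seq_along(lp)),
    risk_score = lp, group = group)
  gm <- scores |>
    mutate(time = records$time, event = records$event) |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), n_events = sum(.data$event),
              km_median = km_median(.data$time, .data$event),
              .groups = "drop")
  out <- list(scores = scores, group_medians = gm,
              degenerate = degenerate)
  class(out) <- "risk_strat"
  out
}

#' @export
print.risk_strat <- function(x, ...) {
  cat("Median risk-score stratification\n")
  print(as.data.frame(x$group_medians))
  invisible(x)
}

#' @describeIn stratify Per-subject scores and groups.
#' @param x A `risk_strat`.
#' @param ... Unused.
#' @export
tidy.risk_strat <- function(x, ...) x$scores

#' @describeIn stratify Group summary with KM medians.
#' @export
glance.risk_strat <- function(x, ...) {
  tidyr::pivot_wider(x$group_medians, names_from = "group",
                     values_from = c("n", "n_events", "km_median"))
}
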