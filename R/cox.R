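# Cox proportional-hazards fitting: a thin, flagged wrapper around
# survival::coxph returning coefficient tables, log partial likelihood and
# AIC, plus the univariable clinical-covariate screen.

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron ties by default) for the
#' given covariate subset.  Fits that fail to converge or show a monotone
#' likelihood (infinite coefficients) are flagged rather than raised.
#'
#' @param records Tibble with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names (empty
#'   vector fits the null model).
#' @param ties_method Ties handling, `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: list with `terms` (tibble: `term`,
#'   `beta`, `hr`, `se`, `p`), `loglik`, `aic`, `k`, `n`, `n_events`,
#'   `flagged`, `fit` (the underlying `coxph` object or NULL for the
#'   null model).
#' @export
cox_fit <- function(records, covariates = character(0),
                    ties_method = c("efron", "breslow")) {
  ties_method <- match.arg(ties_method)
  if (sum(records$event) < 1L) abort("cox_fit requires at least one event")
  if (length(covariates) == 0) {
    f0 <- survival::coxph(survival::Surv(time, event) ~ 1, data = records)
    out <- list(terms = tibble(term = character(), beta = numeric(),
                               hr = numeric(), se = numeric(),
                               p = numeric()),
                loglik = as.numeric(f0$loglik[1]),
                aic = -2 * as.numeric(f0$loglik[1]), k = 0L,
                n = nrow(records), n_events = sum(records$event),
                flagged = FALSE, fit = NULL)
    class(out) <- "cox_fit"
    return(out)
  }
  for (v in covariates) {
    vals <- records[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      abort(paste0("covariate ", v, " is constant"))
    }
  }
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(paste0("`", covariates, "`"),
                                collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = ties_method),
    warning = function(w) {
      if (grepl("converge|infinite|loglik|singular", conditionMessage(w),
                ignore.case = TRUE)) {
        flagged <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)
  co <- sm$coefficients
  if (any(is.na(fit$coefficients)) || any(abs(fit$coefficients) > 15)) {
    flagged <- TRUE
  }
  ll <- as.numeric(fit$loglik[2])
  k <- sum(!is.na(fit$coefficients))
  out <- list(
    terms = tibble(term = rownames(co),
                   beta = co[, "coef"], hr = co[, "exp(coef)"],
                   se = co[, "se(coef)"], p = co[, "Pr(>|z|)"]),
    loglik = ll, aic = -2 * ll + 2 * k, k = as.integer(k),
    n = sm$n, n_events = sm$nevent, flagged = flagged, fit = fit
  )
  # strip backtick residue from term labels of plain numeric covariates
  out$terms$term <- gsub("`", "", out$terms$term)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit:", x$k, "term(s),", x$n, "subjects,", x$n_events,
      "events\n")
  cat("log partial likelihood:", format(x$loglik, digits = 6),
      " AIC:", format(x$aic, digits = 6),
      if (x$flagged) " [flagged]" else "", "\n")
  if (nrow(x$terms) > 0) print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' @describeIn cox_fit Tidy the coefficient table.
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @export
tidy.cox_fit <- function(x, ...) {
  transmute(x$terms, term = .data$term, estimate = .data$beta,
            hazard_ratio = .data$hr, std.error = .data$se,
            p.value = .data$p)
}

#' @describeIn cox_fit One-row model summary.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, k = x$k, loglik = x$loglik,
         aic = x$aic, flagged = x$flagged)
}

#' Univariable screen of clinical covariates
#'
#' One univariable Cox fit per covariate; categorical covariates are
#' treated as factors.  Covariates with a single level are skipped with a
#' warning.
#'
#' @param records Survival tibble (`time`, `event`, covariates).
#' @param covariates Character vector of covariate columns.
#' @param ties_method Passed to [cox_fit()].
#' @return Tibble with one row per fitted term: `covariate`, `term`,
#'   `beta`, `hr`, `se`, `p`, `aic`, `flagged`.
#' @export
covariate_screen <- function(records, covariates,
                             ties_method = "efron") {
  out <- map(covariates, function(v) {
    vals <- records[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      warn(paste0("covariate ", v, " has a single level; skipped"))
      return(NULL)
    }
    rec <- records
    if (is.character(rec[[v]])) rec[[v]] <- factor(rec[[v]])
    f <- cox_fit(rec, v, ties_method)
    mutate(f$terms, covariate = v, aic = f$aic, flagged = f$flagged,
           .before = 1)
  })
  out <- list_rbind(discard(out, is.null))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(covariate = character(), term = character(),
                  beta = numeric(), hr = numeric(), se = numeric(),
                  p = numeric(), aic = numeric(), flagged = logical()))
  }
  out
}
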