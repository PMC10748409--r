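# Multi-stage Cox variable selection: univariable screen, AIC-guided
# backward / forward / bidirectional stepwise passes with p-value gates
# between stages, and a final significance call.

step_backward <- function(records, vars, ties_method, trace) {
  current <- vars
  aic_now <- cox_fit(records, current, ties_method)$aic
  repeat {
    if (length(current) == 0) break
    cand <- map_dbl(current, function(v) {
      f <- tryCatch(cox_fit(records, setdiff(current, v), ties_method),
                    error = function(e) NULL)
      if (is.null(f) || f$flagged) Inf else f$aic
    })
    best <- which.min(cand)
    if (cand[best] < aic_now) {
      trace$add("backward", "drop", current[best], cand[best])
      current <- setdiff(current, current[best])
      aic_now <- cand[best]
    } else break
  }
  current
}

step_forward <- function(records, start, pool, ties_method, trace,
                        stage = "forward") {
  current <- start
  aic_now <- cox_fit(records, current, ties_method)$aic
  repeat {
    addable <- setdiff(pool, current)
    if (length(addable) == 0) break
    cand <- map_dbl(addable, function(v) {
      f <- tryCatch(cox_fit(records, c(current, v), ties_method),
                    error = function(e) NULL)
      if (is.null(f) || f$flagged) Inf else f$aic
    })
    best <- which.min(cand)
    if (cand[best] < aic_now) {
      trace$add(stage, "add", addable[best], cand[best])
      current <- c(current, addable[best])
      aic_now <- cand[best]
    } else break
  }
  current
}

step_both <- function(records, start, pool, ties_method, trace) {
  current <- start
  aic_now <- cox_fit(records, current, ties_method)$aic
  repeat {
    addable <- setdiff(pool, current)
    moves <- bind_rows(
      if (length(addable)) tibble(action = "add", var = addable),
      if (length(current)) tibble(action = "drop", var = current)
    )
    if (is.null(moves) || nrow(moves) == 0) break
    moves$aic <- map_dbl(seq_len(nrow(moves)), function(i) {
      vars <- if (moves$action[i] == "add") c(current, moves$var[i]) else
        setdiff(current, moves$var[i])
      f <- tryCatch(cox_fit(records, vars, ties_method),
                    error = function(e) NULL)
      if (is.null(f) || f$flagged) Inf else f$aic
    })
    best <- which.min(moves$aic)
    if (moves$aic[best] < aic_now) {
      trace$add("bidirectional", moves$action[best], moves$var[best],
                moves$aic[best])
      current <- if (moves$action[best] == "add") {
        c(current, moves$var[best])
      } else setdiff(current, moves$var[best])
      aic_now <- moves$aic[best]
    } else break
  }
  current
}

gate_p <- function(records, vars, threshold, ties_method, trace, stage) {
  if (length(vars) == 0) return(character(0))
  f <- cox_fit(records, vars, ties_method)
  keep <- f$terms$term[!is.na(f$terms$p) & f$terms$p <= threshold]
  for (v in setdiff(vars, keep)) trace$add(stage, "gate-drop", v, NA)
  keep
}

#' Multi-stage Cox variable selection
#'
#' Executes, in order: (1) a univariable Cox fit per candidate, keeping
#' those with `p <= univ_p`; (2) a joint multivariable fit with backward
#' elimination, removing at each step the variable whose removal most
#' lowers the AIC, while the AIC improves; (3) a `p <= stage_p` gate;
#' (4) forward selection over the stage-1 pool, adding the variable with
#' the largest AIC decrease while the AIC improves; (5) a second
#' `p <= stage_p` gate; (6) bidirectional stepwise (best single add or
#' drop by AIC until no improvement); (7) the significance call
#' `p <= final_p` on the resulting model.  Candidates are processed in
#' sorted order, so the selection does not depend on input order.
#'
#' @param records Survival tibble (`time`, `event`, candidate columns).
#' @param candidates Character vector of candidate covariate columns.
#' @param univ_p,stage_p,final_p Stage thresholds (defaults 0.5, 0.1,
#'   0.05).
#' @param ties_method Passed to [cox_fit()].
#' @return Object of class `collett_fit`: `final` (the stage-6
#'   [cox_fit()]), `model_vars`, `significant` (terms with
#'   `p <= final_p`), `pool` (stage-1 survivors), `trace` (tibble of
#'   stages/actions/AIC), `thresholds`.  An empty model at any stage
#'   yields an empty result, not an error.
#' @export
collett_select <- function(records, candidates, univ_p = 0.5,
                           stage_p = 0.1, final_p = 0.05,
                           ties_method = "efron") {
  candidates <- sort(unique(candidates))
  tr <- local({
    rows <- list()
    list(add = function(stage, action, var, aic) {
      rows[[length(rows) + 1L]] <<- tibble(stage = stage, action = action,
                                           var = var,
                                           aic = as.numeric(aic))
    },
    table = function() {
      if (length(rows) == 0) {
        tibble(stage = character(), action = character(),
               var = character(), aic = numeric())
      } else list_rbind(rows)
    })
  })

  usable <- keep(candidates, function(v) {
    vals <- records[[v]]
    length(unique(vals[!is.na(vals)])) >= 2L
  })
  for (v in setdiff(candidates, usable)) {
    warn(paste0("candidate ", v, " is constant; excluded"))
  }

  # stage 1: univariable screen
  pool <- keep(usable, function(v) {
    f <- tryCatch(cox_fit(records, v, ties_method),
                  error = function(e) NULL)
    if (is.null(f) || f$flagged) return(FALSE)
    isTRUE(f$terms$p[1] <= univ_p)
  })
  for (v in pool) tr$add("univariable", "keep", v, NA)

  vars <- pool
  if (length(vars) > 0) {
    vars <- step_backward(records, vars, ties_method, tr)       # 2
    vars <- gate_p(records, vars, stage_p, ties_method, tr,
                   "post-backward")                              # 3
    vars <- step_forward(records, vars, pool, ties_method, tr)   # 4
    vars <- gate_p(records, vars, stage_p, ties_method, tr,
                   "post-forward")                               # 5
    vars <- step_both(records, vars, pool, ties_method, tr)      # 6
  }
  final <- cox_fit(records, vars, ties_method)
  significant <- final$terms$term[!is.na(final$terms$p) &
                                    final$terms$p <= final_p]
  out <- list(final = final, model_vars = vars,
              significant = significant, pool = pool,
              trace = tr$table(),
              thresholds = c(univ_p = univ_p, stage_p = stage_p,
                             final_p = final_p))
  class(out) <- "collett_fit"
  out
}

#' @export
print.collett_fit <- function(x, ...) {
  cat("Multi-stage Cox selection\n")
  cat("  stage-1 pool:", length(x$pool), "candidate(s)\n")
  cat("  final model:", length(x$model_vars), "variable(s);",
      length(x$significant), "significant at p <=",
      x$thresholds[["final_p"]], "\n")
  if (length(x$model_vars) > 0) print(as.data.frame(x$final$terms),
                                      digits = 4)
  invisible(x)
}

#' @describeIn collett_select Tidy the final-model coefficient table,
#'   with a `significant` flag.
#' @param x A `collett_fit`.
#' @param ... Unused.
#' @export
tidy.collett_fit <- function(x, ...) {
  tidy(x$final) |>
    mutate(significant = .data$term %in% x$significant)
}

#' @describeIn collett_select One-row selection summary.
#' @export
glance.collett_fit <- function(x, ...) {
  tibble(n_candidates_pool = length(x$pool),
         n_model = length(x$model_vars),
         n_significant = length(x$significant),
         aic = x$final$aic, loglik = x$final$loglik)
}
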