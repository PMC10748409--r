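# ggplot2 visualization helpers for the main result types.

#' Bar chart of conservation-cascade statuses
#'
#' @param cascade Result of [run_ortholog_cascade()].
#' @return A ggplot object.
#' @export
plot_cascade <- function(cascade) {
  counts <- cascade_counts(cascade)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "SNPs",
                  title = "Ortholog mapping and conservation filter") +
    ggplot2::theme_minimal()
}

#' Histogram of haplotype-block spans
#'
#' @param blocks Block tibble from [find_blocks()].
#' @return A ggplot object.
#' @export
plot_block_spans <- function(blocks) {
  med <- median_block_span(blocks)
  ggplot2::ggplot(blocks, ggplot2::aes(x = .data$span_bp)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = med, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "block span (bp)", y = "blocks",
                  subtitle = paste0("median span ", round(med), " bp")) +
    ggplot2::theme_minimal()
}

#' Genotype heatmap of pooled variants
#'
#' @param gm Genotype matrix tibble from [genotype_matrix()].
#' @return A ggplot object.
#' @export
plot_genotype_heatmap <- function(gm) {
  sc <- sample_cols(gm)
  long <- gm |>
    select("variant_id", all_of(sc)) |>
    pivot_longer(-"variant_id", names_to = "sample",
                 values_to = "genotype")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample,
                                     y = .data$variant_id,
                                     fill = factor(.data$genotype))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey90", `1` = "goldenrod", `2` = "firebrick"),
      na.value = "white", name = "genotype") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Forest plot of a selection result
#'
#' @param object A `collett_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.collett_fit <- function(object, ...) {
  d <- tidy(object) |>
    mutate(lo = exp(.data$estimate - 1.96 * .data$std.error),
           hi = exp(.data$estimate + 1.96 * .data$std.error))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hazard_ratio,
                                  y = .data$term,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo,
                                         xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "hazard ratio", y = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves of the risk groups
#'
#' @param object A `risk_strat` (needs the original records to rebuild
#'   curves, so they are carried in `...` as `records`).
#' @param records The survival tibble used in [stratify()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_strat <- function(object, records, ...) {
  d <- bind_cols(object$scores,
                 select(records, "time", "event"))
  km <- d |>
    group_by(.data$group) |>
    group_modify(function(g, key) {
      sf <- survival::survfit(survival::Surv(g$time, g$event) ~ 1)
      tibble(time = c(0, sf$time), surv = c(1, sf$surv))
    }) |>
    ungroup()
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = "risk group") +
    ggplot2::theme_minimal()
}
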