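# broom-style accessors and ggplot2 autoplot methods for result objects.

#' Tidy an evaluation report
#'
#' One row per metric cell: mode x variant type x genotype class x stratum,
#' with TP/FP/FN counts and precision/recall/F1. `"all"` levels are the
#' marginal aggregates.
#'
#' @param x A `poly_eval` object from [evaluate_calls()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.poly_eval <- function(x, ...) as_tibble(x$cells)

#' One-row summary of an evaluation
#'
#' Overall (type = class = stratum = "all") precision, recall and F1 per
#' mode, in wide form, plus input sizes.
#'
#' @param x A `poly_eval` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.poly_eval <- function(x, ...) {
  top <- x$cells %>%
    filter(.data$vtype == "all", .data$gt_class == "all",
           .data$stratum == "all") %>%
    select("mode", "TP", "FP", "FN", "precision", "recall", "f1")
  wide <- tidyr::pivot_wider(
    top, names_from = "mode",
    values_from = c("TP", "FP", "FN", "precision", "recall", "f1"),
    names_glue = "{mode}_{.value}")
  dplyr::bind_cols(wide, tibble(n_truth = x$n_truth, n_query = x$n_query,
                                n_nocall = x$n_nocall))
}

#' Tidy a merged truth set
#' @param x A `merged_truth` object from [merge_truth()].
#' @param ... Unused.
#' @return The records as a tibble, with a `gt_class` column added.
#' @export
tidy.merged_truth <- function(x, ...) {
  out <- as_tibble(x$records)
  out$gt_class <- classify_genotype(out$gt)
  out
}

#' One-row summary of a merged truth set
#' @param x A `merged_truth` object.
#' @param ... Unused.
#' @return A one-row tibble: site count, output ploidy, confident bases,
#'   hom-ref records dropped during harmonization.
#' @export
glance.merged_truth <- function(x, ...) {
  tibble(n_sites = nrow(x$records), ploidy = x$ploidy,
         confident_bases = region_total_length(x$regions),
         n_hom_ref_dropped = x$n_hom_ref_dropped)
}

#' Plot precision/recall/F1 by mode and variant type
#'
#' @param object A `poly_eval` object.
#' @param stratum Stratum label to plot (default `"all"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poly_eval <- function(object, stratum = "all", ...) {
  df <- object$cells %>%
    filter(.data$gt_class == "all", .data$stratum == !!stratum) %>%
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vtype, y = .data$value,
                                   fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "variant type", y = NULL, fill = "mode",
                  title = paste0("Callset accuracy (stratum: ", stratum, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the dosage confusion matrix
#'
#' Tile plot of truth dosage vs called dosage for the truth ALT allele at
#' every truth site; the diagonal is exact dosage concordance, the
#' `called = 0` column is the missed / called-hom-ref mass.
#'
#' @param x A `poly_eval` object.
#' @return A ggplot object.
#' @export
plot_dosage_confusion <- function(x) {
  stopifnot(inherits(x, "poly_eval"))
  df <- x$confusion
  ggplot2::ggplot(df, ggplot2::aes(x = .data$called_dosage,
                                   y = .data$truth_dosage,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_x_continuous(breaks = 0:6) +
    ggplot2::scale_y_continuous(breaks = 0:6) +
    ggplot2::labs(x = "called dosage", y = "truth dosage",
                  title = "Allelic dosage confusion") +
    ggplot2::theme_minimal()
}
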