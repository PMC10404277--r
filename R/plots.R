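#' Plot methods for polyte result objects
#'
#' `autoplot()` methods give each result type its canonical display: the
#' TE-vs-RNA fold-change scatter for [te_analysis()] results, a volcano for
#' [differential_expression()], the per-base relative-occupancy track for
#' [occupancy_profile()], a paired-bar view for [compare_occupancy()], and
#' mean +/- points bars for [relative_luciferase()].
#'
#' @param object A polyte result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name polyte-autoplot
NULL

#' @rdname polyte-autoplot
#' @method autoplot te_results
#' @export
autoplot.te_results <- function(object, ...) {
  tt <- attr(object, "te_threshold")
  rt <- attr(object, "rna_threshold")
  ggplot2::ggplot(object, ggplot2::aes(.data$rna_log2fc, .data$te_log2fc,
                                       colour = .data$te_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(-tt, tt), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-rt, rt), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(TE_up = "#c0392b",
                                            TE_down = "#2980b9",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "RNA log2 fold-change", y = "TE log2 fold-change",
                  colour = NULL)
}

#' @rdname polyte-autoplot
#' @method autoplot de_results
#' @export
autoplot.de_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$log2fc, -log10(.data$fdr),
                                       colour = .data$de_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 FDR", colour = NULL)
}

#' @rdname polyte-autoplot
#' @param regions Optional feature tibble (`feature_id`, `start`, `end`) to
#'   shade under an occupancy profile.
#' @method autoplot occupancy_profile
#' @export
autoplot.occupancy_profile <- function(object, regions = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$pos, .data$density)) +
    ggplot2::geom_area(fill = "grey40") +
    ggplot2::labs(x = "transcript position (nt)",
                  y = "relative ribosome occupancy")
  if (!is.null(regions)) {
    if ("transcript_id" %in% names(regions)) {
      regions <- filter(regions,
                        .data$transcript_id == object$transcript_id[1])
    }
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$feature_id)) +
      ggplot2::labs(fill = NULL)
  }
  p
}

#' @rdname polyte-autoplot
#' @method autoplot occupancy_comparison
#' @export
autoplot.occupancy_comparison <- function(object, ...) {
  long <- object %>%
    select("region", "proportion_a", "proportion_b") %>%
    tidyr::pivot_longer(-"region", names_to = "condition",
                        values_to = "proportion") %>%
    mutate(condition = dplyr::recode(.data$condition,
                                     proportion_a = "a", proportion_b = "b"))
  ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$proportion,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "occupancy proportion", fill = NULL)
}

#' @rdname polyte-autoplot
#' @method autoplot luciferase_results
#' @export
autoplot.luciferase_results <- function(object, ...) {
  means <- object %>%
    group_by(.data$construct_id) %>%
    summarise(mean_activity = mean(.data$relative_activity), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(.data$construct_id,
                                      .data$mean_activity)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point(data = object,
                        ggplot2::aes(.data$construct_id,
                                     .data$relative_activity)) +
    ggplot2::labs(x = NULL, y = "relative luciferase activity")
}
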