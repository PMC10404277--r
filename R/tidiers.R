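#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a polyte t-test
#'
#' @param x A [unpaired_t_test()] result.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `statistic`, `df`, `p.value`,
#'   `method`.
#' @method tidy polyte_ttest
#' @export
tidy.polyte_ttest <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
         p.value = x$p_value, method = x$method)
}

#' @rdname tidy.polyte_ttest
#' @method glance polyte_ttest
#' @export
glance.polyte_ttest <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         n_x = x$n_x, n_y = x$n_y)
}

#' One-row summaries of TE and DE result tables
#'
#' @param x A `te_results` or `de_results` tibble.
#' @param ... Unused.
#' @return One-row tibble of class counts (plus the thresholds and, for DE,
#'   the common dispersion used).
#' @method glance te_results
#' @export
glance.te_results <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_te_up = sum(x$te_class == "TE_up"),
    n_te_down = sum(x$te_class == "TE_down"),
    te_threshold = attr(x, "te_threshold"),
    rna_threshold = attr(x, "rna_threshold")
  )
}

#' @rdname glance.te_results
#' @method glance de_results
#' @export
glance.de_results <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$de_class == "up"),
    n_down = sum(x$de_class == "down"),
    dispersion = attr(x, "dispersion"),
    fdr_threshold = attr(x, "fdr_threshold"),
    lfc_threshold = attr(x, "lfc_threshold")
  )
}
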