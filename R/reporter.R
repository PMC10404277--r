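#' Relative dual-luciferase activities
#'
#' Computes the per-well Renilla/Firefly ratio (Firefly is the transfection
#' efficiency control, so the ratio cancels well-to-well transfection
#' differences) and normalizes each ratio to the mean ratio of the control
#' construct, whose mean relative activity is therefore 1 by construction.
#'
#' @param wells Tibble with `construct_id`, `replicate`, `renilla`,
#'   `firefly` (all readings positive).
#' @param control_id The normalization construct (e.g. the empty reporter
#'   vector).
#' @return Tibble of class `"luciferase_results"`: `construct_id`,
#'   `replicate`, `ratio`, `relative_activity`.
#' @export
relative_luciferase <- function(wells, control_id) {
  stopifnot(all(c("construct_id", "replicate", "renilla", "firefly") %in%
                  names(wells)))
  if (any(wells$renilla <= 0) || any(wells$firefly <= 0)) {
    abort("luciferase readings must be positive")
  }
  if (!control_id %in% wells$construct_id) {
    abort(paste0("control construct not present: ", control_id))
  }
  wells <- mutate(wells, ratio = .data$renilla / .data$firefly)
  ctl_mean <- mean(wells$ratio[wells$construct_id == control_id])
  out <- wells %>%
    mutate(relative_activity = .data$ratio / ctl_mean) %>%
    select("construct_id", "replicate", "ratio", "relative_activity")
  structure(out, class = c("luciferase_results", class(out)),
            control_id = control_id)
}

#' Two-sample unpaired t-test
#'
#' Student's pooled-variance two-tailed unpaired t-test, the comparison used
#' for reporter activities: `t = (mean(x) - mean(y)) / (s_p *
#' sqrt(1/n_x + 1/n_y))` with `df = n_x + n_y - 2`.  Welch's unequal-variance
#' form is available with `var_equal = FALSE`.
#'
#' @param x,y Numeric vectors with at least 2 observations each.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return Object of class `"polyte_ttest"`: a list with `statistic`, `df`,
#'   `p_value`, `estimate` (mean difference x - y), `n_x`, `n_y`, `method`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
unpaired_t_test <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("each group needs at least 2 observations")
  d <- mean(x) - mean(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    vx <- var(x) / nx; vy <- var(y) / ny
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  }
  tstat <- if (se == 0) 0 else d / se
  p <- if (se == 0) 1 else 2 * pt(-abs(tstat), df)
  structure(
    list(statistic = tstat, df = df, p_value = p, estimate = d,
         n_x = nx, n_y = ny,
         method = if (var_equal) "Student two-sample t-test"
                  else "Welch two-sample t-test"),
    class = "polyte_ttest"
  )
}

#' @export
print.polyte_ttest <- function(x, ...) {
  cat(sprintf("%s\nt = %.4f, df = %.4g, p = %.4g (two-sided)\n",
              x$method, x$statistic, x$df, x$p_value))
  cat(sprintf("mean difference (x - y) = %.4g, n = %d vs %d\n",
              x$estimate, x$n_x, x$n_y))
  invisible(x)
}

#' Test each construct against the control
#'
#' Runs [unpaired_t_test()] of every non-control construct's relative
#' activities against the control's.
#'
#' @param rel A [relative_luciferase()] result.
#' @param var_equal Passed to [unpaired_t_test()].
#' @return Tibble: `construct_id`, `mean_relative_activity`, `t`, `df`,
#'   `p_value`.
#' @export
reporter_tests <- function(rel, var_equal = TRUE) {
  control_id <- attr(rel, "control_id")
  ctl <- rel$relative_activity[rel$construct_id == control_id]
  rel %>%
    filter(.data$construct_id != control_id) %>%
    group_by(.data$construct_id) %>%
    summarise(
      mean_relative_activity = mean(.data$relative_activity),
      test = list(unpaired_t_test(.data$relative_activity, ctl,
                                  var_equal = var_equal)),
      .groups = "drop"
    ) %>%
    mutate(t = purrr::map_dbl(.data$test, "statistic"),
           df = purrr::map_dbl(.data$test, "df"),
           p_value = purrr::map_dbl(.data$test, "p_value")) %>%
    select(-"test")
}
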