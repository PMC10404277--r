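#' Spike-in size factors by median-of-ratios
#'
#' For each library, the size factor is the median over spike-in species of
#' `count / known input amount`, computed over spikes whose count passes
#' `min_count` in that library, then all factors are rescaled to geometric
#' mean 1 so they are comparable across runs.  The median makes the factor
#' robust to individual spike dropouts.  A library-total alternative
#' (`method = "library_total"`: factor proportional to the summed spike-in
#' counts) is available for comparison.
#'
#' @param counts Wide counts tibble (`feature_id`, `is_spikein`, one column
#'   per library), or a tibble already restricted to spike-in rows.
#' @param ref Spike-in reference tibble (`spike_id`, `input_amount`), e.g.
#'   [spikein_reference()].
#' @param min_count Minimum count for a spike-in to enter the per-library
#'   median (default 5; guards ratio stability at low depth).
#' @param method `"median_ratio"` (default) or `"library_total"`.
#' @return Tibble with `library_id`, `size_factor`; geometric mean of the
#'   factors is 1.
#' @export
#' @examples
#' ref <- spikein_reference(10)
#' counts <- tibble::tibble(
#'   feature_id = ref$spike_id, is_spikein = TRUE,
#'   libA = as.integer(round(100 * ref$input_amount)),
#'   libB = as.integer(round(200 * ref$input_amount))
#' )
#' compute_size_factors(counts, ref)  # ratio B/A = 2
compute_size_factors <- function(counts, ref, min_count = 5L,
                                 method = c("median_ratio", "library_total")) {
  method <- match.arg(method)
  stopifnot(all(c("spike_id", "input_amount") %in% names(ref)),
            all(ref$input_amount > 0))
  spikes <- if ("is_spikein" %in% names(counts)) {
    filter(counts, .data$is_spikein)
  } else {
    counts
  }
  lib_ids <- setdiff(names(spikes), c("feature_id", "is_spikein"))
  if (length(lib_ids) == 0) abort("no library columns in `counts`")
  amounts <- ref$input_amount[match(spikes$feature_id, ref$spike_id)]
  if (anyNA(amounts)) {
    abort(paste0("spike-in(s) missing from the reference: ",
                 paste(spikes$feature_id[is.na(amounts)], collapse = ", ")))
  }

  factors <- vapply(lib_ids, function(j) {
    cts <- spikes[[j]]
    keep <- cts >= min_count
    if (sum(keep) < 3) {
      abort(sprintf(
        "library %s has %d spike-in(s) with count >= %d (need >= 3)",
        j, sum(keep), min_count))
    }
    if (method == "median_ratio") {
      median(cts[keep] / amounts[keep])
    } else {
      sum(cts)
    }
  }, numeric(1))

  tibble(library_id = lib_ids,
         size_factor = unname(factors / exp(mean(log(factors)))))
}

#' Normalize a count matrix by size factors
#'
#' Divides every library column by its size factor.  Spike-in rows are
#' retained (still flagged by `is_spikein`) so their post-normalization
#' behaviour can be inspected.
#'
#' @param counts Wide counts tibble (`feature_id`, `is_spikein`, one column
#'   per library).
#' @param size_factors Tibble from [compute_size_factors()] (or any tibble
#'   with `library_id`, `size_factor`).
#' @return The counts tibble with real-valued, normalized library columns.
#' @export
normalize_counts <- function(counts, size_factors) {
  lib_ids <- setdiff(names(counts), c("feature_id", "is_spikein"))
  missing <- setdiff(lib_ids, size_factors$library_id)
  if (length(missing) > 0) {
    abort(paste0("no size factor for library: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(size_factors$size_factor <= 0)) abort("size factors must be positive")
  for (j in lib_ids) {
    f <- size_factors$size_factor[size_factors$library_id == j]
    counts[[j]] <- counts[[j]] / f
  }
  counts
}
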