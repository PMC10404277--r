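#' Select ribosome-protected fragments by length
#'
#' Keeps footprints whose length falls in the canonical monosome-protected
#' window, 28-32 nt by default (inclusive on both ends).
#'
#' @param reads RPF tibble (`transcript_id`, `start`, `length`).
#' @param min_len,max_len Inclusive length bounds.
#' @return The filtered tibble.
#' @export
filter_rpf_by_length <- function(reads, min_len = 28L, max_len = 32L) {
  stopifnot(min_len <= max_len)
  filter(reads, .data$length >= min_len, .data$length <= max_len)
}

#' Per-base relative ribosome occupancy of one transcript
#'
#' Accumulates the read density per base — every base covered by a footprint
#' gains one count (`mode = "coverage"`, the default), or only the 5' end
#' base does (`mode = "end5"`) — and normalizes by the total stacked count
#' over all positions, so the resulting densities sum to 1.
#'
#' @param reads RPF tibble for a single transcript.
#' @param transcript One-row transcripts tibble (`transcript_id` plus
#'   `sequence` or `length`).
#' @param mode Footprint-to-base assignment rule.
#' @return Tibble of class `"occupancy_profile"` with `transcript_id`,
#'   `pos` (0-based), `density`; attribute `empty` is `TRUE` (and densities
#'   all zero) when no read is present, attribute `total_raw` holds the
#'   pre-normalization mass (the summed read lengths in coverage mode).
#' @export
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1", sequence = "AUGAAA")
#' reads <- tibble::tibble(transcript_id = "t1", start = 0L, length = 3L)
#' occupancy_profile(reads, tx)
occupancy_profile <- function(reads, transcript,
                              mode = c("coverage", "end5")) {
  mode <- match.arg(mode)
  stopifnot(nrow(transcript) == 1)
  tlen <- if ("length" %in% names(transcript)) {
    as.integer(transcript$length)
  } else {
    nchar(transcript$sequence)
  }
  reads <- filter(reads, .data$transcript_id == transcript$transcript_id)
  if (nrow(reads) > 0 &&
      (any(reads$start < 0) || any(reads$start + reads$length > tlen) ||
       any(reads$length < 1))) {
    abort("read out of transcript bounds")
  }
  if (nrow(reads) == 0) {
    out <- tibble(transcript_id = transcript$transcript_id,
                  pos = seq_len(tlen) - 1L, density = 0)
    return(structure(out, class = c("occupancy_profile", class(out)),
                     empty = TRUE, total_raw = 0))
  }
  raw <- if (mode == "coverage") {
    cov <- IRanges::coverage(
      IRanges::IRanges(start = reads$start + 1L, width = reads$length),
      width = tlen)
    as.numeric(cov)
  } else {
    tabulate(reads$start + 1L, nbins = tlen)
  }
  total <- sum(raw)
  out <- tibble(transcript_id = transcript$transcript_id,
                pos = seq_len(tlen) - 1L, density = raw / total)
  structure(out, class = c("occupancy_profile", class(out)),
            empty = FALSE, total_raw = total)
}

#' Occupancy proportions over annotated regions
#'
#' Sums the relative occupancy over the bases of each labeled region.  The
#' proportions of a non-overlapping partition of the transcript sum to 1;
#' overlapping regions (e.g. an out-of-frame uORF running into the CDS) are
#' each summed independently, so shared bases count toward both.
#'
#' @param profile An [occupancy_profile()].
#' @param regions Tibble with `feature_id` (or `region`), `start`, `end`
#'   (0-based half-open); rows for other transcripts are ignored when a
#'   `transcript_id` column is present.
#' @return Tibble of class `"region_occupancy"`: `region`, `proportion`.
#' @export
region_occupancy <- function(profile, regions) {
  if (!"region" %in% names(regions)) {
    regions <- rename(regions, region = "feature_id")
  }
  if ("transcript_id" %in% names(regions)) {
    regions <- filter(regions,
                      .data$transcript_id == profile$transcript_id[1])
  }
  tlen <- nrow(profile)
  if (any(regions$start < 0 | regions$end > tlen)) {
    abort("region outside transcript bounds")
  }
  dens <- profile$density
  prop <- purrr::map2_dbl(regions$start, regions$end, function(s, e) {
    if (e <= s) {
      warn(sprintf("empty region [%d, %d); proportion set to 0", s, e))
      return(0)
    }
    sum(dens[(s + 1L):e])
  })
  out <- tibble(region = regions$region, proportion = prop)
  structure(out, class = c("region_occupancy", class(out)),
            empty = isTRUE(attr(profile, "empty")))
}

#' Compare region occupancy between two conditions
#'
#' Per-region difference and log2 ratio of occupancy proportions, e.g.
#' mutant minus control; a shift of ribosomes out of a repressive uORF into
#' the main CDS appears as `diff < 0` on the uORF and `diff > 0` on the CDS.
#'
#' @param a,b `region_occupancy` tibbles over the same region labels
#'   (`a` is the condition of interest, `b` the baseline).
#' @param epsilon Pseudo-proportion for the log2 ratio (default 1e-6).
#' @return Tibble of class `"occupancy_comparison"`: `region`,
#'   `proportion_a`, `proportion_b`, `diff`, `log2_ratio`.
#' @export
compare_occupancy <- function(a, b, epsilon = 1e-6) {
  if (isTRUE(attr(a, "empty")) || isTRUE(attr(b, "empty"))) {
    abort("cannot compare occupancy involving an empty (zero-read) profile")
  }
  if (!setequal(a$region, b$region) || anyDuplicated(a$region)) {
    abort("region labels must match between the two conditions")
  }
  b <- b[match(a$region, b$region), ]
  out <- tibble(
    region = a$region,
    proportion_a = a$proportion,
    proportion_b = b$proportion,
    diff = a$proportion - b$proportion,
    log2_ratio = log2((a$proportion + epsilon) / (b$proportion + epsilon))
  )
  structure(out, class = c("occupancy_comparison", class(out)))
}
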