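tx6 <- tibble::tibble(transcript_id = "t1", sequence = "AUGAAA")

test_that("length filtering is inclusive on both bounds", {
  reads <- tibble::tibble(transcript_id = "t1", start = 0L,
                          length = c(27L, 28L, 30L, 32L, 33L))
  kept <- filter_rpf_by_length(reads)
  expect_equal(kept$length, c(28L, 30L, 32L))
  expect_equal(nrow(filter_rpf_by_length(reads[0, ])), 0)
})

test_that("a single length window keeps the expected share of uniform reads", {
  withr::with_seed(5, {
    reads <- tibble::tibble(transcript_id = "t1", start = 0L,
                            length = sample(25:35, 11000, replace = TRUE))
  })
  kept <- filter_rpf_by_length(reads, 30, 30)
  expect_lt(abs(nrow(kept) - 1000), 3 * sqrt(11000 * (1 / 11) * (10 / 11)))
})

test_that("occupancy profiles match hand-computed coverage", {
  one <- tibble::tibble(transcript_id = "t1", start = 0L, length = 3L)
  p1 <- occupancy_profile(one, tx6)
  expect_equal(p1$density, c(1, 1, 1, 0, 0, 0) / 3)

  two <- tibble::tibble(transcript_id = "t1", start = c(0L, 2L),
                        length = c(3L, 3L))
  p2 <- occupancy_profile(two, tx6)
  expect_equal(p2$density, c(1, 1, 2, 1, 1, 0) / 6)
  expect_equal(attr(p2, "total_raw"), 6)  # sum of read lengths

  expect_error(occupancy_profile(
    tibble::tibble(transcript_id = "t1", start = 4L, length = 3L), tx6),
    "out of transcript bounds")
})

test_that("profiles are unit mass, permutation invariant and mixable", {
  tx <- generate_transcriptome(1, seed = 8)
  tr <- tx$transcripts[1, ]
  reads <- generate_rpf_reads(tr, tx$features,
                              c(five_prime_UTR = 0.3, CDS = 0.7), 2000,
                              seed = 3)
  p <- occupancy_profile(reads, tr)
  expect_lt(abs(sum(p$density) - 1), 1e-12)
  expect_equal(attr(p, "total_raw"), sum(reads$length))

  shuffled <- reads[rev(seq_len(nrow(reads))), ]
  expect_equal(occupancy_profile(shuffled, tr)$density, p$density)

  # mixing subset profiles with raw-mass weights reproduces the pooled one
  a <- occupancy_profile(reads[1:700, ], tr)
  b <- occupancy_profile(reads[701:2000, ], tr)
  wa <- attr(a, "total_raw") / (attr(a, "total_raw") + attr(b, "total_raw"))
  expect_equal(wa * a$density + (1 - wa) * b$density, p$density,
               tolerance = 1e-12)

  # naive per-base loop oracle
  raw <- oracle_coverage(reads$start, reads$length, nchar(tr$sequence))
  expect_equal(p$density, raw / sum(raw))
})

test_that("zero-read profiles are flagged empty and excluded from comparison", {
  p <- occupancy_profile(tibble::tibble(transcript_id = "t1",
                                        start = integer(), length = integer()),
                         tx6)
  expect_true(attr(p, "empty"))
  expect_equal(sum(p$density), 0)
  ro <- suppressWarnings(region_occupancy(
    p, tibble::tibble(region = "CDS", start = 0L, end = 6L)))
  expect_error(compare_occupancy(ro, ro), "empty")
})

test_that("region proportions sum over bases and partitions conserve mass", {
  reads <- tibble::tibble(transcript_id = "t1", start = c(0L, 2L),
                          length = c(3L, 3L))
  p <- occupancy_profile(reads, tx6)
  half <- region_occupancy(p, tibble::tibble(region = "left",
                                             start = 0L, end = 3L))
  expect_equal(half$proportion, 4 / 6)
  part <- region_occupancy(p, tibble::tibble(
    region = c("a", "b", "c"), start = c(0L, 2L, 4L), end = c(2L, 4L, 6L)))
  expect_equal(sum(part$proportion), 1)
  expect_warning(region_occupancy(
    p, tibble::tibble(region = "nil", start = 3L, end = 3L)), "empty region")
  expect_error(region_occupancy(
    p, tibble::tibble(region = "far", start = 0L, end = 9L)), "bounds")
})

test_that("uniform occupancy gives proportions equal to region width share", {
  tr <- tibble::tibble(transcript_id = "t1", length = 100L)
  reads <- tibble::tibble(transcript_id = "t1", start = 0:99, length = 1L)
  p <- occupancy_profile(reads, tr)
  ro <- region_occupancy(p, tibble::tibble(region = "half",
                                           start = 0L, end = 50L))
  expect_equal(ro$proportion, 0.5)
})

test_that("occupancy comparisons are differences and log ratios per region", {
  a <- structure(tibble::tibble(region = c("uORF2", "CDS"),
                                proportion = c(0.1, 0.7)),
                 class = c("region_occupancy", "tbl_df", "tbl", "data.frame"))
  b <- structure(tibble::tibble(region = c("CDS", "uORF2"),
                                proportion = c(0.5, 0.2)),
                 class = c("region_occupancy", "tbl_df", "tbl", "data.frame"))
  cmp <- compare_occupancy(a, b)
  expect_equal(cmp$diff[cmp$region == "uORF2"], -0.1)
  expect_equal(cmp$diff[cmp$region == "CDS"], 0.2)
  same <- compare_occupancy(a, a)
  expect_equal(same$diff, c(0, 0))
  expect_equal(same$log2_ratio, c(0, 0))
  bad <- structure(tibble::tibble(region = "CDS", proportion = 1),
                   class = class(a))
  expect_error(compare_occupancy(a, bad), "labels")
})

test_that("a planted uORF2-to-CDS shift shows the expected sign pattern", {
  tx <- synthetic_uorf_transcript(seed = 12)
  tr <- tx$transcripts[1, ]
  regions <- dplyr::filter(tx$features, feature_id %in% c("uORF2", "CDS"))
  occ_for <- function(w, seed) {
    generate_rpf_reads(tr, tx$features, w, 2000, seed = seed) |>
      filter_rpf_by_length() |>
      occupancy_profile(tr) |>
      region_occupancy(regions)
  }
  ctl <- occ_for(c(uORF2 = 0.5, CDS = 0.5), seed = 1)
  mut <- occ_for(c(uORF2 = 0.2, CDS = 0.8), seed = 2)
  cmp <- compare_occupancy(mut, ctl)
  expect_lt(cmp$diff[cmp$region == "uORF2"], 0)
  expect_gt(cmp$diff[cmp$region == "CDS"], 0)
})

test_that("5'-end counting mode assigns mass to read starts only", {
  reads <- tibble::tibble(transcript_id = "t1", start = c(0L, 0L, 2L),
                          length = c(3L, 3L, 3L))
  p <- occupancy_profile(reads, tx6, mode = "end5")
  expect_equal(p$density, c(2, 0, 1, 0, 0, 0) / 3)
})
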