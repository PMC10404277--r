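genes <- sprintf("g%03d", 1:40)

test_that("noise-free counts equal the rounded closed-form means", {
  des <- simulation_design(dispersion = 0, mean_depth = 300,
                           te_effects = c(g005 = 2, g006 = -1),
                           rna_effects = c(g007 = 1), seed = 2)
  ref <- spikein_reference(12)
  em <- expected_fraction_means(genes, des, ref)
  fc <- generate_fraction_counts(genes, des, ref)
  for (j in em$design_tbl$library_id) {
    expect_equal(fc$counts[[j]], as.integer(round(em$mu[[j]])))
  }
  # planted TE split: polysome x2, monosome x0.5 in the mutant for g005
  mu <- em$mu
  i <- match("g005", mu$feature_id)
  expect_equal(mu$mutant_polysome_rep1[i] / mu$control_polysome_rep1[i], 2)
  expect_equal(mu$mutant_monosome_rep1[i] / mu$control_monosome_rep1[i], 0.5)
  # rna effect moves all fractions
  i7 <- match("g007", mu$feature_id)
  expect_equal(mu$mutant_total_rep1[i7] / mu$control_total_rep1[i7], 2)
})

test_that("spike-in means scale with library factors, independent of genotype", {
  lib <- library_design(simulation_design(fractions = "total"))
  sf <- setNames(c(1, 2, 1, 2), lib$library_id)
  des <- simulation_design(fractions = "total", dispersion = 0,
                           library_scale_factors = sf, seed = 3)
  # integer amounts + unit spike scale => expected means are exact integers
  ref <- spikein_reference(5, log2_amount_range = c(2, 6))
  fc <- generate_fraction_counts(genes, des, ref, spike_scale = 1)
  sp <- dplyr::filter(fc$counts, is_spikein)
  expect_equal(sp$control_total_rep2 / sp$control_total_rep1,
               rep(2, nrow(sp)))
  # mutant spikes identical to control spikes at equal scale
  expect_equal(sp$mutant_total_rep1, sp$control_total_rep1)
})

test_that("counts are deterministic under the design seed", {
  des <- simulation_design(dispersion = 0.1, seed = 77)
  a <- generate_fraction_counts(genes, des, spikein_reference(10))
  b <- generate_fraction_counts(genes, des, spikein_reference(10))
  expect_identical(a$counts, b$counts)
})

test_that("NB noise reproduces the quadratic mean-variance law", {
  many <- simulation_design(genotypes = c("control", "mutant"),
                            fractions = "total", replicates = 200L,
                            mean_depth = 400, dispersion = 0.1, seed = 8)
  fc <- generate_fraction_counts(genes[1:30], many)
  libs <- fc$design$library_id[fc$design$genotype == "control"]
  mat <- as.matrix(fc$counts[, libs])
  m <- rowMeans(mat)
  v <- apply(mat, 1, var)
  alpha_hat <- sum(v - m) / sum(m^2)
  expect_lt(abs(alpha_hat - 0.1), 0.02)
})

test_that("degenerate designs are rejected", {
  expect_error(simulation_design(mean_depth = 0), "positive")
  expect_error(simulation_design(dispersion = -1))
  expect_error(simulation_design(library_scale_factors = c(a = -1)))
})

test_that("RPF reads respect region weights, lengths and determinism", {
  tx <- generate_transcriptome(
    1, uorf_spec = tibble::tibble(gene_id = "gene0001",
                                  kind = "overlapping_out_of_frame"),
    seed = 4)
  tr <- tx$transcripts[1, ]
  cds <- dplyr::filter(tx$features, feature_id == "CDS")

  r <- generate_rpf_reads(tr, tx$features, c(CDS = 1), 500, seed = 1)
  expect_true(all(r$start >= cds$start & r$start < cds$end))
  expect_true(all(r$start + r$length <= nchar(tr$sequence)))
  expect_true(all(r$length %in% 25:35))

  expect_equal(nrow(generate_rpf_reads(tr, tx$features, c(CDS = 1), 0)), 0)

  # disjoint regions so start membership is unambiguous
  r2 <- generate_rpf_reads(tr, tx$features,
                           c(five_prime_UTR = 0.8, three_prime_UTR = 0.2),
                           10000, seed = 2)
  utr5 <- dplyr::filter(tx$features, feature_id == "five_prime_UTR")
  frac <- mean(r2$start >= utr5$start & r2$start < utr5$end)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))

  expect_identical(generate_rpf_reads(tr, tx$features, c(CDS = 1), 50, seed = 9),
                   generate_rpf_reads(tr, tx$features, c(CDS = 1), 50, seed = 9))
})

test_that("regions shorter than the minimum read length are rejected", {
  tr <- tibble::tibble(transcript_id = "t1",
                       sequence = strrep("ACGU", 40))
  feats <- tibble::tibble(transcript_id = "t1",
                          feature = "uORF", feature_id = "uORF1",
                          start = 10L, end = 16L)
  expect_error(generate_rpf_reads(tr, feats, c(uORF1 = 1), 10),
               "shorter than the minimum")
})

test_that("simulated luciferase wells carry the planted activities", {
  acts <- c(NC = 1, wt = 2.5)
  wells <- generate_luciferase_table(acts, n_replicates = 200, cv = 0.05,
                                     seed = 6)
  rel <- relative_luciferase(wells, "NC")
  m <- tapply(rel$relative_activity, rel$construct_id, mean)
  expect_lt(abs(m[["wt"]] - 2.5) / 2.5, 0.05)
})
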