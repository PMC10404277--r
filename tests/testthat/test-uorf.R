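test_that("find_uorfs resolves the worked contained-uORF case", {
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = "AAAUGGCUUAAGGAUGCCCUAACCC",
                       cds_start = 13L, cds_end = 22L)
  u <- find_uorfs(tx)
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 2L)
  expect_equal(u$stop_end, 11L)      # AUG GCU UAA
  expect_equal(u$n_codons, 3L)
  expect_equal(u$overlap_class, "contained_in_utr")
})

test_that("find_uorfs handles no-AUG UTRs and out-of-frame overlap", {
  no_aug <- tibble::tibble(transcript_id = "t1",
                           sequence = "CCCCCCCCCAUGAAAUAG",
                           cds_start = 9L, cds_end = 18L)
  expect_equal(nrow(find_uorfs(no_aug)), 0)

  # AUG at position 2 (cds_start 9): frame 2, walk AUG CCC CAU GAA UGA,
  # first in-frame stop (UGA) inside the CDS
  over <- tibble::tibble(
    transcript_id = "t1",
    sequence = "CCAUGCCCCAUGAAUGAACC",
    cds_start = 9L, cds_end = 18L)
  u <- find_uorfs(over)
  expect_equal(u$start, 2L)
  expect_equal(u$frame_vs_cds, (2L - 9L) %% 3L)  # = 2
  expect_equal(u$overlap_class, "overlapping_out_of_frame")
  expect_equal(u$stop_end, 17L)
  expect_equal(u$n_codons, 5L)
  expect_gt(u$stop_end, over$cds_start)
})

test_that("uORFs without an in-frame stop are reported with the sentinel", {
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = "CAUGCCCCCAUGCCCCCCUUU",
                       cds_start = 9L, cds_end = 18L)
  u <- find_uorfs(tx)
  expect_equal(u$start, 1L)
  expect_true(is.na(u$stop_end))
  expect_equal(u$overlap_class, "overlapping_out_of_frame")
})

test_that("DNA input is transcribed on the fly", {
  rna <- tibble::tibble(transcript_id = "t1",
                        sequence = "AAAUGGCUUAAGGAUGCCCUAACCC",
                        cds_start = 13L, cds_end = 22L)
  dna <- dplyr::mutate(rna, sequence = chartr("U", "T", sequence))
  expect_equal(find_uorfs(dna), find_uorfs(rna))
})

test_that("find_uorfs agrees with the brute-force oracle on random transcripts", {
  tx <- random_raw_transcripts(300, seed = 5)
  u <- find_uorfs(tx)
  for (i in seq_len(nrow(tx))) {
    got <- u[u$transcript_id == tx$transcript_id[i], ]
    want <- oracle_find_uorfs(tx$sequence[i], tx$cds_start[i])
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$stop_end, want$stop_end)
      expect_equal(got$n_codons, want$n_codons)
      expect_equal(got$frame_vs_cds, want$frame_vs_cds)
      expect_equal(got$overlap_class, want$overlap_class)
    }
  }
})

test_that("mutating a start codon removes exactly that uORF and adds none", {
  spec <- tibble::tibble(gene_id = c("gene0001", "gene0001"),
                         kind = c("contained", "overlapping_out_of_frame"))
  tx <- generate_transcriptome(3, uorf_spec = spec, seed = 31)
  u <- find_uorfs(tx$transcripts)
  u2 <- u[u$overlap_class == "overlapping_out_of_frame", ][1, ]
  mut <- mutate_start_codon(tx$transcripts, u2, "UAA")
  after <- find_uorfs(mut)
  expect_equal(nrow(after), nrow(u) - 1)
  expect_false(u2$start %in% after$start[after$transcript_id ==
                                           u2$transcript_id])
  # remaining uORF is untouched
  u1 <- u[u$overlap_class == "contained_in_utr", ]
  expect_true(u1$start %in% after$start)
  # any new start could only sit at the edit boundary; none elsewhere
  new_starts <- setdiff(after$start[after$transcript_id == u2$transcript_id],
                        u$start)
  expect_true(all(abs(new_starts - u2$start) <= 2))
  # CDS coordinates unchanged
  expect_identical(mut$cds_start, tx$transcripts$cds_start)
})

test_that("mutate_start_codon refuses non-AUG positions", {
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = "AAAUGGCUUAAGGAUGCCCUAACCC",
                       cds_start = 13L, cds_end = 22L)
  expect_error(
    mutate_start_codon(tx, list(transcript_id = "t1", start = 0L), "GGG"),
    "not an AUG")
})

test_that("frameshift translation matches hand-derived outcomes", {
  out <- apply_indel_and_translate("AUGAAACUAGGG", pos = 3, del_len = 1)
  expect_equal(out$protein, "MN")
  expect_equal(out$stop_codon_index, 3L)

  # in-frame deletion of one whole codon keeps the original stop codon
  orig <- translate_rna("AUGAAACCCUAG")
  inframe <- apply_indel_and_translate("AUGAAACCCUAG", pos = 3, del_len = 3)
  expect_equal(inframe$stop_codon_index, orig$stop_codon_index - 1L)
  expect_equal(inframe$protein, "MP")

  # zero-length deletion is plain translation
  expect_equal(apply_indel_and_translate("AUGAAACUAGGG", 5, 0)$protein,
               translate_rna("AUGAAACUAGGG")$protein)

  expect_error(apply_indel_and_translate("AUGAAACUAGGG", 1, 2),
               "initiator")
  expect_error(apply_indel_and_translate("AUGAAA", 5, 3), "out of bounds")
})

test_that("translation agrees with an independent codon table", {
  skip_if_not_installed("seqinr")
  withr::with_seed(17, {
    for (k in 1:50) {
      s <- paste0("AUG", paste(sample(c("A", "C", "G", "U"),
                                      3 * sample(5:30, 1), TRUE),
                               collapse = ""))
      got <- translate_rna(s)
      want <- oracle_translate(s)
      expect_equal(got$protein, want$protein)
      expect_equal(got$stop_codon_index, want$stop_codon_index)
    }
  })
})

test_that("in-frame deletions preserve downstream reading frames", {
  tx <- random_raw_transcripts(20, seed = 9)
  for (i in seq_len(nrow(tx))) {
    u_before <- find_uorfs(tx[i, , drop = FALSE])
    cds <- substr(tx$sequence[i], tx$cds_start[i] + 1, tx$cds_end[i])
    res <- apply_indel_and_translate(cds, pos = 6, del_len = 3)
    # frame preserved: every codon boundary after the deletion shifts by one
    # whole codon, so the mutant protein is the original minus one residue
    orig <- translate_rna(cds)
    expect_equal(nchar(res$protein), nchar(orig$protein) - 1L)
    expect_equal(substr(res$protein, 1, 2), substr(orig$protein, 1, 2))
    invisible(u_before)
  }
})
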