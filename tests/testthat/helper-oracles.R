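# Independent brute-force oracles. These deliberately avoid the package's
# code paths (stringr scans, Biostrings tables, IRanges coverage): plain
# substr loops and hand-typed stop codons only.

oracle_stops <- c("UAA", "UAG", "UGA")

oracle_find_uorfs <- function(sequence, cds_start) {
  len <- nchar(sequence)
  out <- list()
  for (i in seq_len(cds_start) - 1L) {        # candidate starts 0..cds_start-1
    if (substr(sequence, i + 1, i + 3) != "AUG") next
    stop_end <- NA_integer_
    n_codons <- 0L
    j <- i
    while (j + 3 <= len) {
      n_codons <- n_codons + 1L
      if (substr(sequence, j + 1, j + 3) %in% oracle_stops) {
        stop_end <- j + 3L
        break
      }
      j <- j + 3L
    }
    frame <- (i - cds_start) %% 3L
    class <- if (!is.na(stop_end) && stop_end <= cds_start) {
      "contained_in_utr"
    } else if (frame != 0L) {
      "overlapping_out_of_frame"
    } else {
      "overlapping_in_frame"
    }
    out[[length(out) + 1L]] <- data.frame(
      start = i, stop_end = stop_end, n_codons = n_codons,
      frame_vs_cds = frame, overlap_class = class,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), stop_end = integer(),
                      n_codons = integer(), frame_vs_cds = integer(),
                      overlap_class = character()))
  }
  do.call(rbind, out)
}

# Naive translation via seqinr (independent codon table); returns the
# protein before the first stop and the 1-based stop codon index (NA if no
# stop within the sequence).
oracle_translate <- function(sequence) {
  dna <- seqinr::s2c(chartr("U", "T", sequence))
  n_codons <- length(dna) %/% 3
  if (n_codons == 0) return(list(protein = "", stop_codon_index = NA_integer_))
  aa <- seqinr::translate(dna[1:(3 * n_codons)])
  i <- match("*", aa)
  if (is.na(i)) {
    list(protein = paste(aa, collapse = ""), stop_codon_index = NA_integer_)
  } else {
    list(protein = paste(aa[seq_len(i - 1)], collapse = ""),
         stop_codon_index = i)
  }
}

# Per-base coverage by an explicit loop over reads and bases.
oracle_coverage <- function(starts, lengths, tlen) {
  raw <- numeric(tlen)
  for (k in seq_along(starts)) {
    for (b in seq(starts[k] + 1, starts[k] + lengths[k])) {
      raw[b] <- raw[b] + 1
    }
  }
  raw
}

# Random transcripts with unmasked 5'UTRs (accidental AUGs welcome), for
# oracle-equivalence scans.
random_raw_transcripts <- function(n, seed) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      utr5 <- sample(30:80, 1)
      codons <- sample(20:60, 1)
      utr3 <- sample(10:40, 1)
      bases <- function(k) paste(sample(c("A", "C", "G", "U"), k, TRUE),
                                 collapse = "")
      body <- paste(replicate(codons - 2, {
        repeat {
          cod <- bases(3)
          if (!cod %in% c("UAA", "UAG", "UGA")) break
        }
        cod
      }), collapse = "")
      data.frame(
        transcript_id = sprintf("rt%04d", i),
        gene_id = sprintf("rt%04d", i),
        sequence = paste0(bases(utr5), "AUG", body,
                          sample(c("UAA", "UAG", "UGA"), 1), bases(utr3)),
        cds_start = utr5,
        cds_end = utr5 + 3L * codons,
        stringsAsFactors = FALSE)
    }))
  })
}
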