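#' Write a simulated transcriptome to FASTA, GFF3 and BED-like TSV
#'
#' FASTA holds the RNA sequences; GFF3 carries the region annotation in
#' 1-based inclusive coordinates (feature types `five_prime_UTR`, `CDS`,
#' `three_prime_UTR`, `uORF`); the TSV mirror keeps the internal 0-based
#' half-open convention for diff-stable downstream use.
#'
#' @param tx A `"transcriptome"` (list with `transcripts` and `features`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_transcriptome <- function(tx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "transcripts.fa")
  gff <- file.path(dir, "features.gff3")
  bed <- file.path(dir, "features.tsv")

  seqs <- Biostrings::RNAStringSet(setNames(tx$transcripts$sequence,
                                            tx$transcripts$transcript_id))
  Biostrings::writeXStringSet(seqs, fa)

  gr <- GenomicRanges::GRanges(
    seqnames = tx$features$transcript_id,
    ranges = IRanges::IRanges(start = tx$features$start + 1L,
                              end = tx$features$end),
    type = tx$features$feature,
    ID = paste0(tx$features$transcript_id, ":", tx$features$feature_id),
    phase = ifelse(tx$features$feature == "CDS", 0L, NA_integer_)
  )
  GenomeInfoDb::seqlengths(gr) <-
    setNames(nchar(tx$transcripts$sequence),
             tx$transcripts$transcript_id)[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, gff, format = "gff3")

  readr::write_tsv(tx$features, bed)
  invisible(c(fasta = fa, gff3 = gff, tsv = bed))
}

#' Read a transcriptome from FASTA + GFF3
#'
#' Inverse of [write_transcriptome()]: rebuilds the transcripts tibble
#' (CDS coordinates taken from the `CDS` features, converted back to 0-based
#' half-open) and the full feature table.  DNA FASTA input is transcribed
#' to RNA.
#'
#' @param fasta,gff3 Paths written by [write_transcriptome()] (or compatible
#'   transcript-space files).
#' @return A list of class `"transcriptome"`.
#' @export
read_transcriptome <- function(fasta, gff3) {
  seqs <- Biostrings::readBStringSet(fasta)
  sequence <- chartr("Tt", "Uu", toupper(as.character(seqs)))
  gr <- rtracklayer::import(gff3, format = "gff3")
  feats <- tibble(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    feature = as.character(gr$type),
    feature_id = sub("^[^:]*:", "", gr$ID %||% as.character(gr$type)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  cds <- filter(feats, .data$feature == "CDS")
  transcripts <- tibble(
    transcript_id = names(sequence),
    gene_id = sub("\\.t\\d+$", "", names(sequence)),
    sequence = unname(sequence)
  ) %>%
    left_join(select(cds, "transcript_id",
                     cds_start = "start", cds_end = "end"),
              by = "transcript_id")
  structure(list(transcripts = transcripts, features = feats),
            class = "transcriptome")
}

#' Read and write count matrices as TSV
#'
#' The wide layout is `feature_id`, `is_spikein`, then one integer column
#' per library.  `read_counts_tsv()` validates every cell and names the
#' file, row and column of the first non-integer or negative entry.
#'
#' @param counts Wide counts tibble.
#' @param path TSV path.
#' @return `write_counts_tsv()`: the path, invisibly; `read_counts_tsv()`:
#'   the counts tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param integer_counts Require integer cells (disable to read normalized
#'   matrices).
#' @export
read_counts_tsv <- function(path, integer_counts = TRUE) {
  counts <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE)
  if (!all(c("feature_id", "is_spikein") %in% names(counts))) {
    abort(paste0(path, ": expected columns feature_id and is_spikein"))
  }
  lib_ids <- setdiff(names(counts), c("feature_id", "is_spikein"))
  for (j in lib_ids) {
    v <- counts[[j]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v) | v < 0 |
                   (integer_counts & v != floor(v)))[1]
    if (!is.na(bad)) {
      abort(sprintf("%s: invalid count at row %d (feature %s), column %s",
                    path, bad, counts$feature_id[bad], j))
    }
    if (integer_counts) counts[[j]] <- as.integer(v)
  }
  counts
}

#' Read and write RPF alignment records as TSV
#'
#' Three columns: `transcript_id`, `start` (0-based), `length` (nt).
#'
#' @param reads RPF tibble.
#' @param path TSV path.
#' @export
write_rpf_tsv <- function(reads, path) {
  readr::write_tsv(reads[, c("transcript_id", "start", "length")], path)
  invisible(path)
}

#' @rdname write_rpf_tsv
#' @export
read_rpf_tsv <- function(path) {
  reads <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             transcript_id = readr::col_character(),
                             start = readr::col_integer(),
                             length = readr::col_integer()))
  if (any(reads$start < 0) || any(reads$length < 1)) {
    abort(paste0(path, ": RPF records must have start >= 0 and length >= 1"))
  }
  reads
}

#' Export RPF records as transcript-space SAM
#'
#' Writes a minimal single-end SAM: one `@SQ` line per transcript and one
#' alignment per footprint (`<length>M` CIGAR, MAPQ 255).  When `transcripts`
#' is given, the SEQ field carries the footprint sequence; otherwise `*`.
#'
#' @param reads RPF tibble.
#' @param path Output SAM path.
#' @param transcripts Optional transcripts tibble with `sequence` (used for
#'   `@SQ` lengths and SEQ fields); otherwise lengths are inferred from the
#'   reads.
#' @export
write_rpf_sam <- function(reads, path, transcripts = NULL) {
  if (!is.null(transcripts)) {
    lens <- setNames(nchar(transcripts$sequence), transcripts$transcript_id)
  } else {
    lens <- tapply(reads$start + reads$length, reads$transcript_id, max)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (tid in names(lens)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tid, as.integer(lens[[tid]])), con)
  }
  if (nrow(reads) > 0) {
    seq_field <- if (!is.null(transcripts)) {
      full <- setNames(chartr("Uu", "Tt", transcripts$sequence),
                       transcripts$transcript_id)
      substr(full[reads$transcript_id], reads$start + 1L,
             reads$start + reads$length)
    } else {
      rep("*", nrow(reads))
    }
    writeLines(sprintf("rpf%06d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       seq_len(nrow(reads)), reads$transcript_id,
                       reads$start + 1L, reads$length, seq_field), con)
  }
  invisible(path)
}

#' Import transcript-space RPF records from SAM
#'
#' Converts the SAM to BAM with Rsamtools and extracts (transcript, start,
#' length); the reference span is taken from the CIGAR (M/D/N/=/X ops), so
#' records written by [write_rpf_sam()] round-trip exactly.
#'
#' @param path SAM file path.
#' @return RPF tibble (`transcript_id`, `start`, `length`).
#' @export
read_rpf_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("SAM import needs the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("rname", "pos", "cigar")))[[1]]
  keep <- !is.na(rec$pos)
  tibble(
    transcript_id = as.character(rec$rname)[keep],
    start = rec$pos[keep] - 1L,
    length = cigar_ref_width(rec$cigar[keep])
  )
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(c) {
    ops <- regmatches(c, gregexpr("\\d+[MIDNSHP=X]", c))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read and write small analysis tables as TSV
#'
#' Thin wrappers with a stable column order, used by the pipeline for size
#' factors, library designs, spike-in references and luciferase plates.
#'
#' @param x Tibble to write.
#' @param path TSV path.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
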