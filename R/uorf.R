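#' Discover upstream open reading frames in 5'UTRs
#'
#' Scans each transcript's 5'UTR for AUG codons and walks each candidate in
#' triplets to its first in-frame stop (UAA/UAG/UGA), continuing past the
#' main-CDS start where necessary.  Each uORF is classified by its relation
#' to the main ORF: fully `contained_in_utr`, or overlapping the CDS either
#' `overlapping_out_of_frame` (shifted frame, the *Xrp1*-uORF2 configuration)
#' or `overlapping_in_frame` (an N-terminal extension).
#'
#' Only AUG starts are considered; near-cognate starts (CUG/GUG) can be
#' enabled with `near_cognate = TRUE`.  A uORF reaching the transcript end
#' without an in-frame stop is reported with `stop_end = NA` rather than
#' dropped.  `T` in input sequences is transcribed to `U` on the fly.
#'
#' @param transcripts Tibble with columns `transcript_id`, `sequence`,
#'   `cds_start` (and optionally `cds_end`); coordinates 0-based half-open.
#' @param near_cognate Also accept CUG and GUG start codons.
#' @return Tibble with one row per uORF: `transcript_id`, `start` (0-based
#'   position of the A of the start codon), `stop_end` (exclusive end of the
#'   stop codon; `NA` if no in-frame stop before the transcript end),
#'   `n_codons` (including the stop when present), `frame_vs_cds`
#'   (`(start - cds_start) mod 3`), `overlap_class`.  Rows are sorted by
#'   transcript and start.
#' @export
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1",
#'                      sequence = "AAAUGGCUUAAGGAUGCCCUAACCC",
#'                      cds_start = 13L, cds_end = 22L)
#' find_uorfs(tx)
find_uorfs <- function(transcripts, near_cognate = FALSE) {
  validate_transcripts_light(transcripts)
  starts_pat <- if (near_cognate) c("AUG", "CUG", "GUG") else "AUG"
  purrr::pmap(
    list(transcripts$transcript_id, transcripts$sequence, transcripts$cds_start),
    function(tid, seq, cds_start) {
      seq <- chartr("Tt", "Uu", toupper(seq))
      hits <- sort(unlist(lapply(starts_pat, function(p) {
        m <- stringr::str_locate_all(seq, stringr::fixed(p))[[1]]
        as.integer(m[, 1] - 1L)
      })))
      hits <- hits[hits < cds_start]
      if (length(hits) == 0) return(NULL)
      orf <- purrr::map(hits, ~ walk_orf(seq, .x))
      tibble(
        transcript_id = tid,
        start = hits,
        stop_end = purrr::map_int(orf, "stop_end"),
        n_codons = purrr::map_int(orf, "n_codons"),
        frame_vs_cds = (hits - cds_start) %% 3L
      ) %>%
        mutate(overlap_class = dplyr::case_when(
          !is.na(.data$stop_end) & .data$stop_end <= cds_start ~ "contained_in_utr",
          .data$frame_vs_cds != 0L ~ "overlapping_out_of_frame",
          TRUE ~ "overlapping_in_frame"
        ))
    }
  ) %>%
    purrr::compact() %>%
    bind_rows() %>%
    empty_uorf_tbl_if_null()
}

empty_uorf_tbl_if_null <- function(x) {
  if (nrow(x) > 0) return(x)
  tibble(transcript_id = character(), start = integer(),
         stop_end = integer(), n_codons = integer(),
         frame_vs_cds = integer(), overlap_class = character())
}

# Triplet walk from `start` to the first stop codon or the transcript end.
# Vectorized: extract all complete codons at once and locate the first stop.
walk_orf <- function(seq, start) {
  len <- nchar(seq)
  if (start > len - 3L) return(list(stop_end = NA_integer_, n_codons = 0L))
  pos <- seq.int(start, len - 3L, by = 3L)
  codons <- substring(seq, pos + 1L, pos + 3L)
  i <- which(codons %in% the$stop_codons)[1]
  if (is.na(i)) {
    list(stop_end = NA_integer_, n_codons = length(codons))
  } else {
    list(stop_end = as.integer(pos[i] + 3L), n_codons = i)
  }
}

validate_transcripts_light <- function(transcripts) {
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "sequence", "cds_start") %in%
                  names(transcripts)))
  invisible(transcripts)
}

#' Mutate a uORF start codon
#'
#' Replaces the three bases of a uORF start codon (default with the stop
#' codon UAA, mirroring a uORF2^UAA reporter construct), leaving CDS
#' coordinates untouched.  Re-running [find_uorfs()] on the result no longer
#' reports a uORF at that position.
#'
#' @param transcripts Transcripts tibble (see [find_uorfs()]).
#' @param uorf One-row data frame with `transcript_id` and `start` (a row of
#'   [find_uorfs()] output), or a list with those fields.
#' @param replacement Three-base RNA codon to write in place of the AUG.
#'   Note that even a G-free replacement such as UAA cannot rule out a new
#'   start at the edit boundary: its trailing `A` may combine with a
#'   downstream `UG` (`AUGUG...` becomes `UAAUG...`), so callers needing
#'   strict closure should re-run [find_uorfs()] on the result.
#' @return The transcripts tibble with the edited sequence.
#' @export
mutate_start_codon <- function(transcripts, uorf, replacement = "UAA") {
  stopifnot(nchar(replacement) == 3,
            grepl("^[ACGU]{3}$", replacement))
  uorf <- as.list(as.data.frame(uorf)[1, , drop = FALSE])
  i <- match(uorf$transcript_id, transcripts$transcript_id)
  if (is.na(i)) abort(paste0("unknown transcript: ", uorf$transcript_id))
  s <- transcripts$sequence[i]
  p <- as.integer(uorf$start)
  if (substr(s, p + 1L, p + 3L) != "AUG") {
    abort(sprintf("position %d of %s is not an AUG (found %s)",
                  p, uorf$transcript_id, substr(s, p + 1L, p + 3L)))
  }
  substr(s, p + 1L, p + 3L) <- replacement
  transcripts$sequence[i] <- s
  transcripts
}

#' Translate an RNA sequence from its first base
#'
#' Walks the sequence in triplets from position 0 using the standard genetic
#' code and stops at the first stop codon (or the last complete codon).
#'
#' @param seq RNA (or DNA; `T` is converted) character scalar.
#' @return One-row tibble: `protein` (amino acids before the first stop) and
#'   `stop_codon_index` (1-based codon index of the first stop; `NA` when no
#'   stop occurs within the sequence).
#' @export
translate_rna <- function(seq) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  if (!grepl("^[ACGU]*$", seq)) abort("sequence contains non-ACGU(T) characters")
  len <- nchar(seq)
  if (len < 3L) return(tibble(protein = "", stop_codon_index = NA_integer_))
  pos <- seq.int(0L, len - 3L, by = 3L)
  codons <- substring(seq, pos + 1L, pos + 3L)
  aa <- unname(the$genetic_code[codons])
  i <- match("*", aa)
  if (is.na(i)) {
    tibble(protein = paste(aa, collapse = ""), stop_codon_index = NA_integer_)
  } else {
    tibble(protein = paste(head(aa, i - 1L), collapse = ""),
           stop_codon_index = as.integer(i))
  }
}

#' Apply a deletion to a CDS and predict the translation outcome
#'
#' Models frameshift mutagenesis: deletes `del_len` bases starting at `pos`
#' (0-based) from a CDS and translates the result from its first codon.  A
#' deletion whose length is not a multiple of 3 shifts the reading frame and
#' typically creates a premature stop codon, yielding a truncated protein.
#'
#' @param cds RNA string beginning with the initiator AUG.
#' @param pos 0-based position of the first deleted base.
#' @param del_len Number of bases to delete (0 allowed).
#' @return One-row tibble: `protein`, `stop_codon_index` (1-based index of
#'   the first stop codon in the mutant reading; `NA` if none), and
#'   `mutant_cds`.
#' @export
#' @examples
#' apply_indel_and_translate("AUGAAACUAGGG", pos = 3, del_len = 1)
apply_indel_and_translate <- function(cds, pos, del_len) {
  cds <- chartr("Tt", "Uu", toupper(cds))
  len <- nchar(cds)
  if (substr(cds, 1L, 3L) != "AUG") abort("CDS must start with AUG")
  if (pos < 0 || del_len < 0 || pos + del_len > len) {
    abort("deletion window out of bounds")
  }
  if (del_len > 0 && pos < 3) {
    abort("deletion would disrupt the initiator AUG")
  }
  mutant <- paste0(substr(cds, 1L, pos), substr(cds, pos + del_len + 1L, len))
  out <- translate_rna(mutant)
  out$mutant_cds <- mutant
  out
}
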