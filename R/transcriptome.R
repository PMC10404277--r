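#' Simulate a transcriptome with annotated regions and optional planted uORFs
#'
#' Generates single-isoform transcripts (5'UTR + CDS + 3'UTR) as RNA
#' sequences, together with a region-annotation table.  Upstream open reading
#' frames (uORFs) can be planted on request, either fully contained in the
#' 5'UTR or overlapping the main CDS in a shifted reading frame (the
#' configuration seen for the *Xrp1* 5'UTR).  5'UTRs are rejection-sampled so
#' that they contain no AUG other than the planted uORF starts; this keeps
#' base composition unbiased while making the planted truth the complete
#' truth, so downstream uORF discovery can be scored exactly.
#'
#' Coordinates are 0-based half-open throughout; `cds_start` is the position
#' of the A of the initiator AUG, `cds_end` the exclusive end of the stop
#' codon.
#'
#' @param n_genes Number of genes (one transcript per gene).
#' @param utr5_len_range,cds_codons_range,utr3_len_range Inclusive integer
#'   ranges to draw the 5'UTR length (nt), CDS length (codons, including the
#'   initiator and the stop) and 3'UTR length (nt) from.
#' @param uorf_spec Optional tibble with columns `gene_id` and `kind`
#'   (`"contained"` or `"overlapping_out_of_frame"`); one uORF is planted per
#'   row.  A gene may appear twice (one contained + one overlapping).
#' @param seed Integer seed; identical seeds and arguments reproduce
#'   identical output.
#'
#' @return A list of class `"transcriptome"` with elements
#'   * `transcripts`: tibble with `transcript_id`, `gene_id`, `sequence`,
#'     `cds_start`, `cds_end`;
#'   * `features`: tibble with `transcript_id`, `feature`, `feature_id`,
#'     `start`, `end` (0-based half-open) covering `five_prime_UTR`, `CDS`,
#'     `three_prime_UTR` and any planted `uORF`s.
#' @export
#' @examples
#' tx <- generate_transcriptome(
#'   5, uorf_spec = tibble::tibble(gene_id = "gene0001", kind = "contained"),
#'   seed = 1
#' )
#' find_uorfs(tx$transcripts)
generate_transcriptome <- function(n_genes,
                                   utr5_len_range = c(60L, 120L),
                                   cds_codons_range = c(50L, 200L),
                                   utr3_len_range = c(30L, 80L),
                                   uorf_spec = NULL,
                                   seed = 1L) {
  stopifnot(n_genes >= 1)
  check_range(utr5_len_range, "utr5_len_range", min_lo = 0)
  check_range(cds_codons_range, "cds_codons_range", min_lo = 2)
  check_range(utr3_len_range, "utr3_len_range", min_lo = 0)
  uorf_spec <- normalize_uorf_spec(uorf_spec)

  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  if (!is.null(uorf_spec)) {
    bad <- setdiff(uorf_spec$gene_id, gene_ids)
    if (length(bad) > 0) {
      abort(paste0("uorf_spec references unknown gene_id: ",
                   paste(bad, collapse = ", ")))
    }
  }

  transcripts <- withr::with_seed(seed, {
    purrr::map(gene_ids, function(gid) {
      kinds <- if (is.null(uorf_spec)) character(0) else
        uorf_spec$kind[uorf_spec$gene_id == gid]
      simulate_transcript(gid, utr5_len_range, cds_codons_range,
                          utr3_len_range, kinds)
    }) %>% bind_rows()
  })

  uorfs <- find_uorfs(transcripts)
  check_planted_uorfs(uorfs, uorf_spec)

  structure(
    list(transcripts = transcripts, features = build_features(transcripts, uorfs)),
    class = "transcriptome"
  )
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome> %d transcripts, %d annotated features\n",
              nrow(x$transcripts), nrow(x$features)))
  print(x$transcripts, ...)
  invisible(x)
}

# ---- internals --------------------------------------------------------------

check_range <- function(r, what, min_lo) {
  if (length(r) != 2 || any(is.na(r)) || r[1] > r[2] || r[1] < min_lo) {
    abort(sprintf("`%s` must be a non-empty integer range with lower bound >= %d",
                  what, min_lo))
  }
}

normalize_uorf_spec <- function(uorf_spec) {
  if (is.null(uorf_spec) || (is.data.frame(uorf_spec) && nrow(uorf_spec) == 0)) {
    return(NULL)
  }
  if (!is.data.frame(uorf_spec)) uorf_spec <- bind_rows(uorf_spec)
  stopifnot(all(c("gene_id", "kind") %in% names(uorf_spec)))
  bad <- setdiff(uorf_spec$kind, c("contained", "overlapping_out_of_frame"))
  if (length(bad) > 0) {
    abort(paste0("unknown uORF kind: ", paste(bad, collapse = ", ")))
  }
  uorf_spec
}

random_bases <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_codons <- function(k, exclude_aug = FALSE) {
  if (k == 0) return("")
  pool <- the$sense_codons
  if (exclude_aug) pool <- setdiff(pool, "AUG")
  paste(sample(pool, k, replace = TRUE), collapse = "")
}

simulate_transcript <- function(gene_id, utr5_len_range, cds_codons_range,
                                utr3_len_range, kinds) {
  utr5_len <- sample_range(utr5_len_range)
  n_codons <- sample_range(cds_codons_range)
  utr3_len <- sample_range(utr3_len_range)

  cds <- paste0("AUG", random_codons(n_codons - 2L),
                sample(the$stop_codons, 1L))
  utr5 <- plant_utr5(utr5_len, kinds)
  utr3 <- random_bases(utr3_len)

  tibble(
    transcript_id = paste0(gene_id, ".t1"),
    gene_id = gene_id,
    sequence = paste0(utr5, cds, utr3),
    cds_start = utr5_len,
    cds_end = utr5_len + 3L * n_codons
  )
}

sample_range <- function(r) {
  if (r[1] == r[2]) as.integer(r[1]) else sample(seq.int(r[1], r[2]), 1L)
}

# Build a 5'UTR of the requested length whose only AUGs are planted uORF
# starts.  Contained uORFs are placed left of any overlapping one; the
# overlapping uORF is anchored so that its reading frame differs from the CDS
# frame and no in-frame stop occurs before the CDS start.  Rejection sampling
# keeps composition unbiased.
plant_utr5 <- function(utr_len, kinds, max_tries = 10000L) {
  kinds <- sort(kinds)  # "contained" < "overlapping_out_of_frame"
  n_over <- sum(kinds == "overlapping_out_of_frame")
  if (n_over > 1) abort("at most one overlapping uORF can be planted per gene")
  reserve <- if (n_over == 1) 4L else 0L  # room for the overlapping AUG + shift
  need <- 6L * sum(kinds == "contained") + reserve
  if (utr_len < need) {
    abort(sprintf(
      "infeasible uorf_spec: 5'UTR length %d cannot hold %s (needs >= %d nt)",
      utr_len, paste(kinds, collapse = " + "), need))
  }

  for (try in seq_len(max_tries)) {
    bases <- strsplit(random_bases(utr_len), "")[[1]]
    cursor <- 0L
    planted <- integer(0)
    ok <- TRUE
    for (kind in kinds) {
      if (kind == "contained") {
        k_max <- (utr_len - reserve - cursor) %/% 3L
        if (k_max < 2L) { ok <- FALSE; break }
        k <- sample_range(c(2L, min(k_max, 5L)))
        p <- sample_range(c(cursor, utr_len - reserve - 3L * k))
        body <- paste0("AUG", random_codons(k - 2L, exclude_aug = TRUE),
                       sample(the$stop_codons, 1L))
        bases[(p + 1):(p + 3L * k)] <- strsplit(body, "")[[1]]
        planted <- c(planted, p)
        cursor <- p + 3L * k
      } else {
        cand <- seq.int(cursor, utr_len - 3L)
        cand <- cand[(cand - utr_len) %% 3L != 0L]
        if (length(cand) == 0) { ok <- FALSE; break }
        p <- cand[sample.int(length(cand), 1L)]
        n_full <- (utr_len - p) %/% 3L  # complete codons inside the UTR
        body <- paste0("AUG", random_codons(n_full - 1L, exclude_aug = TRUE))
        bases[(p + 1):(p + 3L * n_full)] <- strsplit(body, "")[[1]]
        r <- (utr_len - p) %% 3L  # 1 or 2 leftover bases before the CDS
        if (r == 2L) {
          # the leftover pair reads with the CDS-initial A; avoid UA-A / UG-A
          repeat {
            pair <- sample(c("A", "C", "G", "U"), 2L, replace = TRUE)
            if (!(pair[1] == "U" && pair[2] %in% c("A", "G"))) break
          }
          bases[(utr_len - 1L):utr_len] <- pair
        }
        planted <- c(planted, p)
      }
    }
    if (!ok) next
    utr <- paste(bases, collapse = "")
    hits <- aug_positions(utr)
    if (identical(sort(hits), sort(planted))) return(utr)
  }
  abort("failed to construct an AUG-masked 5'UTR; widen utr5_len_range")
}

aug_positions <- function(s) {
  m <- stringr::str_locate_all(s, stringr::fixed("AUG"))[[1]]
  as.integer(m[, 1] - 1L)
}

check_planted_uorfs <- function(uorfs, uorf_spec) {
  if (is.null(uorf_spec)) return(invisible(TRUE))
  found <- uorfs %>%
    mutate(gene_id = sub("\\.t1$", "", .data$transcript_id),
           kind = ifelse(.data$overlap_class == "contained_in_utr",
                         "contained", .data$overlap_class))
  for (i in seq_len(nrow(uorf_spec))) {
    hit <- found$gene_id == uorf_spec$gene_id[i] & found$kind == uorf_spec$kind[i]
    if (!any(hit)) {
      abort(sprintf("internal error: planted %s uORF for %s was not recovered",
                    uorf_spec$kind[i], uorf_spec$gene_id[i]))
    }
  }
  invisible(TRUE)
}

build_features <- function(transcripts, uorfs) {
  core <- transcripts %>%
    dplyr::reframe(
      feature = c("five_prime_UTR", "CDS", "three_prime_UTR"),
      feature_id = .data$feature,
      start = c(0L, .data$cds_start, .data$cds_end),
      end = c(.data$cds_start, .data$cds_end, nchar(.data$sequence)),
      .by = "transcript_id"
    )
  if (nrow(uorfs) > 0) {
    lens <- setNames(nchar(transcripts$sequence), transcripts$transcript_id)
    u <- uorfs %>%
      group_by(.data$transcript_id) %>%
      mutate(feature = "uORF",
             feature_id = paste0("uORF", dplyr::row_number()),
             end = ifelse(is.na(.data$stop_end),
                          lens[.data$transcript_id], .data$stop_end)) %>%
      ungroup() %>%
      select("transcript_id", "feature", "feature_id", "start", "end")
    core <- bind_rows(core, u)
  }
  core %>% arrange(.data$transcript_id, .data$start, .data$feature_id) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Validate a transcripts tibble
#'
#' Checks the structural invariants every transcript must satisfy: CDS
#' coordinates within bounds, CDS length divisible by 3 and an AUG at
#' `cds_start`.
#'
#' @param transcripts Tibble with columns `transcript_id`, `sequence`,
#'   `cds_start`, `cds_end`.
#' @return The input, invisibly; aborts with the offending transcript named
#'   otherwise.
#' @export
validate_transcripts <- function(transcripts) {
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "sequence", "cds_start", "cds_end") %in%
                  names(transcripts)))
  len <- nchar(transcripts$sequence)
  ok <- transcripts$cds_start >= 0 &
    transcripts$cds_start < transcripts$cds_end &
    transcripts$cds_end <= len &
    (transcripts$cds_end - transcripts$cds_start) %% 3L == 0L &
    substr(transcripts$sequence, transcripts$cds_start + 1L,
           transcripts$cds_start + 3L) == "AUG"
  if (!all(ok)) {
    abort(paste0("invalid transcript(s): ",
                 paste(transcripts$transcript_id[!ok], collapse = ", ")))
  }
  invisible(transcripts)
}

#' A synthetic two-uORF transcript with controlled geometry
#'
#' Builds one transcript whose 5'UTR carries a contained uORF (uORF1) and an
#' out-of-frame uORF (uORF2) that initiates a fixed number of nucleotides
#' upstream of the main start codon and terminates within a bounded window
#' inside the CDS — the architecture of the *Xrp1* 5'UTR, where uORF2
#' overlaps the main ORF in a shifted reading frame.  Unlike
#' [generate_transcriptome()], which places uORFs at random feasible
#' positions, the fixed upstream offset and bounded overlap make the
#' transcript suitable for ribosome-occupancy comparisons: footprints over
#' uORF2 place substantial mass on 5'UTR bases, so a uORF2-to-CDS
#' redistribution is visible in region proportions.
#'
#' @param utr5_len 5'UTR length (nt).
#' @param uorf2_upstream Distance (nt) from the uORF2 AUG to the main start;
#'   must not be a multiple of 3 (out-of-frame requirement).
#' @param overlap_range Admissible span (nt, min/max) between the main start
#'   and the end of uORF2's stop codon; the sequence is resampled until the
#'   naturally occurring shifted-frame stop falls inside it.
#' @param cds_codons CDS length in codons (including initiator and stop).
#' @param utr3_len 3'UTR length (nt).
#' @param seed Integer seed.
#' @return A list of class `"transcriptome"` with one transcript
#'   (`gene0001.t1`) and its features, uORF1 (contained) and uORF2
#'   (overlapping) included.
#' @export
synthetic_uorf_transcript <- function(utr5_len = 150L, uorf2_upstream = 40L,
                                      overlap_range = c(15L, 60L),
                                      cds_codons = 100L, utr3_len = 60L,
                                      seed = 1L) {
  if (uorf2_upstream %% 3L == 0L) {
    abort("uorf2_upstream must not be a multiple of 3 (uORF2 is out of frame)")
  }
  if (utr5_len < uorf2_upstream + 12L) {
    abort("utr5_len too short for the requested uORF2 offset")
  }
  transcripts <- withr::with_seed(seed, {
    tr <- NULL
    for (try in 1:10000) {
      tr <- NULL
      p2 <- utr5_len - uorf2_upstream
      bases <- strsplit(random_bases(utr5_len), "")[[1]]
      # contained uORF1 left of uORF2
      k <- sample_range(c(2L, min(5L, (p2 - 1L) %/% 3L)))
      p1 <- sample_range(c(0L, p2 - 3L * k - 1L))
      body1 <- paste0("AUG", random_codons(k - 2L, exclude_aug = TRUE),
                      sample(the$stop_codons, 1L))
      bases[(p1 + 1):(p1 + 3L * k)] <- strsplit(body1, "")[[1]]
      # uORF2: stop-free through the rest of the UTR
      n_full <- (utr5_len - p2) %/% 3L
      body2 <- paste0("AUG", random_codons(n_full - 1L, exclude_aug = TRUE))
      bases[(p2 + 1):(p2 + 3L * n_full)] <- strsplit(body2, "")[[1]]
      if ((utr5_len - p2) %% 3L == 2L) {
        repeat {
          pair <- sample(c("A", "C", "G", "U"), 2L, replace = TRUE)
          if (!(pair[1] == "U" && pair[2] %in% c("A", "G"))) break
        }
        bases[(utr5_len - 1L):utr5_len] <- pair
      }
      utr5 <- paste(bases, collapse = "")
      if (!identical(sort(aug_positions(utr5)), sort(c(p1, p2)))) next
      cds <- paste0("AUG", random_codons(cds_codons - 2L),
                    sample(the$stop_codons, 1L))
      tr <- tibble(transcript_id = "gene0001.t1", gene_id = "gene0001",
                   sequence = paste0(utr5, cds, random_bases(utr3_len)),
                   cds_start = utr5_len,
                   cds_end = utr5_len + 3L * cds_codons)
      u <- find_uorfs(tr)
      if (nrow(u) != 2L) next
      u2 <- u[u$start == p2, ]
      if (u2$overlap_class != "overlapping_out_of_frame" ||
          is.na(u2$stop_end)) next
      overlap <- u2$stop_end - utr5_len
      if (overlap >= overlap_range[1] && overlap <= overlap_range[2]) {
        break
      }
      tr <- NULL
    }
    if (is.null(tr)) abort("failed to realize the requested uORF2 overlap")
    tr
  })
  uorfs <- find_uorfs(transcripts)
  structure(
    list(transcripts = transcripts,
         features = build_features(transcripts, uorfs)),
    class = "transcriptome"
  )
}
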