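#' Per-gene translation efficiency from fraction abundances
#'
#' Translation efficiency (TE) is the polysome/monosome abundance ratio —
#' the fraction of a transcript pool engaged by multiple ribosomes relative
#' to single-ribosome mRNAs — computed with a pseudocount for stability:
#' `TE = (polysome + pseudocount) / (monosome + pseudocount)`.
#'
#' @param polysome,monosome Non-negative numeric vectors of normalized
#'   per-gene abundances (same length).
#' @param pseudocount Added to both fractions; must be positive unless all
#'   inputs are positive.
#' @return Numeric vector of TE values.
#' @export
compute_te <- function(polysome, monosome, pseudocount = 1) {
  stopifnot(length(polysome) == length(monosome))
  if (any(polysome < 0) || any(monosome < 0)) {
    abort("fraction abundances must be non-negative")
  }
  if (pseudocount <= 0 && (any(polysome <= 0) || any(monosome <= 0))) {
    abort("pseudocount must be positive when zero abundances are present")
  }
  (polysome + pseudocount) / (monosome + pseudocount)
}

#' Classify translation-efficiency changes
#'
#' Applies the scatter-plot rule used to call translationally regulated
#' genes: a gene is `TE_up` when its TE log2 fold-change exceeds
#' `te_threshold` while its transcript-abundance log2 fold-change stays
#' inside `(-rna_threshold, rna_threshold)` (i.e. translation changes
#' without an RNA-level change); `TE_down` mirrors this; everything else is
#' `unchanged`.  Inequalities are strict, so values exactly at a threshold
#' are `unchanged`.
#'
#' @param te_lfc,rna_lfc Numeric vectors (recycled to common length).
#' @param te_threshold,rna_threshold Positive thresholds (default 1, i.e.
#'   2-fold on TE, within 2-fold on RNA).
#' @return Character vector in `c("TE_up", "TE_down", "unchanged")`.
#' @export
classify_te_change <- function(te_lfc, rna_lfc,
                               te_threshold = 1, rna_threshold = 1) {
  stopifnot(te_threshold > 0, rna_threshold > 0)
  dplyr::case_when(
    te_lfc > te_threshold & abs(rna_lfc) < rna_threshold ~ "TE_up",
    te_lfc < -te_threshold & abs(rna_lfc) < rna_threshold ~ "TE_down",
    TRUE ~ "unchanged"
  )
}

#' Translation-efficiency analysis across genotypes
#'
#' Computes per-genotype TE from spike-in-normalized monosome and polysome
#' columns, the TE log2 fold-change between mutant and control, the
#' transcript-abundance log2 fold-change from the total fraction, and the
#' TE-change class of every gene.
#'
#' Within a genotype, replicate TEs are combined either as the geometric
#' mean of per-replicate polysome/monosome ratios (`combine = "geometric"`,
#' the default; replicates are paired by replicate number) or by pooling
#' replicate means before the ratio (`combine = "pooled"`).
#'
#' @param norm_counts Normalized wide counts tibble (from
#'   [normalize_counts()]); spike-in rows are dropped.
#' @param design Library-design tibble (`library_id`, `genotype`,
#'   `fraction`, `replicate`).
#' @param control,treatment Genotype labels; defaults are the first and
#'   second level encountered in `design`.
#' @param pseudocount Added to normalized abundances (default 1).
#' @param te_threshold,rna_threshold Passed to [classify_te_change()].
#' @param combine Replicate-combination rule, see Details.
#' @return Tibble of class `"te_results"` with columns `gene_id`,
#'   `te_control`, `te_mutant`, `te_log2fc`, `rna_log2fc`, `te_class`.
#' @export
te_analysis <- function(norm_counts, design,
                        control = NULL, treatment = NULL,
                        pseudocount = 1,
                        te_threshold = 1, rna_threshold = 1,
                        combine = c("geometric", "pooled")) {
  combine <- match.arg(combine)
  genotypes <- unique(design$genotype)
  control <- control %||% genotypes[1]
  treatment <- treatment %||% setdiff(genotypes, control)[1]
  stopifnot(control %in% genotypes, treatment %in% genotypes)
  need <- c("monosome", "polysome")
  if (!all(need %in% design$fraction)) {
    abort("design must contain monosome and polysome libraries")
  }
  genes <- if ("is_spikein" %in% names(norm_counts)) {
    filter(norm_counts, !.data$is_spikein)
  } else {
    norm_counts
  }

  te_for <- function(genotype) {
    reps <- sort(unique(design$replicate[design$genotype == genotype]))
    poly <- vapply(reps, function(r)
      fraction_column(genes, design, genotype, "polysome", r),
      numeric(nrow(genes)))
    mono <- vapply(reps, function(r)
      fraction_column(genes, design, genotype, "monosome", r),
      numeric(nrow(genes)))
    poly <- matrix(poly, nrow = nrow(genes))
    mono <- matrix(mono, nrow = nrow(genes))
    if (combine == "geometric") {
      lt <- vapply(seq_along(reps), function(k)
        log(compute_te(poly[, k], mono[, k], pseudocount)),
        numeric(nrow(genes)))
      exp(rowMeans(matrix(lt, nrow = nrow(genes))))
    } else {
      compute_te(rowMeans(poly), rowMeans(mono), pseudocount)
    }
  }

  te_ctl <- te_for(control)
  te_mut <- te_for(treatment)
  rna_lfc <- if ("total" %in% design$fraction) {
    rna_log2fc(total_mean(genes, design, treatment),
               total_mean(genes, design, control), pseudocount)
  } else {
    rep(NA_real_, nrow(genes))
  }

  out <- tibble(
    gene_id = genes$feature_id,
    te_control = te_ctl,
    te_mutant = te_mut,
    te_log2fc = te_log2fc(te_mut, te_ctl),
    rna_log2fc = rna_lfc,
    te_class = classify_te_change(te_log2fc(te_mut, te_ctl),
                                  tidyr::replace_na(rna_lfc, 0),
                                  te_threshold, rna_threshold)
  )
  structure(out, class = c("te_results", class(out)),
            te_threshold = te_threshold, rna_threshold = rna_threshold)
}

fraction_column <- function(genes, design, genotype, fraction, replicate) {
  lib <- design$library_id[design$genotype == genotype &
                             design$fraction == fraction &
                             design$replicate == replicate]
  if (length(lib) != 1) {
    abort(sprintf("expected exactly one %s/%s replicate %d library",
                  genotype, fraction, replicate))
  }
  genes[[lib]]
}

total_mean <- function(genes, design, genotype) {
  libs <- design$library_id[design$genotype == genotype &
                              design$fraction == "total"]
  rowMeans(as.matrix(genes[, libs, drop = FALSE]))
}

#' TE and RNA log2 fold-changes
#'
#' `te_log2fc()` is `log2(te_mutant / te_control)` on per-gene TE values;
#' `rna_log2fc()` is `log2((mean_mutant + pseudocount) /
#' (mean_control + pseudocount))` on per-genotype mean normalized total-RNA
#' abundances.
#'
#' @param te_mutant,te_control Positive TE vectors.
#' @return Numeric vector of log2 fold-changes.
#' @export
te_log2fc <- function(te_mutant, te_control) {
  if (any(te_mutant <= 0) || any(te_control <= 0)) {
    abort("TE values must be positive")
  }
  log2(te_mutant / te_control)
}

#' @rdname te_log2fc
#' @param mean_mutant,mean_control Non-negative mean normalized abundances.
#' @param pseudocount Positive stabilizer.
#' @export
rna_log2fc <- function(mean_mutant, mean_control, pseudocount = 1) {
  stopifnot(pseudocount > 0 || (all(mean_mutant > 0) && all(mean_control > 0)))
  log2((mean_mutant + pseudocount) / (mean_control + pseudocount))
}
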