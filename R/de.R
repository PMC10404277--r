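#' Method-of-moments common NB dispersion
#'
#' Pools per-gene, per-group sample means and variances into a single
#' dispersion estimate under the quadratic mean-variance law
#' `Var = mu + alpha * mu^2`: `alpha_hat = sum(v - m) / sum(m^2)`, truncated
#' at 0.  Sharing one dispersion across genes is what makes a 2-vs-2 design
#' testable at all; it mirrors common-dispersion usage in count-based DE.
#'
#' @param mat Numeric matrix, genes x libraries.
#' @param groups Vector assigning each column to a group; every group needs
#'   at least 2 columns.
#' @return Non-negative dispersion estimate (scalar).
#' @export
estimate_common_dispersion <- function(mat, groups) {
  mat <- as.matrix(mat)
  if (any(table(groups) < 2)) {
    abort("dispersion is inestimable with fewer than 2 replicates per group")
  }
  num <- 0; den <- 0
  for (g in unique(groups)) {
    sub <- mat[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  max(0, num / den)
}

#' Exact negative-binomial test for one gene
#'
#' Conditions the group-A sum on the gene total: when the `nA` (`nB`)
#' replicate counts in each group are i.i.d. NB with a common mean and
#' dispersion `alpha`, the group sums are NB with sizes `nA/alpha` and
#' `nB/alpha`, and the conditional law of the A-sum given the total does not
#' depend on the unknown mean.  The two-sided p-value sums the conditional
#' probabilities of all outcomes no more likely than the observed one
#' (binomial in the `alpha -> 0` limit).
#'
#' @param sum_a,sum_b Group count sums (non-negative integers).
#' @param n_a,n_b Replicates per group.
#' @param dispersion Common NB dispersion `alpha` (0 gives the binomial
#'   exact test).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(sum_a, sum_b, n_a, n_b, dispersion) {
  stopifnot(sum_a >= 0, sum_b >= 0, n_a >= 1, n_b >= 1, dispersion >= 0)
  total <- sum_a + sum_b
  if (total == 0) return(1)
  k <- 0:total
  if (dispersion < 1e-8) {
    logf <- dbinom(k, total, n_a / (n_a + n_b), log = TRUE)
  } else {
    mu_a <- total * n_a / (n_a + n_b)
    mu_b <- total * n_b / (n_a + n_b)
    logf <- dnbinom(k, size = n_a / dispersion, mu = mu_a, log = TRUE) +
      dnbinom(total - k, size = n_b / dispersion, mu = mu_b, log = TRUE)
  }
  f <- exp(logf - max(logf))
  f <- f / sum(f)
  min(1, sum(f[f <= f[sum_a + 1] * (1 + 1e-7)]))
}

#' Differential expression by an exact NB test
#'
#' A minimal count-based differential-expression stage for the total-RNA
#' fraction: normalized counts are rounded, all-zero genes dropped, a common
#' dispersion estimated by [estimate_common_dispersion()], each gene tested
#' with [nb_exact_test()], p-values adjusted by Benjamini-Hochberg, and
#' genes called `up` / `down` when `fdr < fdr_threshold` and
#' `|log2fc| > lfc_threshold` (strict inequalities), `ns` otherwise.
#'
#' @param norm_total Normalized wide counts tibble; only total-fraction
#'   library columns in `design` are used, spike-in rows are dropped.
#' @param design Library-design tibble (`library_id`, `genotype`,
#'   `fraction`, `replicate`).
#' @param control,treatment Genotype labels (defaults: first and second
#'   level in `design`); log2 fold-changes are treatment over control.
#' @param fdr_threshold,lfc_threshold Calling thresholds (defaults 0.05, 1).
#' @param pseudocount Added to group means for the fold-change (default 0.5).
#' @param dispersion Optional fixed dispersion; estimated when `NULL`.
#' @return Tibble of class `"de_results"`: `gene_id`, `log2fc`, `p_value`,
#'   `fdr`, `de_class`.
#' @export
differential_expression <- function(norm_total, design,
                                    control = NULL, treatment = NULL,
                                    fdr_threshold = 0.05, lfc_threshold = 1,
                                    pseudocount = 0.5, dispersion = NULL) {
  genotypes <- unique(design$genotype)
  control <- control %||% genotypes[1]
  treatment <- treatment %||% setdiff(genotypes, control)[1]
  dsub <- filter(design, .data$fraction == "total",
                 .data$genotype %in% c(control, treatment))
  if (nrow(dsub) == 0) abort("design has no total-fraction libraries")
  if (any(table(dsub$genotype) < 2)) {
    abort("differential expression needs >= 2 replicates per genotype")
  }
  genes <- if ("is_spikein" %in% names(norm_total)) {
    filter(norm_total, !.data$is_spikein)
  } else {
    norm_total
  }
  mat <- round(as.matrix(genes[, dsub$library_id, drop = FALSE]))
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]
  gene_ids <- genes$feature_id[keep]
  groups <- dsub$genotype

  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(mat, groups)
  }
  n_ctl <- sum(groups == control)
  n_mut <- sum(groups == treatment)
  sum_ctl <- rowSums(mat[, groups == control, drop = FALSE])
  sum_mut <- rowSums(mat[, groups == treatment, drop = FALSE])

  p <- vapply(seq_along(gene_ids), function(i)
    nb_exact_test(sum_mut[i], sum_ctl[i], n_mut, n_ctl, dispersion),
    numeric(1))
  lfc <- log2((sum_mut / n_mut + pseudocount) /
                (sum_ctl / n_ctl + pseudocount))
  fdr <- p.adjust(p, method = "BH")

  out <- tibble(
    gene_id = gene_ids,
    log2fc = lfc,
    p_value = p,
    fdr = fdr,
    de_class = dplyr::case_when(
      fdr < fdr_threshold & lfc > lfc_threshold ~ "up",
      fdr < fdr_threshold & lfc < -lfc_threshold ~ "down",
      TRUE ~ "ns"
    )
  )
  structure(out, class = c("de_results", class(out)),
            dispersion = dispersion,
            fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold)
}
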