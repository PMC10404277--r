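#' Describe a polysome-fraction sequencing simulation
#'
#' Bundles the parameters of the simulated study design: a two-genotype
#' (control vs mutant) layout with total/monosome/polysome fractions and
#' replicated libraries, negative-binomial counting noise, and planted
#' per-gene effects.  A planted translation-efficiency (TE) log2 fold-change
#' of delta is split symmetrically — polysome loading x 2^(+delta/2),
#' monosome loading x 2^(-delta/2) in the mutant — so transcript abundance is
#' untouched unless `rna_effects` says otherwise.
#'
#' @param genotypes Character vector of length 2; the first level is the
#'   control.
#' @param fractions Subset of `c("total", "monosome", "polysome")`.
#' @param replicates Replicates per (genotype, fraction) condition.
#' @param mean_depth Expected baseline count per gene per library.
#' @param dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2); 0 gives noise-free rounded means.
#' @param te_effects,rna_effects Named numeric vectors (gene_id -> log2FC)
#'   of planted TE and transcript-abundance effects in the mutant.
#' @param library_scale_factors Named numeric vector (library_id -> positive
#'   scale), or a single value recycled to all libraries; emulates depth /
#'   input differences that spike-in normalization must undo.
#' @param seed Integer seed for count generation.
#' @return A list of class `"simulation_design"`.
#' @export
simulation_design <- function(genotypes = c("control", "mutant"),
                              fractions = c("total", "monosome", "polysome"),
                              replicates = 2L,
                              mean_depth = 500,
                              dispersion = 0.05,
                              te_effects = numeric(0),
                              rna_effects = numeric(0),
                              library_scale_factors = 1,
                              seed = 1L) {
  stopifnot(length(genotypes) == 2, replicates >= 1, dispersion >= 0,
            all(fractions %in% c("total", "monosome", "polysome")),
            all(library_scale_factors > 0))
  if (mean_depth <= 0) abort("mean_depth must be positive")
  structure(
    list(genotypes = genotypes, fractions = fractions,
         replicates = as.integer(replicates), mean_depth = mean_depth,
         dispersion = dispersion, te_effects = te_effects,
         rna_effects = rna_effects,
         library_scale_factors = library_scale_factors,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' Library layout of a simulation design
#'
#' @param design A [simulation_design()].
#' @return Tibble with `library_id`, `genotype`, `fraction`, `replicate`;
#'   `library_id` is `<genotype>_<fraction>_rep<k>`.
#' @export
library_design <- function(design) {
  tidyr::expand_grid(
    genotype = design$genotypes,
    fraction = design$fractions,
    replicate = seq_len(design$replicates)
  ) %>%
    mutate(library_id = paste0(.data$genotype, "_", .data$fraction,
                               "_rep", .data$replicate)) %>%
    select("library_id", "genotype", "fraction", "replicate")
}

#' ERCC-like spike-in reference table
#'
#' A configurable number of spike-in species (default 92, echoing the ERCC
#' mix) with log2-spaced known input amounts in an arbitrary consistent unit.
#'
#' @param n_spikes Number of spike-in species.
#' @param log2_amount_range Range of log2 input amounts; amounts are spaced
#'   evenly on the log2 scale across it.
#' @return Tibble with `spike_id`, `input_amount`.
#' @export
spikein_reference <- function(n_spikes = 92L, log2_amount_range = c(-3, 3)) {
  stopifnot(n_spikes >= 1)
  tibble(
    spike_id = sprintf("SPIKE%03d", seq_len(n_spikes)),
    input_amount = 2^seq(log2_amount_range[1], log2_amount_range[2],
                         length.out = n_spikes)
  )
}

#' Expected count means of a simulated design
#'
#' Closed-form expected counts for every (row, library) cell, before noise:
#' gene rows get `mean_depth * 2^rna_effect * loading * scale`, with the
#' fraction loading carrying half the planted TE effect with opposite signs
#' in polysome vs monosome; spike-in rows get
#' `spike_scale * input_amount * scale`, independent of genotype.
#'
#' @param gene_ids Character vector of gene ids (or a transcripts tibble with
#'   a `gene_id` column).
#' @param design A [simulation_design()].
#' @param spikein_ref Optional [spikein_reference()] tibble.
#' @param spike_scale Counts per unit input amount; default scales the mean
#'   spike-in count to `mean_depth`.
#' @return List: `mu` (tibble feature_id, is_spikein, one numeric column per
#'   library) and `design_tbl` (the [library_design()]).
#' @export
expected_fraction_means <- function(gene_ids, design, spikein_ref = NULL,
                                    spike_scale = NULL) {
  if (is.data.frame(gene_ids)) gene_ids <- unique(gene_ids$gene_id)
  stopifnot(length(gene_ids) >= 1, !anyDuplicated(gene_ids))
  lib <- library_design(design)
  scale <- resolve_scale_factors(design$library_scale_factors, lib$library_id)
  te <- effect_of(gene_ids, design$te_effects)
  rna <- effect_of(gene_ids, design$rna_effects)
  mutant <- design$genotypes[2]

  mu_gene <- vapply(seq_len(nrow(lib)), function(j) {
    is_mut <- lib$genotype[j] == mutant
    loading <- switch(lib$fraction[j],
      total = rep(1, length(gene_ids)),
      polysome = if (is_mut) 2^(te / 2) else rep(1, length(gene_ids)),
      monosome = if (is_mut) 2^(-te / 2) else rep(1, length(gene_ids))
    )
    design$mean_depth * (if (is_mut) 2^rna else 1) * loading * scale[j]
  }, numeric(length(gene_ids)))
  mu_gene <- matrix(mu_gene, nrow = length(gene_ids),
                    dimnames = list(NULL, lib$library_id))
  mu <- tibble(feature_id = gene_ids, is_spikein = FALSE) %>%
    bind_cols(as_tibble(mu_gene))

  if (!is.null(spikein_ref)) {
    if (any(spikein_ref$spike_id %in% gene_ids)) {
      abort("spike ids must be disjoint from gene ids")
    }
    spike_scale <- spike_scale %||%
      (design$mean_depth / mean(spikein_ref$input_amount))
    mu_spike <- outer(spikein_ref$input_amount * spike_scale, scale)
    colnames(mu_spike) <- lib$library_id
    mu <- bind_rows(mu, tibble(feature_id = spikein_ref$spike_id,
                               is_spikein = TRUE) %>%
                      bind_cols(as_tibble(mu_spike)))
  }
  list(mu = mu, design_tbl = lib)
}

resolve_scale_factors <- function(sf, lib_ids) {
  if (length(sf) == 1 && is.null(names(sf))) {
    return(setNames(rep(sf, length(lib_ids)), lib_ids))
  }
  missing <- setdiff(lib_ids, names(sf))
  if (length(missing) > 0) {
    abort(paste0("library_scale_factors missing for: ",
                 paste(missing, collapse = ", ")))
  }
  sf[lib_ids]
}

effect_of <- function(gene_ids, effects) {
  out <- setNames(rep(0, length(gene_ids)), gene_ids)
  if (length(effects) > 0) out[names(effects)] <- effects
  unname(out)
}

#' Simulate fraction count matrices with spike-ins
#'
#' Draws a gene x library count matrix from the expected means of
#' [expected_fraction_means()], using negative-binomial noise
#' (`rnbinom(mu, size = 1/alpha)`); `dispersion = 0` emits the rounded means
#' exactly, and `noise_model = "poisson"` draws Poisson counts instead.
#'
#' @inheritParams expected_fraction_means
#' @param noise_model `"nb"` (default) or `"poisson"`.
#' @return List of class `"fraction_counts"`: `counts` (wide tibble
#'   `feature_id`, `is_spikein`, one integer column per library) and
#'   `design` (the library-design tibble).
#' @export
generate_fraction_counts <- function(gene_ids, design, spikein_ref = NULL,
                                     spike_scale = NULL,
                                     noise_model = c("nb", "poisson")) {
  noise_model <- match.arg(noise_model)
  em <- expected_fraction_means(gene_ids, design, spikein_ref, spike_scale)
  lib_ids <- em$design_tbl$library_id
  counts <- em$mu
  withr::with_seed(design$seed, {
    for (j in lib_ids) {
      mu <- counts[[j]]
      counts[[j]] <- if (noise_model == "poisson") {
        rpois(length(mu), mu)
      } else if (design$dispersion == 0) {
        as.integer(round(mu))
      } else {
        rnbinom(length(mu), mu = mu, size = 1 / design$dispersion)
      }
      counts[[j]] <- as.integer(counts[[j]])
    }
  })
  structure(list(counts = counts, design = em$design_tbl),
            class = "fraction_counts")
}

#' Default ribosome-footprint length distribution
#'
#' Uniform over 25-35 nt, so the canonical 28-32 nt selection removes a
#' non-trivial share of reads.
#'
#' @return Named numeric vector of probabilities (names are lengths in nt).
#' @export
rpf_length_dist <- function() {
  setNames(rep(1 / 11, 11), 25:35)
}

#' Simulate ribosome-protected fragments on one transcript
#'
#' Samples reads region-by-region: each read picks a region with the given
#' weight, a length from `length_dist`, and a start uniform over the region
#' (truncated so the footprint stays on the transcript).
#'
#' @param transcript One-row transcripts tibble (needs `transcript_id` and
#'   `sequence`).
#' @param features Feature tibble for that transcript (`feature_id`, `start`,
#'   `end`; 0-based half-open), e.g. from [generate_transcriptome()].
#' @param region_weights Named numeric summing to 1; names must match
#'   `feature_id`s.
#' @param n_reads Number of reads to draw.
#' @param length_dist Named probability vector over read lengths;
#'   default [rpf_length_dist()].
#' @param seed Integer seed.
#' @return Tibble with `transcript_id`, `start` (0-based), `length`.
#' @export
generate_rpf_reads <- function(transcript, features, region_weights,
                               n_reads, length_dist = rpf_length_dist(),
                               seed = 1L) {
  stopifnot(nrow(transcript) == 1, n_reads >= 0,
            abs(sum(region_weights) - 1) < 1e-8, all(region_weights >= 0),
            all(as.integer(names(length_dist)) >= 1),
            abs(sum(length_dist) - 1) < 1e-8)
  tlen <- nchar(transcript$sequence)
  feats <- features %>%
    filter(.data$transcript_id == transcript$transcript_id,
           .data$feature_id %in% names(region_weights))
  missing <- setdiff(names(region_weights), feats$feature_id)
  if (length(missing) > 0) {
    abort(paste0("region(s) not annotated on transcript: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(feats$start < 0 | feats$end > tlen)) {
    abort("region outside transcript bounds")
  }
  min_len <- min(as.integer(names(length_dist)))
  active <- names(region_weights)[region_weights > 0]
  too_short <- feats %>%
    filter(.data$feature_id %in% active,
           .data$end - .data$start < min_len) %>%
    pull("feature_id")
  if (length(too_short) > 0) {
    abort(paste0("region shorter than the minimum read length: ",
                 paste(too_short, collapse = ", ")))
  }
  if (n_reads == 0) {
    return(tibble(transcript_id = character(), start = integer(),
                  length = integer()))
  }
  lens_support <- as.integer(names(length_dist))
  withr::with_seed(seed, {
    region <- sample(feats$feature_id, n_reads, replace = TRUE,
                     prob = region_weights[feats$feature_id])
    len <- sample(lens_support, n_reads, replace = TRUE, prob = length_dist)
    lo <- feats$start[match(region, feats$feature_id)]
    hi <- feats$end[match(region, feats$feature_id)] - 1L
    start <- lo + floor(runif(n_reads) * (hi - lo + 1))
    len <- pmin(len, tlen - start)  # footprint truncated at the 3' end
    tibble(transcript_id = transcript$transcript_id,
           start = as.integer(start), length = as.integer(len))
  })
}

#' Simulate a dual-luciferase plate table
#'
#' Draws per-well Renilla/Firefly luminescence with log-normal well noise.
#' Firefly models transfection efficiency (shared by both channels); the
#' planted `activities` scale only Renilla, so the Renilla/Firefly ratio
#' carries the construct effect.
#'
#' @param activities Named numeric vector: construct_id -> true relative
#'   activity (the control construct should be 1).
#' @param n_replicates Wells per construct.
#' @param base_firefly,base_renilla Baseline luminescence levels.
#' @param cv Log-normal coefficient of variation of well effects.
#' @param seed Integer seed.
#' @return Tibble with `construct_id`, `replicate`, `renilla`, `firefly`.
#' @export
generate_luciferase_table <- function(activities, n_replicates = 3L,
                                      base_firefly = 1e5, base_renilla = 2e4,
                                      cv = 0.1, seed = 1L) {
  stopifnot(length(activities) >= 1, !is.null(names(activities)),
            all(activities > 0), n_replicates >= 1, cv >= 0)
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, {
    tidyr::expand_grid(construct_id = names(activities),
                       replicate = seq_len(n_replicates)) %>%
      mutate(
        transfection = rlnorm(n(), -sdlog^2 / 2, sdlog),
        firefly = base_firefly * .data$transfection *
          rlnorm(n(), -sdlog^2 / 2, sdlog),
        renilla = base_renilla * .data$transfection *
          activities[.data$construct_id] * rlnorm(n(), -sdlog^2 / 2, sdlog)
      ) %>%
      select("construct_id", "replicate", "renilla", "firefly")
  })
}
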