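#' Configuration for the synthetic five-stage expression study
#'
#' Builds and validates the parameter set used by [simulate_triome()] and the
#' individual generators. The defaults emulate the design of a pooled
#' five-stage carcinogenesis study at desk scale: one column per stage (the
#' study pooled RNA per stage, so there are no replicates), log-normal probe
#' intensities, per-stage two-fold planted differential expression, two miRNAs
#' upregulated in stages 3 and 4 whose targets are enriched among mRNAs
#' downregulated in those stages, and lncRNAs whose flanking coding genes
#' carry planted GO terms.
#'
#' @param n_lnc,n_mrna,n_mirna number of probes per RNA class.
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of baseline probe
#'   intensities on the log2 scale (stage 1 holds these baselines).
#' @param de_fraction_per_stage fraction of probes planted differentially
#'   expressed in each disease stage; must lie in (0, 1).
#' @param planted_up34_mirnas number of miRNAs forced upregulated in both
#'   stages 3 and 4 (and guaranteed to be the only such miRNAs).
#' @param planted_up34_lncs number of lncRNAs forced upregulated in both
#'   stages 3 and 4 (the cis-neighbor analysis selects these).
#' @param planted_down34_mrnas number of mRNAs forced downregulated in both
#'   stages 3 and 4 (the miRNA-target intersection draws on these).
#' @param planted_fc fold-change magnitude applied to planted probes; must be
#'   at least the downstream differential-expression threshold of 2.
#' @param noise_log2_sd sd of multiplicative log2-normal measurement noise
#'   applied to every cell; 0 gives exactly reconstructible data.
#' @param detect_floor intensity above which a probe counts as expressed;
#'   planting is restricted to probes that stay above this floor in every
#'   stage so that planted calls survive detection filtering.
#' @param n_chromosomes,chrom_length genome layout for the locus table.
#' @param lnc_overlap_fraction fraction of lncRNA loci shifted to overlap a
#'   coding gene, to exercise the distance-zero neighbor rule.
#' @param targets_per_mirna number of predicted target mRNAs per miRNA.
#' @param target_enrichment_in_down34 probability that a target of a planted
#'   up-in-3/4 miRNA is drawn from the down-in-3/4 mRNA set.
#' @param n_go_terms,genes_per_term GO annotation layout.
#' @param planted_enriched_terms number of GO terms built to over-represent
#'   both the miRNA-associated mRNAs and the lncRNA neighbor genes.
#' @param seed integer RNG seed; a fixed seed gives bit-identical outputs.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_triome()]
#' @export
#' @examples
#' cfg <- sim_config(n_lnc = 50, n_mrna = 80, n_mirna = 10, seed = 7)
#' cfg$planted_up34_mirnas
sim_config <- function(n_lnc = 2000L,
                       n_mrna = 2000L,
                       n_mirna = 100L,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 2.5,
                       de_fraction_per_stage = 0.05,
                       planted_up34_mirnas = 2L,
                       planted_up34_lncs = 40L,
                       planted_down34_mrnas = 100L,
                       planted_fc = 4,
                       noise_log2_sd = 0.2,
                       detect_floor = 50,
                       n_chromosomes = 5L,
                       chrom_length = 2e7,
                       lnc_overlap_fraction = 0.05,
                       targets_per_mirna = 100L,
                       target_enrichment_in_down34 = 0.8,
                       n_go_terms = 50L,
                       genes_per_term = 40L,
                       planted_enriched_terms = 3L,
                       seed = 1L) {
  cfg <- list(
    n_lnc = as.integer(n_lnc), n_mrna = as.integer(n_mrna),
    n_mirna = as.integer(n_mirna), n_stages = .N_STAGES,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    de_fraction_per_stage = de_fraction_per_stage,
    planted_up34_mirnas = as.integer(planted_up34_mirnas),
    planted_up34_lncs = as.integer(planted_up34_lncs),
    planted_down34_mrnas = as.integer(planted_down34_mrnas),
    planted_fc = planted_fc,
    noise_log2_sd = noise_log2_sd,
    detect_floor = detect_floor,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length,
    lnc_overlap_fraction = lnc_overlap_fraction,
    targets_per_mirna = as.integer(targets_per_mirna),
    target_enrichment_in_down34 = target_enrichment_in_down34,
    n_go_terms = as.integer(n_go_terms),
    genes_per_term = as.integer(genes_per_term),
    planted_enriched_terms = as.integer(planted_enriched_terms),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_lnc", "n_mrna", "n_mirna", "n_chromosomes")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("sim_config: '", nm, "' must be a positive count", call. = FALSE)
  }
  for (nm in c("planted_up34_mirnas", "planted_up34_lncs",
               "planted_down34_mrnas", "targets_per_mirna",
               "n_go_terms", "genes_per_term", "planted_enriched_terms")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop("sim_config: '", nm, "' must be a non-negative count", call. = FALSE)
  }
  if (cfg$de_fraction_per_stage <= 0 || cfg$de_fraction_per_stage >= 1)
    stop("sim_config: 'de_fraction_per_stage' must lie in (0, 1)", call. = FALSE)
  if (cfg$planted_fc < 2)
    stop("sim_config: 'planted_fc' must be >= 2, the differential-expression threshold",
         call. = FALSE)
  if (cfg$noise_log2_sd < 0)
    stop("sim_config: 'noise_log2_sd' must be >= 0", call. = FALSE)
  if (cfg$target_enrichment_in_down34 < 0 || cfg$target_enrichment_in_down34 > 1)
    stop("sim_config: 'target_enrichment_in_down34' must lie in [0, 1]", call. = FALSE)
  if (cfg$lnc_overlap_fraction < 0 || cfg$lnc_overlap_fraction > 1)
    stop("sim_config: 'lnc_overlap_fraction' must lie in [0, 1]", call. = FALSE)
  if (cfg$targets_per_mirna > cfg$n_mrna)
    stop("sim_config: 'targets_per_mirna' cannot exceed 'n_mrna'", call. = FALSE)
  if (cfg$genes_per_term > cfg$n_mrna)
    stop("sim_config: 'genes_per_term' cannot exceed 'n_mrna'", call. = FALSE)
  if (cfg$planted_up34_mirnas > cfg$n_mirna ||
      cfg$planted_up34_lncs > cfg$n_lnc ||
      cfg$planted_down34_mrnas > cfg$n_mrna)
    stop("sim_config: planted set sizes cannot exceed the class probe counts",
         call. = FALSE)
  if (cfg$planted_enriched_terms > cfg$n_go_terms)
    stop("sim_config: 'planted_enriched_terms' cannot exceed 'n_go_terms'",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic five-stage study configuration\n")
  cat(sprintf("  probes: %d lncRNA / %d miRNA / %d mRNA; %d stages\n",
              x$n_lnc, x$n_mirna, x$n_mrna, x$n_stages))
  cat(sprintf("  planted: %.0f%% DE per stage at fold change %g, %d up-3/4 miRNAs,\n",
              100 * x$de_fraction_per_stage, x$planted_fc, x$planted_up34_mirnas))
  cat(sprintf("           %d up-3/4 lncRNAs, %d down-3/4 mRNAs, %d enriched GO terms\n",
              x$planted_up34_lncs, x$planted_down34_mrnas, x$planted_enriched_terms))
  cat(sprintf("  noise sd (log2): %g; seed: %d\n", x$noise_log2_sd, x$seed))
  invisible(x)
}
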