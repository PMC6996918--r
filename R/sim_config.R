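#' Default per-pair expected reference-allele ratios
#'
#' Reference mapping bias inflates the reference ratio slightly above 0.5;
#' defaults place transitions (A>G, C>T, G>A, T>C) at 0.55 and transversions
#' at 0.52-0.53, spanning the "slightly inflated from 0.5" regime the bias
#' model is designed to absorb.
#' @export
default_bias_table <- function() {
  c("A>C" = 0.53, "A>G" = 0.55, "A>T" = 0.52,
    "C>A" = 0.53, "C>G" = 0.52, "C>T" = 0.55,
    "G>A" = 0.55, "G>C" = 0.52, "G>T" = 0.53,
    "T>A" = 0.52, "T>C" = 0.55, "T>G" = 0.53)
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by [simulate_cohort()]: cohort size,
#' gene/SNP layout, sequencing depth, nucleotide-pair mapping bias, the mix of
#' paired normal/tumor ASE patterns, the allelic effect size, and how planted
#' tumor-ASE loci are apportioned among driving mechanisms.
#'
#' @param n_patients number of matched normal/tumor pairs.
#' @param n_genes number of genes in the panel.
#' @param snps_per_gene integer range (length-2) of heterozygous SNPs per gene.
#' @param rna_depth,dna_depth list(mean, dispersion) of the negative-binomial
#'   read-depth model per assay (dispersion = NB `size`; `Inf` gives fixed
#'   depth).
#' @param bias_table named vector over the 12 ordered nucleotide pairs giving
#'   the true expected reference ratio p0 in (0,1) at balanced loci.
#' @param pattern_mix named proportions over `P1..P6` and `no-change`,
#'   summing to 1.
#' @param effect_ratio reference-allele ratio used for the imbalanced state,
#'   in (0.5, 1); the opposite-direction state uses `1 - effect_ratio`.
#' @param cnv_fraction fraction of tumor-ASE loci (patterns P1/P3/P4/P6) whose
#'   imbalance is driven by a DNA copy-number change.
#' @param skip_fraction fraction of tumor-ASE loci driven by exon skipping
#'   (with coupled antisense RNA); the remainder are pure-regulatory.
#' @param skip_fold planted tumor/normal fold increase of the exon-skipping
#'   isoform (ISO1 split reads) at skipping loci.
#' @param antisense_coupling multiplicative link between the planted skipping
#'   fold and the planted antisense fold (antisense fold =
#'   `antisense_coupling * skip_fold`).
#' @param iso1_rate,antisense_rate baseline ISO1 / antisense read rates as a
#'   fraction of library size.
#' @param library_size RNA library size used for isoform and antisense counts.
#' @param cnv_major,cnv_minor planted tumor copy state at CNV-driven loci
#'   (default 3/1: unbalanced duplication, DNA allelic ratio 0.75).
#' @param seed master seed; every stream in the generator derives from it via
#'   [sub_seed()].
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20,
                       n_genes = 100,
                       snps_per_gene = c(1L, 3L),
                       rna_depth = list(mean = 60, dispersion = 5),
                       dna_depth = list(mean = 60, dispersion = 5),
                       bias_table = default_bias_table(),
                       pattern_mix = c("P1" = 0.07, "P2" = 0.005,
                                       "P3" = 0.002, "P4" = 0.035,
                                       "P5" = 0.02, "P6" = 0.005,
                                       "no-change" = 0.863),
                       effect_ratio = 0.75,
                       cnv_fraction = 0.3,
                       skip_fraction = 0.3,
                       skip_fold = 2.5,
                       antisense_coupling = 1.0,
                       iso1_rate = 1e-3,
                       antisense_rate = 5e-4,
                       library_size = 1e5,
                       cnv_major = 3L,
                       cnv_minor = 1L,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              snps_per_gene = as.integer(snps_per_gene),
              rna_depth = rna_depth, dna_depth = dna_depth,
              bias_table = bias_table, pattern_mix = pattern_mix,
              effect_ratio = effect_ratio,
              cnv_fraction = cnv_fraction, skip_fraction = skip_fraction,
              skip_fold = skip_fold, antisense_coupling = antisense_coupling,
              iso1_rate = iso1_rate, antisense_rate = antisense_rate,
              library_size = library_size,
              cnv_major = as.integer(cnv_major),
              cnv_minor = as.integer(cnv_minor),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 1 || cfg$n_genes < 1) {
    stop("sim_config: n_patients and n_genes must be positive")
  }
  if (length(cfg$snps_per_gene) != 2 || any(cfg$snps_per_gene < 1) ||
      cfg$snps_per_gene[1] > cfg$snps_per_gene[2]) {
    stop("sim_config: snps_per_gene must be a non-decreasing positive range")
  }
  for (d in list(cfg$rna_depth, cfg$dna_depth)) {
    if (!is.list(d) || is.null(d$mean) || d$mean < 0 ||
        is.null(d$dispersion) || d$dispersion <= 0) {
      stop("sim_config: depth models need mean >= 0 and dispersion > 0")
    }
  }
  if (!setequal(names(cfg$bias_table), NUCLEOTIDE_PAIRS) ||
      any(cfg$bias_table <= 0) || any(cfg$bias_table >= 1)) {
    stop("sim_config: bias_table must cover the 12 ordered pairs with p0 in (0,1)")
  }
  if (!setequal(names(cfg$pattern_mix), PATTERN_MIX_LEVELS) ||
      any(cfg$pattern_mix < 0) ||
      abs(sum(cfg$pattern_mix) - 1) > 1e-9) {
    stop("sim_config: pattern_mix must cover P1..P6 and no-change and sum to 1")
  }
  if (cfg$effect_ratio <= 0.5 || cfg$effect_ratio >= 1) {
    stop("sim_config: effect_ratio must lie in (0.5, 1)")
  }
  if (cfg$cnv_fraction < 0 || cfg$skip_fraction < 0 ||
      cfg$cnv_fraction + cfg$skip_fraction > 1) {
    stop("sim_config: cnv_fraction + skip_fraction must lie in [0, 1]")
  }
  if (cfg$skip_fold <= 0 || cfg$antisense_coupling < 0) {
    stop("sim_config: folds must be positive")
  }
  cfg
}

#' Planted per-tissue reference ratios for each paired pattern
#'
#' States per pattern (normal, tumor): P1 = (balanced, alt-skewed);
#' P2 = (ref-skewed, balanced); P3 = (ref-skewed, alt-skewed);
#' P4 = (balanced, ref-skewed); P5 = (alt-skewed, balanced);
#' P6 = (alt-skewed, ref-skewed); no-change = (balanced, balanced).
#'
#' @param pattern character vector of pattern labels.
#' @param effect_ratio reference ratio of the ref-skewed state.
#' @return data.frame with `normal_ratio` and `tumor_ratio`.
#' @export
pattern_ratios <- function(pattern, effect_ratio = 0.75) {
  hi <- effect_ratio
  lo <- 1 - effect_ratio
  normal <- c("P1" = 0.5, "P2" = hi, "P3" = hi,
              "P4" = 0.5, "P5" = lo, "P6" = lo, "no-change" = 0.5)
  tumor <- c("P1" = lo, "P2" = 0.5, "P3" = lo,
             "P4" = hi, "P5" = 0.5, "P6" = hi, "no-change" = 0.5)
  data.frame(normal_ratio = unname(normal[pattern]),
             tumor_ratio = unname(tumor[pattern]))
}

#' Compose a true allelic ratio with a mapping bias
#'
#' Bias acts on the odds scale: the observed reference-read probability is
#' `odds(r) * odds(b)` renormalized, so a balanced locus (r = 0.5) is observed
#' at exactly the pair's bias ratio b, and the true ratio is recoverable by
#' [bias_invert()].
#'
#' @param r true reference-allele ratio.
#' @param b pair bias (expected ratio at balanced loci).
#' @return observed reference-read probability.
#' @export
bias_compose <- function(r, b) {
  (r * b) / (r * b + (1 - r) * (1 - b))
}

#' @rdname bias_compose
#' @param p observed reference-read probability.
#' @export
bias_invert <- function(p, b) {
  (p * (1 - b)) / (p * (1 - b) + (1 - p) * b)
}
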