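#' Exact two-sided binomial test for allele-specific expression
#'
#' Tests whether the reference-read count departs from the expected reference
#' ratio p0 (the site's nucleotide-pair mapping-bias estimate, 0.5 when
#' unbiased). The two-sided p-value is the exact "minimum-likelihood" sum:
#' the total probability of all outcomes whose point probability does not
#' exceed that of the observed count (with a 1e-7 relative tolerance for
#' floating-point ties, as in standard exact-test implementations).
#'
#' @param ref reference-read count(s).
#' @param n informative depth(s) (ref + alt).
#' @param p0 expected reference ratio(s) under no ASE.
#' @return data.frame with `p_value` and `direction`
#'   (`"REF"` if ref/n > p0 else `"ALT"`; `"BAL"` when ref/n == p0 exactly).
#'   Zero-depth sites get NA p-values.
#' @export
binomial_ase <- function(ref, n, p0 = 0.5) {
  m <- max(length(ref), length(n), length(p0))
  ref <- rep_len(ref, m); n <- rep_len(n, m); p0 <- rep_len(p0, m)
  p_value <- vapply(seq_len(m), function(i) {
    if (is.na(n[i]) || n[i] <= 0) return(NA_real_)
    d <- dbinom(0:n[i], n[i], p0[i])
    min(1, sum(d[d <= d[ref[i] + 1L] * (1 + 1e-7)]))
  }, numeric(1))
  ratio <- ifelse(n > 0, ref / n, NA_real_)
  direction <- ifelse(is.na(ratio), NA_character_,
                      ifelse(ratio > p0, "REF",
                             ifelse(ratio < p0, "ALT", "BAL")))
  data.frame(p_value = p_value, direction = direction,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg selection with the dual ASE threshold
#'
#' Computes BH q-values and flags a site as significant ASE only when both
#' conditions hold: raw p < `p_max` and q <= `fdr` (the conjunctive
#' "p < 0.005 at FDR 5%" rule). Applied within one sample and universe of
#' sites.
#'
#' @param p numeric p-values in `[0, 1]` (NAs propagate).
#' @param p_max raw p-value ceiling (default 0.005).
#' @param fdr FDR level (default 0.05).
#' @return data.frame with `q_value` and `significant`.
#' @export
fdr_select <- function(p, p_max = 0.005, fdr = 0.05) {
  if (length(p) == 0) {
    return(data.frame(q_value = numeric(0), significant = logical(0)))
  }
  q <- p.adjust(p, method = "BH")
  data.frame(q_value = q,
             significant = !is.na(p) & p < p_max & q <= fdr)
}

#' SNP-level ASE calls for one sample
#'
#' Runs [binomial_ase()] at each filtered het site with its pair-specific p0,
#' applies [fdr_select()] across the sample's sites, and assigns the
#' directional state: `REF` or `ALT` only for significant sites, `BAL`
#' otherwise. Zero-information sites are skipped and logged.
#'
#' @param counts filtered allele-count data.frame for one sample.
#' @param bias a `bias_model` (or NULL for p0 = 0.5 everywhere).
#' @param p_max,fdr thresholds as in [fdr_select()].
#' @return data.frame of site keys plus `ref_ratio`, `p0`, `p_value`,
#'   `q_value`, `significant`, `state`; attribute `"skipped"` logs
#'   zero-depth sites.
#' @export
ase_calls <- function(counts, bias = NULL, p_max = 0.005, fdr = 0.05) {
  validate_allele_counts(counts)
  n <- counts$refCount + counts$altCount
  p0 <- bias_p0(bias, counts$refAllele, counts$altAllele)
  log <- new_log()
  if (any(n == 0)) log <- add_log(log, counts$variantID[n == 0], "zero_informative_reads")
  bt <- binomial_ase(counts$refCount, n, p0)
  sel <- fdr_select(bt$p_value, p_max = p_max, fdr = fdr)
  state <- ifelse(sel$significant, bt$direction, "BAL")
  out <- cbind(
    counts[, intersect(c("contig", "position", "variantID", "refAllele",
                         "altAllele", "refCount", "altCount",
                         "sample", "patient", "tissue", "gene"),
                       names(counts)), drop = FALSE],
    data.frame(ref_ratio = ifelse(n > 0, counts$refCount / n, NA_real_),
               p0 = p0, p_value = bt$p_value, q_value = sel$q_value,
               significant = sel$significant, state = state,
               stringsAsFactors = FALSE))
  out <- out[n > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- log
  out
}

#' Gene-level ASE by pseudo-phased aggregation
#'
#' Aggregates the heterozygous SNPs of one gene in one sample following the
#' MBASED-style pseudo-phasing protocol: each site's major allele is the one
#' with the higher RNA read count (ties break to reference), the major
#' haplotype collects those alleles, and the gene's major allele frequency
#' (MAF) is the summed major-allele count over the summed informative depth.
#' Significance is calibrated by Monte Carlo: each replicate redraws every
#' site binomially at its bias p0, re-derives the major haplotype, and the
#' p-value is the smoothed fraction of replicates whose MAF reaches the
#' observed one — so the post-hoc maximisation inherent in pseudo-phasing is
#' built into the null. The haplotype label is `reference` when the major
#' haplotype holds more reference than alternative alleles, `alternative`
#' in the opposite case, `ambiguous` on ties.
#'
#' @param counts allele-count data.frame for one gene and sample (zero-count
#'   sites are excluded).
#' @param bias a `bias_model` or NULL.
#' @param n_mc number of Monte-Carlo replicates (>= 100 recommended; fewer
#'   warns).
#' @param seed integer seed for the replicate stream.
#' @param maf_min,p_max MAF and p-value thresholds for the ASE flag
#'   (defaults 0.7 and 0.05).
#' @return one-row data.frame: `n_sites`, `major_count`, `total_count`,
#'   `maf`, `mc_p`, `haplotype`, `ase` (flag before FDR; see
#'   [gene_ase_table()] for the cohort-level FDR pass).
#' @export
gene_ase <- function(counts, bias = NULL, n_mc = 10000, seed = 1L,
                     maf_min = 0.7, p_max = 0.05) {
  if (n_mc < 100) warning("n_mc < 100 gives a coarse Monte-Carlo p-value")
  n <- counts$refCount + counts$altCount
  counts <- counts[n > 0, , drop = FALSE]
  n <- n[n > 0]
  if (nrow(counts) == 0) stop("gene_ase needs at least one informative site")
  p0 <- bias_p0(bias, counts$refAllele, counts$altAllele)

  major <- pmax(counts$refCount, counts$altCount)
  major_is_ref <- counts$refCount >= counts$altCount  # tie -> reference
  maf <- sum(major) / sum(n)
  n_ref <- sum(major_is_ref)
  n_alt <- sum(!major_is_ref)
  haplotype <- if (n_ref > n_alt) "reference"
               else if (n_alt > n_ref) "alternative" else "ambiguous"

  set.seed(seed)
  k <- length(n)
  ref_rep <- matrix(rbinom(n_mc * k, rep(n, each = n_mc),
                           rep(p0, each = n_mc)), nrow = n_mc)
  major_rep <- pmax(ref_rep, matrix(rep(n, each = n_mc), nrow = n_mc) - ref_rep)
  maf_rep <- rowSums(major_rep) / sum(n)
  mc_p <- (1 + sum(maf_rep >= maf)) / (n_mc + 1)

  data.frame(n_sites = k, major_count = sum(major), total_count = sum(n),
             maf = maf, mc_p = mc_p, haplotype = haplotype,
             ase = maf > maf_min & mc_p < p_max,
             stringsAsFactors = FALSE)
}

#' Gene-level ASE across all genes of one sample, with FDR control
#'
#' Runs [gene_ase()] per gene and applies BH across the sample's genes; the
#' final ASE flag requires MAF > `maf_min`, Monte-Carlo p < `p_max`, and
#' q <= `fdr`.
#'
#' @param counts allele-count data.frame for one sample with a `gene` column.
#' @inheritParams gene_ase
#' @param fdr FDR level across genes (default 0.05).
#' @return data.frame with one row per gene (gene seeds derive from `seed`
#'   and the gene index, so results are order-invariant per gene set).
#' @export
gene_ase_table <- function(counts, bias = NULL, n_mc = 10000, seed = 1L,
                           maf_min = 0.7, p_max = 0.05, fdr = 0.05) {
  stopifnot(!is.null(counts$gene))
  genes <- sort(unique(counts$gene))
  res <- do.call(rbind, lapply(seq_along(genes), function(i) {
    g <- gene_ase(counts[counts$gene == genes[i], , drop = FALSE], bias,
                  n_mc = n_mc, seed = sub_seed(seed, 2L, i),
                  maf_min = maf_min, p_max = p_max)
    cbind(data.frame(gene = genes[i], stringsAsFactors = FALSE), g)
  }))
  q <- p.adjust(res$mc_p, method = "BH")
  res$q_value <- q
  res$ase <- res$maf > maf_min & res$mc_p < p_max & q <= fdr
  res
}

#' Proportion of significant ASE calls within a site universe
#'
#' @param calls [ase_calls()] output for one sample.
#' @param universe optional logical vector (or index) restricting the sites,
#'   e.g. membership in the tumor-suppressor census; default all sites.
#' @return proportion of significant calls; NA with a warning when the
#'   universe is empty.
#' @export
proportion_ase <- function(calls, universe = NULL) {
  x <- if (is.null(universe)) calls else calls[universe, , drop = FALSE]
  if (nrow(x) == 0) {
    warning("empty site universe; proportion undefined")
    return(NA_real_)
  }
  mean(x$significant)
}
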