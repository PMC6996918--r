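#' @importFrom stats pbinom dbinom p.adjust fisher.test wilcox.test ks.test
NULL

#' Filtering and genotype-calling thresholds
#'
#' Defaults follow the pipeline's published settings: sites need at least 20
#' informative reads and 4 reads per allele, and must fall in regions of
#' perfect 50bp mapability; DNA genotype calls need depth >= 8, allelic depth
#' of 2 or more, variant allele frequency >= 0.2, and a variant-support p below
#' 0.01 (one-sided binomial against the sequencing error rate). Mapping and
#' base quality minima (20/30, MQ 14 for genotyping) are metadata here: counts
#' arrive pre-extracted, the read-level filters having been applied upstream.
#'
#' @param min_site_depth minimum ref + alt reads per site.
#' @param min_allele_depth minimum reads per allele.
#' @param min_mapq,min_baseq read-level minima recorded for provenance.
#' @param mapability_threshold required 50bp mapability score.
#' @param gt_min_depth,gt_min_allele_depth,gt_min_vaf,gt_p,gt_min_mapq
#'   genotype-calling thresholds.
#' @param gt_error_rate sequencing error rate for the variant-support test.
#' @param hom_alt_vaf VAF at or above which a supported variant is called
#'   homozygous-alternative rather than heterozygous.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_site_depth = 20,
                          min_allele_depth = 4,
                          min_mapq = 20, min_baseq = 30,
                          mapability_threshold = 1,
                          gt_min_depth = 8, gt_min_allele_depth = 2,
                          gt_min_vaf = 0.2, gt_p = 0.01, gt_min_mapq = 14,
                          gt_error_rate = 0.01,
                          hom_alt_vaf = 0.8) {
  cfg <- as.list(environment())
  stopifnot(min_site_depth > 0, min_allele_depth > 0,
            gt_min_vaf > 0, gt_min_vaf < 1, gt_p > 0)
  class(cfg) <- "filter_config"
  cfg
}

#' Filter allele-count sites for ASE analysis
#'
#' Retains sites with at least `min_site_depth` informative reads
#' (ref + alt), at least `min_allele_depth` reads on *each* allele, and —
#' when a mapability track is supplied — position inside an interval of
#' mapability equal to `mapability_threshold`. Thresholds are inclusive
#' (minima). Every rejection is logged with a machine-readable reason; the
#' operation is idempotent.
#'
#' @param counts validated allele-count data.frame.
#' @param cfg a [filter_config()].
#' @param mapability optional data.frame from [read_mapability_bed()]
#'   (0-based half-open intervals with a `score` column).
#' @return filtered data.frame with attribute `"rejections"` (a data.frame of
#'   id, reason).
#' @export
filter_sites <- function(counts, cfg = filter_config(), mapability = NULL) {
  validate_allele_counts(counts)
  log <- new_log()
  informative <- counts$refCount + counts$altCount
  drop_depth <- informative < cfg$min_site_depth
  drop_allele <- !drop_depth & (counts$refCount < cfg$min_allele_depth |
                                counts$altCount < cfg$min_allele_depth)
  drop_map <- rep(FALSE, nrow(counts))
  if (!is.null(mapability)) {
    ok <- mapability$score >= cfg$mapability_threshold
    keep_iv <- mapability[ok, , drop = FALSE]
    drop_map <- !vapply(seq_len(nrow(counts)), function(i) {
      any(keep_iv$contig == counts$contig[i] &
          keep_iv$start0 < counts$position[i] &
          counts$position[i] <= keep_iv$end0)
    }, logical(1))
    drop_map <- drop_map & !drop_depth & !drop_allele
  }
  if (any(drop_depth)) log <- add_log(log, counts$variantID[drop_depth], "min_site_depth")
  if (any(drop_allele)) log <- add_log(log, counts$variantID[drop_allele], "min_allele_depth")
  if (any(drop_map)) log <- add_log(log, counts$variantID[drop_map], "mapability")
  out <- counts[!(drop_depth | drop_allele | drop_map), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- log
  out
}

#' Call genotypes from DNA allele counts
#'
#' Threshold-based variant calling on per-site DNA counts. A variant is
#' supported when informative depth >= `gt_min_depth`, alt reads >=
#' `gt_min_allele_depth`, VAF >= `gt_min_vaf`, and a one-sided binomial test
#' of the alt count against the sequencing error rate gives p < `gt_p`.
#' Supported variants with VAF >= `hom_alt_vaf` are called `hom-alt`,
#' otherwise `het`; unsupported sites with adequate depth are `hom-ref`;
#' sites below the depth minimum are `no-call`. Calls are row-order
#' invariant.
#'
#' @param dna_counts allele-count data.frame with `assay == "DNA"` (or no
#'   assay column, in which case DNA is assumed as declared by the caller).
#' @param cfg a [filter_config()].
#' @return data.frame of the input site keys plus `vaf`, `variant_p`, and
#'   `genotype` in `c("hom-ref", "het", "hom-alt", "no-call")`.
#' @export
call_genotypes <- function(dna_counts, cfg = filter_config()) {
  validate_allele_counts(dna_counts)
  if (!is.null(dna_counts$assay) && any(dna_counts$assay != "DNA")) {
    stop("genotypes are called from DNA counts only")
  }
  n <- dna_counts$refCount + dna_counts$altCount
  vaf <- ifelse(n > 0, dna_counts$altCount / n, NA_real_)
  # one-sided: could this many alt reads arise from sequencing error alone?
  variant_p <- pbinom(dna_counts$altCount - 1L, n, cfg$gt_error_rate,
                      lower.tail = FALSE)
  supported <- n >= cfg$gt_min_depth &
    dna_counts$altCount >= cfg$gt_min_allele_depth &
    !is.na(vaf) & vaf >= cfg$gt_min_vaf &
    variant_p < cfg$gt_p
  genotype <- ifelse(n < cfg$gt_min_depth, "no-call",
              ifelse(supported & vaf >= cfg$hom_alt_vaf, "hom-alt",
              ifelse(supported, "het", "hom-ref")))
  cbind(dna_counts[, intersect(c("contig", "position", "variantID",
                                 "refAllele", "altAllele", "sample"),
                               names(dna_counts)), drop = FALSE],
        data.frame(vaf = vaf, variant_p = variant_p, genotype = genotype,
                   stringsAsFactors = FALSE))
}

#' Fit the nucleotide-pair mapping-bias model
#'
#' For each of the 12 ordered ref->alt pairs, the expected reference ratio p0
#' is the pooled reference-read fraction over that pair's heterozygous sites:
#' p0 = sum(ref) / sum(ref + alt). Pairs observed at fewer than
#' `min_sites_per_pair` sites fall back to 0.5. Estimation is per sample by
#' default (mapping bias is library-specific); pass counts from one sample,
#' or pool across samples explicitly via `pooled = TRUE` on a multi-sample
#' table.
#'
#' @param het_counts filtered allele-count data.frame at heterozygous sites.
#' @param min_sites_per_pair minimum sites for a pair-specific estimate.
#' @param pooled allow a multi-sample table to be pooled into one model.
#' @return list of class `bias_model` with `p0` (named vector over the 12
#'   pairs), `n_sites`, `n_reads`, and `fallback` (logical per pair).
#' @export
fit_bias_model <- function(het_counts, min_sites_per_pair = 50,
                           pooled = FALSE) {
  if (!pooled && !is.null(het_counts$sample) &&
      length(unique(het_counts$sample)) > 1) {
    stop("multiple samples supplied; fit per sample or set pooled = TRUE")
  }
  if (nrow(het_counts) == 0) {
    warning("no heterozygous sites; returning all-fallback bias model")
  }
  pair <- paste0(het_counts$refAllele, ">", het_counts$altAllele)
  p0 <- setNames(rep(0.5, 12), NUCLEOTIDE_PAIRS)
  n_sites <- setNames(integer(12), NUCLEOTIDE_PAIRS)
  n_reads <- setNames(numeric(12), NUCLEOTIDE_PAIRS)
  for (pr in NUCLEOTIDE_PAIRS) {
    idx <- which(pair == pr)
    n_sites[pr] <- length(idx)
    n_reads[pr] <- sum(het_counts$refCount[idx] + het_counts$altCount[idx])
    if (length(idx) >= min_sites_per_pair && n_reads[pr] > 0) {
      p0[pr] <- sum(het_counts$refCount[idx]) / n_reads[pr]
      # degenerate pools (all-ref or all-alt) would put p0 on the boundary
      p0[pr] <- min(max(p0[pr], 1e-6), 1 - 1e-6)
    }
  }
  structure(list(p0 = p0, n_sites = n_sites, n_reads = n_reads,
                 fallback = n_sites < min_sites_per_pair),
            class = "bias_model")
}

#' Look up the expected reference ratio for sites under a bias model
#'
#' @param bias a `bias_model` (or NULL for the flat 0.5 null).
#' @param ref_allele,alt_allele single-base allele vectors.
#' @return numeric p0 vector.
#' @export
bias_p0 <- function(bias, ref_allele, alt_allele) {
  if (is.null(bias)) return(rep(0.5, length(ref_allele)))
  unname(bias$p0[paste0(ref_allele, ">", alt_allele)])
}
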