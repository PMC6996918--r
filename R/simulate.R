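#' @importFrom stats rbinom rnbinom rpois runif rnorm
NULL

draw_depth <- function(n, model) {
  if (is.infinite(model$dispersion)) {
    rep(as.integer(round(model$mean)), n)
  } else {
    rnbinom(n, size = model$dispersion, mu = model$mean)
  }
}

# Deterministic gene panel shared by all patients: gene coordinates, exon
# models, the heterozygous SNP panel, and one skipping event per gene.
# Stream: sub_seed(seed, 0).
build_gene_panel <- function(cfg) {
  set.seed(sub_seed(cfg$seed, 0L))
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  contigs <- paste0("chr", (seq_len(cfg$n_genes) - 1L) %% 4L + 1L)
  idx_on_contig <- stats::ave(seq_len(cfg$n_genes), contigs,
                              FUN = seq_along)
  gene_start <- 10000L + (idx_on_contig - 1L) * 20000L
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  n_exons <- sample(4:8, cfg$n_genes, replace = TRUE)

  exon_len <- 150L
  intron_len <- 400L
  exons <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(i) {
    starts <- gene_start[i] + (seq_len(n_exons[i]) - 1L) * (exon_len + intron_len)
    data.frame(gene = genes[i], contig = contigs[i], strand = strand[i],
               start = starts, end = starts + exon_len - 1L,
               exon_index = seq_len(n_exons[i]), stringsAsFactors = FALSE)
  }))

  bases <- c("A", "C", "G", "T")
  snps <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(i) {
    k <- sample(cfg$snps_per_gene[1]:cfg$snps_per_gene[2], 1)
    k <- min(k, n_exons[i])
    in_exons <- sort(sample(seq_len(n_exons[i]), k))
    ex <- exons[exons$gene == genes[i], ]
    pos <- ex$start[in_exons] + exon_len %/% 2L
    pair <- sample(NUCLEOTIDE_PAIRS, k, replace = TRUE)
    ra <- substr(pair, 1, 1)
    aa <- substr(pair, 3, 3)
    stopifnot(all(ra %in% bases), all(aa %in% bases))
    data.frame(gene = genes[i], contig = contigs[i],
               position = pos,
               variantID = sprintf("%s_snp%d", genes[i], seq_len(k)),
               refAllele = ra, altAllele = aa, pair = pair,
               stringsAsFactors = FALSE)
  }))

  skip_exon <- pmax(2L, pmin(n_exons - 1L,
                             1L + sample.int(6L, cfg$n_genes, replace = TRUE)))
  events <- data.frame(gene = genes, event_id = paste0(genes, "_ev1"),
                       skipped_exon_index = skip_exon,
                       stringsAsFactors = FALSE)

  gene_tbl <- data.frame(gene = genes, contig = contigs, strand = strand,
                         start = gene_start,
                         end = gene_start + (n_exons - 1L) * (exon_len + intron_len) +
                           exon_len - 1L,
                         n_exons = n_exons, stringsAsFactors = FALSE)
  list(genes = gene_tbl, exons = exons, snps = snps, events = events)
}

#' Simulate a paired normal/tumor cohort with planted ASE patterns
#'
#' Generates every input the downstream pipeline consumes, with known truth:
#' RNA and DNA allele-count tables for matched normal/tumor samples, a phased
#' genotype VCF, exon models, isoform (ISO1 split-read) and antisense count
#' tables, tumor copy-number segments, gene-level methylation values, and a
#' per-site truth table.
#'
#' Per patient x gene, a paired pattern is drawn from `pattern_mix`; tumor-ASE
#' loci (P1/P3/P4/P6) are apportioned among mechanisms `cnv`,
#' `skipping+antisense`, and `pure-regulatory` by `cnv_fraction` /
#' `skip_fraction`. RNA reference counts are binomial at the planted ratio
#' composed with the nucleotide-pair mapping bias ([bias_compose()]); DNA
#' counts are balanced except at CNV loci, where the allelic ratio follows the
#' planted copy state (bias-free: the bias model targets RNA-read mapping).
#' Skipping loci scale tumor ISO1 counts by `skip_fold` and antisense counts
#' by `antisense_coupling * skip_fold`.
#'
#' Randomness is organised in documented streams derived from the master seed
#' via [sub_seed()]: the gene panel uses stream (0); patient i, gene g uses
#' stream (1, i, g). Adding patients or genes therefore never perturbs draws
#' of earlier units, and identical configs yield byte-identical outputs.
#'
#' @param cfg a [sim_config()].
#' @return list of class `lofase_sim` with elements `rna_counts`,
#'   `dna_counts` (long tables with `patient`, `tissue`, `sample`, `gene`
#'   columns appended to the canonical allele-count columns), `vcf_sites`,
#'   `vcf_gt`, `genes`, `exons`, `events`, `isoform`, `antisense`,
#'   `segments`, `methylation`, `truth`, and `config`.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  panel <- build_gene_panel(cfg)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  tumor_patterns <- c("P1", "P3", "P4", "P6")

  rna <- list(); dna <- list(); iso <- list(); anti <- list()
  segs <- list(); meth <- list(); truth <- list()
  k <- 0L
  for (i in seq_len(cfg$n_patients)) {
    pat <- patients[i]
    for (g in seq_len(cfg$n_genes)) {
      set.seed(sub_seed(cfg$seed, 1L, i, g))
      gene <- panel$genes$gene[g]
      sn <- panel$snps[panel$snps$gene == gene, , drop = FALSE]
      pattern <- sample(names(cfg$pattern_mix), 1, prob = cfg$pattern_mix)
      mech <- if (pattern %in% tumor_patterns) {
        u <- runif(1)
        if (u < cfg$cnv_fraction) "cnv"
        else if (u < cfg$cnv_fraction + cfg$skip_fraction) "skipping+antisense"
        else "pure-regulatory"
      } else if (pattern %in% c("P2", "P5")) "pure-regulatory" else "none"
      r <- pattern_ratios(pattern, cfg$effect_ratio)
      b <- unname(cfg$bias_table[sn$pair])

      ns <- nrow(sn)
      k <- k + 1L
      for (tissue in c("normal", "tumor")) {
        ratio <- if (tissue == "normal") r$normal_ratio else r$tumor_ratio
        n_rna <- draw_depth(ns, cfg$rna_depth)
        ref_rna <- rbinom(ns, n_rna, bias_compose(ratio, b))
        rna[[length(rna) + 1L]] <- data.frame(
          contig = sn$contig, position = sn$position,
          variantID = sn$variantID, refAllele = sn$refAllele,
          altAllele = sn$altAllele, refCount = ref_rna,
          altCount = n_rna - ref_rna, totalCount = n_rna,
          patient = pat, tissue = tissue,
          sample = paste0(pat, "_", tissue), gene = gene,
          stringsAsFactors = FALSE)

        dna_ratio <- 0.5
        if (tissue == "tumor" && mech == "cnv") {
          cn_ratio <- cfg$cnv_major / (cfg$cnv_major + cfg$cnv_minor)
          dna_ratio <- if (r$tumor_ratio > 0.5) cn_ratio else 1 - cn_ratio
        }
        n_dna <- draw_depth(ns, cfg$dna_depth)
        ref_dna <- rbinom(ns, n_dna, dna_ratio)
        dna[[length(dna) + 1L]] <- data.frame(
          contig = sn$contig, position = sn$position,
          variantID = sn$variantID, refAllele = sn$refAllele,
          altAllele = sn$altAllele, refCount = ref_dna,
          altCount = n_dna - ref_dna, totalCount = n_dna,
          patient = pat, tissue = tissue,
          sample = paste0(pat, "_", tissue), gene = gene,
          stringsAsFactors = FALSE)
      }

      skip_mult <- if (mech == "skipping+antisense") cfg$skip_fold else 1
      as_mult <- if (mech == "skipping+antisense")
        cfg$antisense_coupling * cfg$skip_fold else 1
      ev <- panel$events[g, ]
      lam_iso <- cfg$iso1_rate * cfg$library_size
      lam_as <- cfg$antisense_rate * cfg$library_size
      iso[[k]] <- data.frame(
        gene = gene, event_id = ev$event_id,
        skipped_exon_index = ev$skipped_exon_index,
        sample = paste0(pat, c("_normal", "_tumor")),
        iso1_count = c(rpois(1, lam_iso), rpois(1, lam_iso * skip_mult)),
        library_size = cfg$library_size, stringsAsFactors = FALSE)
      anti[[k]] <- data.frame(
        event_id = ev$event_id,
        sample = paste0(pat, c("_normal", "_tumor")),
        donor_antisense = c(rpois(1, lam_as), rpois(1, lam_as * as_mult)),
        acceptor_antisense = c(rpois(1, lam_as), rpois(1, lam_as * as_mult)),
        library_size = cfg$library_size, stringsAsFactors = FALSE)

      if (mech == "cnv") {
        major <- cfg$cnv_major; minor <- cfg$cnv_minor
      } else {
        major <- 1L; minor <- 1L
      }
      segs[[k]] <- data.frame(
        sample = paste0(pat, "_tumor"), contig = panel$genes$contig[g],
        start = panel$genes$start[g] - 500L,
        end = panel$genes$end[g] + 500L,
        major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)

      m_norm <- runif(1, 0.1, 0.6)
      m_tum <- pmin(0.95, m_norm * exp(rnorm(1, 0, 0.05)))
      meth[[k]] <- data.frame(
        gene = gene, sample = paste0(pat, c("_normal", "_tumor")),
        value = c(m_norm, m_tum), stringsAsFactors = FALSE)

      truth[[k]] <- data.frame(
        variantID = sn$variantID, patient = pat, gene = gene,
        pattern = pattern, mechanism = mech,
        normal_ratio = r$normal_ratio, tumor_ratio = r$tumor_ratio,
        stringsAsFactors = FALSE)
    }
  }

  gt <- matrix("0|1", nrow = nrow(panel$snps), ncol = cfg$n_patients,
               dimnames = list(NULL, patients))
  structure(list(
    rna_counts = do.call(rbind, rna),
    dna_counts = do.call(rbind, dna),
    vcf_sites = data.frame(contig = panel$snps$contig,
                           position = panel$snps$position,
                           id = panel$snps$variantID,
                           ref = panel$snps$refAllele,
                           alt = panel$snps$altAllele,
                           stringsAsFactors = FALSE),
    vcf_gt = gt,
    genes = panel$genes,
    exons = panel$exons,
    events = panel$events,
    isoform = do.call(rbind, iso),
    antisense = do.call(rbind, anti),
    segments = do.call(rbind, segs),
    methylation = do.call(rbind, meth),
    truth = do.call(rbind, truth),
    config = cfg
  ), class = "lofase_sim")
}

#' Simulate null sites with no allele-specific expression
#'
#' Reference counts are binomial at the nucleotide-pair bias p0 alone, so any
#' test computed with the true p0 sees a pure null; used for type-I-error and
#' calibration checks.
#'
#' @param n_sites number of sites (pairs are cycled through the 12 ordered
#'   nucleotide pairs).
#' @param depth_model list(mean, dispersion) as in [sim_config()].
#' @param bias_table named p0 vector over the 12 pairs.
#' @param seed integer seed.
#' @return allele-count data.frame with `pair` and `p0` columns appended.
#' @export
simulate_null_sites <- function(n_sites, depth_model = list(mean = 100, dispersion = 5),
                                bias_table = default_bias_table(),
                                seed = 1L) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (is.null(depth_model$mean) || depth_model$mean <= 0) {
    stop("depth_model mean must be positive")
  }
  set.seed(sub_seed(seed, 9L))
  pair <- NUCLEOTIDE_PAIRS[(seq_len(n_sites) - 1L) %% 12L + 1L]
  p0 <- unname(bias_table[pair])
  n <- draw_depth(n_sites, depth_model)
  ref <- rbinom(n_sites, n, p0)
  data.frame(contig = "chr1", position = seq_len(n_sites) * 1000L,
             variantID = sprintf("null_%06d", seq_len(n_sites)),
             refAllele = substr(pair, 1, 1), altAllele = substr(pair, 3, 3),
             refCount = ref, altCount = n - ref, totalCount = n,
             pair = pair, p0 = p0, stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits the on-disk interface of the pipeline: per-sample allele-count TSVs
#' (RNA and DNA), a phased genotype VCF, BED12 exon models, and the isoform /
#' antisense / segment / methylation / truth TSVs.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir` invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "lofase_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(sim$rna_counts$sample)) {
    write_allele_counts(sim$rna_counts[sim$rna_counts$sample == s, ],
                        file.path(dir, paste0("rna_", s, ".tsv")))
    write_allele_counts(sim$dna_counts[sim$dna_counts$sample == s, ],
                        file.path(dir, paste0("dna_", s, ".tsv")))
  }
  write_gt_vcf(sim$vcf_sites, sim$vcf_gt, file.path(dir, "genotypes.vcf"))
  write_exon_bed12(sim$exons, file.path(dir, "exons.bed12"))
  write_tsv(sim$isoform, file.path(dir, "isoform_counts.tsv"))
  write_tsv(sim$antisense, file.path(dir, "antisense_counts.tsv"))
  write_tsv(sim$segments, file.path(dir, "segments.tsv"))
  write_tsv(sim$methylation, file.path(dir, "methylation.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
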