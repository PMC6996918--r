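#' Compare normal vs tumor per-patient ASE proportions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test on the two vectors of
#' per-patient proportions of significant ASE sites. The default treats the
#' vectors as unpaired distributions of proportions; `paired = TRUE` gives
#' the signed-rank variant.
#'
#' @param normal_proportions,tumor_proportions numeric vectors (one value per
#'   patient).
#' @param paired use the paired Wilcoxon signed-rank test.
#' @return list `statistic` (U, or V when paired) and `p_value`.
#' @export
compare_groups <- function(normal_proportions, tumor_proportions,
                           paired = FALSE) {
  if (length(normal_proportions) < 2 || length(tumor_proportions) < 2) {
    stop("compare_groups needs at least two proportions per group")
  }
  wt <- suppressWarnings(
    wilcox.test(tumor_proportions, normal_proportions,
                alternative = "two.sided", paired = paired))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-pattern precision and recall against planted truth
#'
#' @param pairs classified paired sites with `variantID`, `patient`,
#'   `pattern`.
#' @param truth truth table with `variantID`, `patient`, `pattern`.
#' @return data.frame per pattern P1..P6: `n_truth`, `n_pred`, `tp`,
#'   `precision`, `recall` (NA when undefined).
#' @export
evaluate_patterns <- function(pairs, truth) {
  key_pred <- paste(pairs$patient, pairs$variantID)
  key_truth <- paste(truth$patient, truth$variantID)
  tr <- truth$pattern[match(key_pred, key_truth)]
  do.call(rbind, lapply(PATTERN_LEVELS, function(p) {
    pred_p <- pairs$pattern == p
    truth_p <- !is.na(tr) & tr == p
    tp <- sum(pred_p & truth_p)
    data.frame(pattern = p, n_truth = sum(truth_p), n_pred = sum(pred_p),
               tp = tp,
               precision = if (sum(pred_p) > 0) tp / sum(pred_p) else NA_real_,
               recall = if (sum(truth_p) > 0) tp / sum(truth_p) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Mechanism recovery against planted truth
#'
#' Evaluates the mechanism detectors directly against the generator's truth
#' labels. DNA concordance is scored per site over planted tumor-ASE loci
#' with informative DNA depth at or above `min_dna_depth`: sensitivity on
#' CNV-driven loci, false-positive rate on pure-regulatory loci (whose DNA
#' is balanced). Exon-skipping detection is scored per patient x gene locus
#' over all loci with an isoform event: precision and recall of the
#' `exon_skipping` flag for planted `skipping+antisense` loci, and recall of
#' the joint `antisense_supported` flag.
#'
#' @param sim a `lofase_sim` bundle with truth.
#' @param min_dna_depth DNA depth floor for the concordance evaluation
#'   (default 40).
#' @param fold_min fold threshold passed to [skipping_antisense()].
#' @return list `dna` (sensitivity, fpr, n_cnv, n_reg) and `skipping`
#'   (precision, recall, antisense_recall, n_truth, n_pred).
#' @export
evaluate_mechanisms <- function(sim, min_dna_depth = 40, fold_min = 1.5) {
  tr <- sim$truth
  rna_t <- sim$rna_counts[sim$rna_counts$tissue == "tumor", ]
  dna_t <- sim$dna_counts[sim$dna_counts$tissue == "tumor", ]
  key <- function(x) paste(x$patient, x$variantID)
  ir <- match(key(tr), key(rna_t))
  id <- match(key(tr), key(dna_t))
  flag <- dna_concordance(rna_t$refCount[ir], rna_t$altCount[ir],
                          dna_t$refCount[id], dna_t$altCount[id],
                          min_dna_depth = min_dna_depth)
  is_cnv <- tr$mechanism == "cnv"
  is_reg <- tr$mechanism == "pure-regulatory" &
    tr$pattern %in% c("P1", "P3", "P4", "P6")
  dna <- list(sensitivity = mean(flag[is_cnv], na.rm = TRUE),
              fpr = mean(flag[is_reg], na.rm = TRUE),
              n_cnv = sum(is_cnv & !is.na(flag)),
              n_reg = sum(is_reg & !is.na(flag)))

  loci <- unique(tr[, c("patient", "gene", "mechanism")])
  iso <- sim$isoform; anti <- sim$antisense
  key_iso <- paste(iso$gene, iso$sample)
  gi_n <- match(paste(loci$gene, paste0(loci$patient, "_normal")), key_iso)
  gi_t <- match(paste(loci$gene, paste0(loci$patient, "_tumor")), key_iso)
  key_anti <- paste(anti$event_id, anti$sample)
  ai_n <- match(paste(iso$event_id[gi_n], paste0(loci$patient, "_normal")), key_anti)
  ai_t <- match(paste(iso$event_id[gi_t], paste0(loci$patient, "_tumor")), key_anti)
  sk <- skipping_antisense(iso$iso1_count[gi_n], iso$iso1_count[gi_t],
                           iso$library_size[gi_n], iso$library_size[gi_t],
                           anti$donor_antisense[ai_n], anti$donor_antisense[ai_t],
                           anti$acceptor_antisense[ai_n],
                           anti$acceptor_antisense[ai_t],
                           fold_min = fold_min)
  truth_skip <- loci$mechanism == "skipping+antisense"
  tp <- sum(sk$exon_skipping & truth_skip)
  skipping <- list(
    precision = if (sum(sk$exon_skipping) > 0) tp / sum(sk$exon_skipping)
                else NA_real_,
    recall = if (sum(truth_skip) > 0) tp / sum(truth_skip) else NA_real_,
    antisense_recall = if (sum(truth_skip) > 0)
      sum(sk$antisense_supported & truth_skip) / sum(truth_skip)
      else NA_real_,
    n_truth = sum(truth_skip), n_pred = sum(sk$exon_skipping))
  list(dna = dna, skipping = skipping)
}

#' Run the full paired-cohort pipeline on a simulated (or assembled) bundle
#'
#' Executes the stages in dependency order: site filtering, per-sample bias
#' model estimation, SNP-level ASE calls, paired pattern classification,
#' gene-level ASE, mechanism attribution (DNA concordance, copy-number
#' duplication, methylation, splice-site overlap, exon skipping + antisense),
#' and cohort summaries. Stages whose inputs are absent from the bundle are
#' skipped with an explicit message. Reruns with the same bundle and
#' parameters are deterministic.
#'
#' @param sim a `lofase_sim` bundle (or a list with the same elements; only
#'   `rna_counts` is mandatory).
#' @param filter a [filter_config()].
#' @param bias_min_sites minimum sites per nucleotide pair for the bias model
#'   (default 10; pairs below it fall back to 0.5).
#' @param bias_scope `"pooled"` (default) estimates one bias model from the
#'   het sites of the whole cohort — the genome-wide, population-level
#'   reading, and much less noisy on small panels; `"per-sample"` fits one
#'   model per library.
#' @param p_max,fdr,fisher_max,maf_min ASE thresholds (defaults 0.005, 0.05,
#'   0.05, 0.7).
#' @param n_mc Monte-Carlo replicates for gene-level ASE (0 skips the gene
#'   stage).
#' @param seed seed for the gene-level Monte-Carlo streams.
#' @param outdir optional directory: summary tables and a JSON run manifest
#'   are written there.
#' @return list of class `lofase_run`: `bias_models`, `calls` (per-sample
#'   ASE calls), `pairs` (per-patient classified paired sites, pooled),
#'   `gene_ase`, `attributions`, `pattern_summary`, `mechanism_summary`,
#'   `ase_proportions`, `group_test`, `truth_eval` (when truth is present),
#'   `manifest`.
#' @export
run_pipeline <- function(sim, filter = filter_config(),
                         bias_min_sites = 10,
                         bias_scope = c("pooled", "per-sample"),
                         p_max = 0.005, fdr = 0.05, fisher_max = 0.05,
                         maf_min = 0.7, n_mc = 0, seed = 1L,
                         outdir = NULL) {
  stopifnot(!is.null(sim$rna_counts))
  bias_scope <- match.arg(bias_scope)
  rna <- sim$rna_counts
  samples <- unique(rna$sample)

  filtered <- lapply(samples, function(s)
    filter_sites(rna[rna$sample == s, , drop = FALSE], filter))
  names(filtered) <- samples
  pooled_bias <- if (bias_scope == "pooled") {
    fit_bias_model(do.call(rbind, filtered),
                   min_sites_per_pair = bias_min_sites, pooled = TRUE)
  } else NULL

  calls <- list(); bias_models <- list()
  for (s in samples) {
    cs <- filtered[[s]]
    bias_models[[s]] <- pooled_bias %||%
      fit_bias_model(cs, min_sites_per_pair = bias_min_sites)
    calls[[s]] <- ase_calls(cs, bias_models[[s]], p_max = p_max, fdr = fdr)
  }

  patients <- unique(rna$patient)
  pairs <- do.call(rbind, lapply(patients, function(p) {
    nc <- calls[[paste0(p, "_normal")]]
    tc <- calls[[paste0(p, "_tumor")]]
    if (is.null(nc) || is.null(tc)) return(NULL)
    pp <- paired_patterns(nc, tc, fisher_max = fisher_max)
    if (nrow(pp) == 0) return(NULL)
    cbind(data.frame(patient = p, stringsAsFactors = FALSE), pp)
  }))

  gene_tbl <- NULL
  if (n_mc > 0) {
    gene_tbl <- do.call(rbind, lapply(seq_along(samples), function(i) {
      cs <- filtered[[samples[i]]]
      if (nrow(cs) == 0) return(NULL)
      g <- gene_ase_table(cs, bias_models[[samples[i]]], n_mc = n_mc,
                          seed = sub_seed(seed, 3L, i), maf_min = maf_min,
                          p_max = 0.05, fdr = fdr)
      cbind(data.frame(sample = samples[i], stringsAsFactors = FALSE), g)
    }))
  }

  attributions <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    ase_sites <- pairs[pairs$pattern %in% PATTERN_LEVELS, , drop = FALSE]
    if (nrow(ase_sites) > 0) {
      attributions <- attribute_mechanisms(ase_sites, sim)
    }
  }

  pattern_summary <- if (!is.null(pairs) && nrow(pairs) > 0) {
    pattern_table(pairs, gene_roles = sim$gene_roles)
  } else NULL

  mech_summary <- if (!is.null(attributions) && nrow(attributions) > 0) {
    mechanism_summary(attributions)
  } else NULL

  props <- do.call(rbind, lapply(patients, function(p) {
    data.frame(
      patient = p,
      normal = proportion_ase(calls[[paste0(p, "_normal")]]),
      tumor = proportion_ase(calls[[paste0(p, "_tumor")]]),
      stringsAsFactors = FALSE)
  }))
  group_test <- if (nrow(props) >= 2) {
    compare_groups(props$normal, props$tumor)
  } else NULL

  truth_eval <- NULL
  if (!is.null(sim$truth) && !is.null(pairs)) {
    truth_eval <- list(patterns = evaluate_patterns(pairs, sim$truth))
  }

  manifest <- list(
    n_samples = length(samples), n_patients = length(patients),
    thresholds = list(p_max = p_max, fdr = fdr, fisher_max = fisher_max,
                      maf_min = maf_min, bias_min_sites = bias_min_sites),
    n_mc = n_mc, seed = seed,
    n_paired_sites = if (is.null(pairs)) 0L else nrow(pairs))

  run <- structure(list(bias_models = bias_models, calls = calls,
                        pairs = pairs, gene_ase = gene_tbl,
                        attributions = attributions,
                        pattern_summary = pattern_summary,
                        mechanism_summary = mech_summary,
                        ase_proportions = props, group_test = group_test,
                        truth_eval = truth_eval, manifest = manifest),
                   class = "lofase_run")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(pairs)) write_tsv(pairs, file.path(outdir, "paired_patterns.tsv"))
    if (!is.null(pattern_summary))
      write_tsv(pattern_summary, file.path(outdir, "pattern_summary.tsv"))
    if (!is.null(attributions))
      write_tsv(attributions, file.path(outdir, "mechanism_attributions.tsv"))
    if (!is.null(gene_tbl)) write_tsv(gene_tbl, file.path(outdir, "gene_ase.tsv"))
    write_tsv(props, file.path(outdir, "ase_proportions.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' Attribute candidate mechanisms to classified paired ASE sites
#'
#' For every site with a paired pattern P1-P6, evaluates each available
#' mechanism flag against the bundle's auxiliary tables; missing tables skip
#' the corresponding flag with a message.
#'
#' @param ase_sites classified paired sites (pattern in P1..P6) with
#'   `patient`, `variantID`, `gene`, tumor counts.
#' @param sim the input bundle (`dna_counts`, `segments`, `methylation`,
#'   `exons`, `isoform`, `antisense` are used when present).
#' @return per-site attribution data.frame.
#' @export
attribute_mechanisms <- function(ase_sites, sim) {
  out <- ase_sites[, c("patient", "variantID", "gene", "pattern")]
  out$site_key <- paste(out$patient, out$variantID)

  if (!is.null(sim$dna_counts)) {
    dna_t <- sim$dna_counts[sim$dna_counts$tissue == "tumor", , drop = FALSE]
    idx <- match(out$site_key, paste(dna_t$patient, dna_t$variantID))
    out$dna_explained <- dna_concordance(
      ase_sites$refCount_tumor, ase_sites$altCount_tumor,
      dna_t$refCount[idx], dna_t$altCount[idx])
  } else message("mechanisms: DNA counts absent, DNA stage skipped")

  site_pos <- NULL
  if (!is.null(sim$rna_counts)) {
    rc <- unique(sim$rna_counts[, c("variantID", "contig", "position")])
    site_pos <- rc[match(ase_sites$variantID, rc$variantID), ]
  }
  if (!is.null(sim$segments) && !is.null(site_pos)) {
    out$cnv_duplication <- vapply(seq_len(nrow(out)), function(i) {
      seg <- sim$segments[sim$segments$sample ==
                          paste0(out$patient[i], "_tumor"), , drop = FALSE]
      cnv_duplication_check(site_pos$contig[i], site_pos$position[i], seg)
    }, logical(1))
  } else message("mechanisms: segments absent, CNV stage skipped")

  if (!is.null(sim$methylation)) {
    mn <- sim$methylation
    kn <- paste(mn$gene, mn$sample)
    nv <- mn$value[match(paste(out$gene, paste0(out$patient, "_normal")), kn)]
    tv <- mn$value[match(paste(out$gene, paste0(out$patient, "_tumor")), kn)]
    out$methylation_changed <- methylation_change(nv, tv)
  } else message("mechanisms: methylation absent, stage skipped")

  if (!is.null(sim$exons) && !is.null(site_pos)) {
    out$splice_site_overlap <- splice_site_overlap(
      site_pos$contig, site_pos$position, sim$exons)
  } else message("mechanisms: exon models absent, splice-site stage skipped")

  if (!is.null(sim$isoform)) {
    iso <- sim$isoform
    anti <- sim$antisense
    key_iso <- paste(iso$gene, iso$sample)
    gi_n <- match(paste(out$gene, paste0(out$patient, "_normal")), key_iso)
    gi_t <- match(paste(out$gene, paste0(out$patient, "_tumor")), key_iso)
    dn <- dt <- an <- at <- rep(NA_real_, nrow(out))
    if (!is.null(anti)) {
      key_anti <- paste(anti$event_id, anti$sample)
      ai_n <- match(paste(iso$event_id[gi_n], paste0(out$patient, "_normal")),
                    key_anti)
      ai_t <- match(paste(iso$event_id[gi_t], paste0(out$patient, "_tumor")),
                    key_anti)
      dn <- anti$donor_antisense[ai_n]; dt <- anti$donor_antisense[ai_t]
      an <- anti$acceptor_antisense[ai_n]; at <- anti$acceptor_antisense[ai_t]
    }
    sk <- skipping_antisense(iso$iso1_count[gi_n], iso$iso1_count[gi_t],
                             iso$library_size[gi_n], iso$library_size[gi_t],
                             dn, dt, an, at)
    missing_event <- is.na(gi_n) | is.na(gi_t)
    sk$exon_skipping[missing_event] <- FALSE
    sk$antisense_supported[missing_event] <- FALSE
    out <- cbind(out, sk)
  } else message("mechanisms: isoform counts absent, skipping stage skipped")

  out$site_key <- NULL
  out
}
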