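#' DNA concordance: is RNA allelic imbalance explained by DNA counts?
#'
#' A site's ASE is DNA-explained when the matched DNA counts are themselves
#' significantly imbalanced (exact binomial against 0.5, p < `alpha`) *and*
#' skewed in the same direction as the RNA. Sites whose DNA depth falls below
#' the genotype-calling minimum are undetermined (NA) and excluded from
#' denominators.
#'
#' @param rna_ref,rna_alt RNA ref/alt counts.
#' @param dna_ref,dna_alt matched DNA ref/alt counts.
#' @param alpha DNA significance threshold (default 0.05).
#' @param min_dna_depth minimum informative DNA depth (default 8, the
#'   genotype-calling floor).
#' @return logical vector (`NA` = undetermined).
#' @export
dna_concordance <- function(rna_ref, rna_alt, dna_ref, dna_alt,
                            alpha = 0.05, min_dna_depth = 8) {
  n_dna <- dna_ref + dna_alt
  bt <- binomial_ase(dna_ref, n_dna, 0.5)
  rna_dir <- sign(rna_ref / (rna_ref + rna_alt) - 0.5)
  dna_dir <- sign(dna_ref / pmax(n_dna, 1) - 0.5)
  out <- !is.na(bt$p_value) & bt$p_value < alpha &
    dna_dir == rna_dir & rna_dir != 0
  out[n_dna < min_dna_depth] <- NA
  out
}

#' Copy-number duplication check at a locus
#'
#' Flags loci whose overlapping tumor segment carries a duplication with
#' unequal allele copies (total copy number > 2 and major != minor) — a DNA
#' copy state that can generate allelic imbalance. Loci with no overlapping
#' segment are FALSE.
#'
#' @param contig,position locus coordinates (1-based).
#' @param segments tumor segments `contig`, `start`, `end` (1-based
#'   inclusive), `major_cn`, `minor_cn`.
#' @return logical vector.
#' @export
cnv_duplication_check <- function(contig, position, segments) {
  vapply(seq_along(position), function(i) {
    ov <- segments$contig == contig[i] &
      segments$start <= position[i] & position[i] <= segments$end
    any(ov & segments$major_cn + segments$minor_cn > 2 &
        segments$major_cn != segments$minor_cn)
  }, logical(1))
}

#' eQTL attribution for a gene with ASE
#'
#' `eqtl_egene`: the gene has at least one known cis-eQTL. `eqtl_in_phase`:
#' some heterozygous eQTL's high-expression allele lies on the gene's
#' over-expressed haplotype and the eQTL is in linkage disequilibrium with
#' the ASE variant (r >= `r_min`). The high-expression allele follows the
#' sign of the eQTL slope (GTEx convention: the slope is the effect of the
#' alternative allele), and the over-expressed haplotype is the pseudo-phased
#' major haplotype label from [gene_ase()]. Missing LD leaves in-phase
#' undetermined (NA).
#'
#' @param haplotype gene's major-haplotype label
#'   (`"reference"`/`"alternative"`/`"ambiguous"`).
#' @param eqtls data.frame of the gene's eQTL records: `variant`, `slope`.
#' @param eqtl_gt named GT strings for the eQTL variants in this sample.
#' @param ld named numeric vector of LD r between each eQTL variant and the
#'   ASE variant (may be missing entries).
#' @param r_min LD threshold (default 0.42).
#' @return list `(eqtl_egene, eqtl_in_phase)`.
#' @export
eqtl_attribution <- function(haplotype, eqtls, eqtl_gt = NULL, ld = NULL,
                             r_min = 0.42) {
  if (is.null(eqtls) || nrow(eqtls) == 0) {
    return(list(eqtl_egene = FALSE, eqtl_in_phase = FALSE))
  }
  het <- c("0/1", "1/0", "0|1", "1|0")
  in_phase <- FALSE
  undetermined <- FALSE
  for (i in seq_len(nrow(eqtls))) {
    v <- eqtls$variant[i]
    g <- if (!is.null(eqtl_gt)) eqtl_gt[v] else NA_character_
    if (is.na(g) || !(g %in% het)) next
    high_allele <- if (eqtls$slope[i] > 0) "alternative" else "reference"
    if (haplotype %in% c("reference", "alternative") &&
        high_allele == haplotype) {
      r <- if (!is.null(ld)) ld[v] else NA_real_
      if (is.na(r)) { undetermined <- TRUE; next }
      if (abs(r) >= r_min) { in_phase <- TRUE; break }
    }
  }
  list(eqtl_egene = TRUE,
       eqtl_in_phase = if (!in_phase && undetermined) NA else in_phase)
}

#' Methylation fold-change flag
#'
#' Flags genes whose methylation differs by more than `fold_min` between
#' normal and tumor, in either direction:
#' `max(tumor/normal, normal/tumor) > fold_min`.
#'
#' @param normal_value,tumor_value gene-level methylation values (> 0; apply
#'   a pseudocount upstream if zeros occur).
#' @param fold_min fold threshold (default 1.3).
#' @return logical vector (`NA` when a value is missing).
#' @export
methylation_change <- function(normal_value, tumor_value, fold_min = 1.3) {
  fold <- pmax(tumor_value / normal_value, normal_value / tumor_value)
  ifelse(is.na(fold), NA, fold > fold_min)
}

#' Does a site fall in a canonical splice-site dinucleotide?
#'
#' Strand-aware check against the 2-base consensus donor (first two intronic
#' bases downstream of an exon in transcription order) and acceptor (last two
#' intronic bases upstream of an exon) dinucleotides of every annotated
#' intron. Sites outside any annotated gene are FALSE.
#'
#' @param contig,position site coordinates (1-based).
#' @param exons exon model data.frame (`gene`, `contig`, `strand`, `start`,
#'   `end`, 1-based inclusive) as from [read_exon_bed12()].
#' @return logical vector.
#' @export
splice_site_overlap <- function(contig, position, exons) {
  splice_pos <- do.call(rbind, lapply(split(exons, exons$gene), function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    # introns between consecutive exons, in genomic coordinates
    istart <- e$end[-nrow(e)] + 1L   # first intronic base (genomic left)
    iend <- e$start[-1L] - 1L        # last intronic base (genomic right)
    if (e$strand[1] == "+") {
      donor <- c(istart, istart + 1L)
      acceptor <- c(iend - 1L, iend)
    } else {
      donor <- c(iend, iend - 1L)
      acceptor <- c(istart + 1L, istart)
    }
    data.frame(contig = e$contig[1], pos = c(donor, acceptor),
               stringsAsFactors = FALSE)
  }))
  if (is.null(splice_pos)) return(rep(FALSE, length(position)))
  key <- paste(splice_pos$contig, splice_pos$pos)
  paste(contig, position) %in% key
}

#' Exon-skipping and antisense support at an event
#'
#' ISO1 split-read counts (reads spanning the two exons flanking the skipped
#' exon) and donor/acceptor antisense counts are normalized to counts per
#' million with pseudocount 1; `exon_skipping` requires tumor/normal ISO1
#' fold >= `fold_min`, and `antisense_supported` additionally requires both
#' the donor and acceptor antisense folds >= `fold_min` (antisense is only
#' evaluated at skipping events).
#'
#' @param iso1_normal,iso1_tumor ISO1 counts.
#' @param lib_normal,lib_tumor library sizes.
#' @param as_donor_normal,as_donor_tumor,as_acceptor_normal,as_acceptor_tumor
#'   antisense read counts at the donor/acceptor sites.
#' @param fold_min fold threshold (default 1.5).
#' @return data.frame `iso1_fold`, `antisense_donor_fold`,
#'   `antisense_acceptor_fold`, `exon_skipping`, `antisense_supported`.
#' @export
skipping_antisense <- function(iso1_normal, iso1_tumor,
                               lib_normal, lib_tumor,
                               as_donor_normal = NA, as_donor_tumor = NA,
                               as_acceptor_normal = NA, as_acceptor_tumor = NA,
                               fold_min = 1.5) {
  iso1_fold <- cpm1(iso1_tumor, lib_tumor) / cpm1(iso1_normal, lib_normal)
  donor_fold <- cpm1(as_donor_tumor, lib_tumor) / cpm1(as_donor_normal, lib_normal)
  acceptor_fold <- cpm1(as_acceptor_tumor, lib_tumor) /
    cpm1(as_acceptor_normal, lib_normal)
  skipping <- !is.na(iso1_fold) & iso1_fold >= fold_min
  antisense <- skipping & !is.na(donor_fold) & donor_fold >= fold_min &
    !is.na(acceptor_fold) & acceptor_fold >= fold_min
  data.frame(iso1_fold = iso1_fold,
             antisense_donor_fold = donor_fold,
             antisense_acceptor_fold = acceptor_fold,
             exon_skipping = skipping,
             antisense_supported = antisense)
}

#' DNA-concordance summary table (per patient, with cohort total)
#'
#' Reproduces the "ASE SNPs explained by DNA counts" layout: per patient the
#' explained count, the total ASE count, and the percentage (half-up, one
#' decimal); the total row pools the counts before taking the percentage.
#'
#' @param explained,total integer vectors per patient.
#' @param patient patient labels.
#' @param digits decimals (default 1).
#' @return data.frame with a final `Total` row.
#' @export
summarize_dna_concordance <- function(patient, explained, total, digits = 1) {
  if (length(patient) == 0) stop("empty cohort")
  pct <- round_half_up(100 * explained / total, digits)
  rbind(
    data.frame(patient = patient, explained = explained, total = total,
               percentage = pct, stringsAsFactors = FALSE),
    data.frame(patient = "Total", explained = sum(explained),
               total = sum(total),
               percentage = round_half_up(100 * sum(explained) / sum(total),
                                          digits),
               stringsAsFactors = FALSE))
}

#' Exon-skipping / antisense summary table (per pattern, with total)
#'
#' Per paired ASE pattern: total ASE SNPs, SNPs with >= 1.5x ISO1, SNPs with
#' at least 1.5x ISO1 and 1.5x antisense at both splice sites, and both
#' percentages over the pattern's total ASE SNPs (half-up, one decimal).
#'
#' @param pattern pattern labels.
#' @param total,iso1,iso1_antisense count vectors per pattern.
#' @param digits decimals (default 1).
#' @return data.frame with a final `Total` row.
#' @export
summarize_skipping <- function(pattern, total, iso1, iso1_antisense,
                               digits = 1) {
  if (length(pattern) == 0) stop("empty cohort")
  row_pct <- function(num, den) round_half_up(100 * num / den, digits)
  rbind(
    data.frame(pattern = as.character(pattern), total = total, iso1 = iso1,
               iso1_pct = row_pct(iso1, total),
               iso1_antisense = iso1_antisense,
               iso1_antisense_pct = row_pct(iso1_antisense, total),
               stringsAsFactors = FALSE),
    data.frame(pattern = "Total", total = sum(total), iso1 = sum(iso1),
               iso1_pct = row_pct(sum(iso1), sum(total)),
               iso1_antisense = sum(iso1_antisense),
               iso1_antisense_pct = row_pct(sum(iso1_antisense), sum(total)),
               stringsAsFactors = FALSE))
}

#' Cohort mechanism summary from per-site attributions
#'
#' Tallies per-patient DNA-explained proportions and per-pattern
#' skipping/antisense proportions from a per-site attribution table, plus
#' overall per-mechanism proportions over all attributed ASE sites.
#'
#' @param attributions data.frame with one row per ASE site: `patient`,
#'   `pattern`, and logical flags `dna_explained`, `cnv_duplication`,
#'   `exon_skipping`, `antisense_supported` (others optional:
#'   `eqtl_egene`, `eqtl_in_phase`, `methylation_changed`,
#'   `splice_site_overlap`).
#' @param digits decimals (default 1).
#' @return list `dna_table`, `skipping_table`, `proportions` (named vector
#'   of per-mechanism fractions over determinable sites).
#' @export
mechanism_summary <- function(attributions, digits = 1) {
  if (nrow(attributions) == 0) stop("empty cohort")
  by_pat <- split(attributions, attributions$patient)
  dna_table <- summarize_dna_concordance(
    patient = names(by_pat),
    explained = vapply(by_pat, function(x)
      sum(x$dna_explained, na.rm = TRUE), numeric(1)),
    total = vapply(by_pat, function(x)
      sum(!is.na(x$dna_explained)), numeric(1)),
    digits = digits)

  pat_levels <- intersect(PATTERN_LEVELS, unique(attributions$pattern))
  by_pattern <- split(attributions, factor(attributions$pattern, pat_levels))
  skipping_table <- summarize_skipping(
    pattern = names(by_pattern),
    total = vapply(by_pattern, nrow, numeric(1)),
    iso1 = vapply(by_pattern, function(x)
      sum(x$exon_skipping, na.rm = TRUE), numeric(1)),
    iso1_antisense = vapply(by_pattern, function(x)
      sum(x$antisense_supported, na.rm = TRUE), numeric(1)),
    digits = digits)

  flags <- intersect(c("dna_explained", "cnv_duplication", "eqtl_egene",
                       "eqtl_in_phase", "methylation_changed",
                       "splice_site_overlap", "exon_skipping",
                       "antisense_supported"),
                     names(attributions))
  proportions <- vapply(flags, function(f)
    mean(attributions[[f]], na.rm = TRUE), numeric(1))
  list(dna_table = dna_table, skipping_table = skipping_table,
       proportions = proportions)
}
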