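# Sequence-Ontology normalization for consequence synonyms seen in
# annotation exports ("non-sense", "frameshift", ...).
CONSEQUENCE_SYNONYMS <- c(
  "non-sense" = "stop_gained", "nonsense" = "stop_gained",
  "stop_gain" = "stop_gained",
  "frameshift" = "frameshift_variant",
  "splice_acceptor" = "splice_acceptor_variant",
  "splice_donor" = "splice_donor_variant",
  "whole_gene_deletion" = "transcript_ablation",
  "start_loss" = "start_lost", "stop_loss" = "stop_lost",
  "missense" = "missense_variant", "synonymous" = "synonymous_variant"
)

TRUNCATING_BASE <- c("stop_gained", "frameshift_variant",
                     "splice_acceptor_variant", "splice_donor_variant",
                     "transcript_ablation")
TRUNCATING_EXTENDED <- c(TRUNCATING_BASE, "start_lost", "stop_lost")

KNOWN_CONSEQUENCES <- c(
  TRUNCATING_EXTENDED, "missense_variant", "synonymous_variant",
  "intron_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "upstream_gene_variant", "downstream_gene_variant",
  "splice_region_variant", "intergenic_variant", "inframe_deletion",
  "inframe_insertion", "non_coding_transcript_exon_variant"
)

#' Classify variants as loss-of-function
#'
#' Deleterious (LOF) classes: the truncating consequences — nonsense
#' (stop gained), frameshift, splice acceptor/donor, whole-gene deletion —
#' and missense variants called deleterious by SIFT *and* damaging by
#' PolyPhen-2. Any variant labelled benign or likely benign by ClinVar is
#' overridden to not-LOF regardless of the other annotations. Two modes share
#' the rules but differ in the truncating set: `"population"` uses the base
#' set; `"second-hit"` extends it with start-lost and stop-lost.
#'
#' @param consequence Sequence-Ontology consequence terms (common synonyms
#'   are normalized; unknown vocabulary warns and yields not-LOF, never a
#'   silent drop).
#' @param sift SIFT labels (`"deleterious"` counts, including the
#'   low-confidence qualifier); NA for unannotated.
#' @param polyphen PolyPhen-2 labels; both `probably_damaging` and
#'   `possibly_damaging` count unless `polyphen_strict`.
#' @param clinvar ClinVar clinical significance (NA when absent).
#' @param mode `"population"` or `"second-hit"`.
#' @param polyphen_strict require `probably_damaging`.
#' @return data.frame `is_lof`, `reason` with reason in
#'   `c("truncating-class", "missense-concordant-damaging", "not-lof",
#'   "clinvar-benign-override")`.
#' @export
classify_lof <- function(consequence, sift = NA, polyphen = NA, clinvar = NA,
                         mode = c("population", "second-hit"),
                         polyphen_strict = FALSE) {
  mode <- match.arg(mode)
  m <- length(consequence)
  sift <- rep_len(tolower(as.character(sift)), m)
  polyphen <- rep_len(tolower(as.character(polyphen)), m)
  clinvar <- rep_len(tolower(as.character(clinvar)), m)
  cq <- tolower(trimws(consequence))
  if (any(!nzchar(cq) | is.na(cq))) stop("empty consequence term")
  known_syn <- cq %in% names(CONSEQUENCE_SYNONYMS)
  cq[known_syn] <- CONSEQUENCE_SYNONYMS[cq[known_syn]]
  unknown <- !(cq %in% KNOWN_CONSEQUENCES)
  if (any(unknown)) {
    warning("unknown consequence term(s) treated as not-LOF: ",
            paste(unique(cq[unknown]), collapse = ", "))
  }
  truncating_set <- if (mode == "population") TRUNCATING_BASE
                    else TRUNCATING_EXTENDED
  damaging_labels <- if (polyphen_strict) "probably_damaging"
                     else c("probably_damaging", "possibly_damaging")
  sift_del <- !is.na(sift) & grepl("^deleterious", sift)
  poly_dam <- !is.na(polyphen) & polyphen %in% damaging_labels
  benign <- !is.na(clinvar) &
    clinvar %in% c("benign", "likely_benign", "benign/likely_benign")

  reason <- rep("not-lof", m)
  reason[cq %in% truncating_set] <- "truncating-class"
  reason[cq == "missense_variant" & sift_del & poly_dam] <-
    "missense-concordant-damaging"
  reason[benign] <- "clinvar-benign-override"
  data.frame(is_lof = reason %in% c("truncating-class",
                                    "missense-concordant-damaging"),
             reason = reason, stringsAsFactors = FALSE)
}

gt_alt_dose <- function(gt) {
  # dose of the alternative allele in a bi-allelic GT string
  if (any(grepl("[2-9]", gt))) {
    stop("multi-allelic genotypes must be decomposed upstream")
  }
  clean <- gsub("[|/]", "", gt)
  dose <- vapply(strsplit(clean, ""), function(a) {
    a <- a[a != "."]
    if (length(a) == 0) NA_integer_ else sum(a == "1")
  }, integer(1))
  dose
}

#' Per-individual LOF burden over census sites in a population VCF
#'
#' Intersects LOF-classified census variants with a population VCF (matching
#' on contig + position + ref + alt, never position alone) and tallies, per
#' individual, homozygous and heterozygous LOF genotypes; per gene, the
#' carrier fraction (individuals with >= 1 LOF allele / all individuals);
#' and the distribution of individuals by number of LOF-carrying genes.
#'
#' @param census data.frame of annotated census variants with columns
#'   `contig`, `position`, `ref`, `alt`, `gene`, plus the annotation columns
#'   consumed by [classify_lof()] (`consequence`, `sift`, `polyphen`,
#'   `clinvar`).
#' @param vcf either a path to a VCF or the list returned by
#'   [read_gt_vcf()].
#' @param mode passed to [classify_lof()].
#' @return list with `burden` (individual, hom_count, het_count),
#'   `gene_carriers` (gene, carriers, carrier_fraction, sorted decreasing),
#'   `genes_per_individual` (individual, n_genes), and `matched_sites`.
#' @export
intersect_population <- function(census, vcf, mode = "population") {
  if (is.character(vcf)) vcf <- read_gt_vcf(vcf)
  lof <- classify_lof(census$consequence, census$sift, census$polyphen,
                      census$clinvar, mode = mode)
  census_lof <- census[lof$is_lof, , drop = FALSE]
  key_c <- paste(census_lof$contig, census_lof$position,
                 census_lof$ref, census_lof$alt)
  key_v <- paste(vcf$sites$contig, vcf$sites$position,
                 vcf$sites$ref, vcf$sites$alt)
  hit <- match(key_c, key_v)
  matched <- which(!is.na(hit))
  individuals <- colnames(vcf$gt)

  dose <- matrix(0L, nrow = length(matched), ncol = length(individuals))
  for (j in seq_along(matched)) {
    dose[j, ] <- gt_alt_dose(vcf$gt[hit[matched[j]], ])
  }
  hom <- colSums(dose == 2L, na.rm = TRUE)
  het <- colSums(dose == 1L, na.rm = TRUE)

  genes <- census_lof$gene[matched]
  if (length(matched) > 0) {
    carrier_by_gene <- t(vapply(split(seq_along(genes), genes), function(rows) {
      carried <- colSums(dose[rows, , drop = FALSE] >= 1L, na.rm = TRUE) > 0
      c(sum(carried), mean(carried))
    }, numeric(2)))
    gene_carriers <- data.frame(
      gene = rownames(carrier_by_gene),
      carriers = as.integer(carrier_by_gene[, 1]),
      carrier_fraction = carrier_by_gene[, 2],
      stringsAsFactors = FALSE)
    gene_carriers <- gene_carriers[order(-gene_carriers$carrier_fraction,
                                         gene_carriers$gene), ]
    rownames(gene_carriers) <- NULL
  } else {
    gene_carriers <- data.frame(gene = character(0), carriers = integer(0),
                                carrier_fraction = numeric(0),
                                stringsAsFactors = FALSE)
  }

  n_genes_per_ind <- if (length(matched) > 0) {
    vapply(seq_along(individuals), function(i) {
      length(unique(genes[dose[, i] >= 1L & !is.na(dose[, i])]))
    }, integer(1))
  } else rep(0L, length(individuals))

  list(
    burden = data.frame(individual = individuals, hom_count = as.integer(hom),
                        het_count = as.integer(het), stringsAsFactors = FALSE),
    gene_carriers = gene_carriers,
    genes_per_individual = data.frame(individual = individuals,
                                      n_genes = n_genes_per_ind,
                                      stringsAsFactors = FALSE),
    matched_sites = length(matched)
  )
}
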