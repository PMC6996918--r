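#' @importFrom utils read.table write.table head
NULL

#' Write a tab-separated table
#'
#' Plain TSV with a header row, no quoting, no row names — the dialect used by
#' every flat-file interface in this package (isoform counts, antisense counts,
#' copy-number segments, methylation, truth labels, summaries).
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

ALLELE_COUNT_COLS <- c("contig", "position", "variantID", "refAllele",
                       "altAllele", "refCount", "altCount", "totalCount")

#' Validate an allele-count table
#'
#' Enforces the structural invariants of per-site allele counts: single-base
#' alleles, non-negative counts, and refCount + altCount <= totalCount
#' (totalCount may additionally include reads carrying neither allele).
#'
#' @param x data.frame with the ASEReadCounter-style columns
#'   `contig position variantID refAllele altAllele refCount altCount totalCount`.
#' @return `x` invisibly; malformed rows raise an error naming the row number.
#' @export
validate_allele_counts <- function(x) {
  missing_cols <- setdiff(ALLELE_COUNT_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop("allele-count table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad_allele <- which(!grepl("^[ACGT]$", x$refAllele) |
                      !grepl("^[ACGT]$", x$altAllele))
  if (length(bad_allele) > 0) {
    stop("non single-base allele at row(s): ",
         paste(head(bad_allele, 5), collapse = ", "))
  }
  bad_count <- which(x$refCount < 0 | x$altCount < 0 |
                     x$refCount + x$altCount > x$totalCount)
  if (length(bad_count) > 0) {
    stop("count invariant violated (ref + alt > total or negative) at row(s): ",
         paste(head(bad_count, 5), collapse = ", "))
  }
  invisible(x)
}

#' Read a per-site allele-count table
#'
#' Reads the GATK ASEReadCounter-style TSV emitted by [simulate_cohort()] (or
#' produced upstream from RNA/WXS BAMs), validates it, and annotates the sample
#' and assay the file belongs to.
#'
#' @param path TSV path with header
#'   `contig position variantID refAllele altAllele refCount altCount totalCount`.
#' @param sample sample identifier to attach.
#' @param assay `"RNA"` or `"DNA"`.
#' @return validated data.frame with `sample` and `assay` columns appended.
#' @export
read_allele_counts <- function(path, sample = NA_character_,
                               assay = c("RNA", "DNA")) {
  assay <- match.arg(assay)
  x <- read_tsv(path)
  validate_allele_counts(x)
  x$sample <- sample
  x$assay <- assay
  x
}

#' Write an allele-count table
#'
#' Emits only the eight canonical columns; sample and assay identity live in
#' the file name, as in ASEReadCounter output.
#'
#' @param x allele-count data.frame.
#' @param path output path.
#' @export
write_allele_counts <- function(x, path) {
  validate_allele_counts(x)
  write_tsv(x[, ALLELE_COUNT_COLS], path)
}

#' Write a genotype-only VCF 4.2
#'
#' Minimal VCF emitter for GT-only records, used by the simulator and the
#' genotype caller. Sites are one row per bi-allelic SNP; genotypes are given
#' as a sites x samples character matrix of GT strings (`"0/1"`, or `"0|1"`
#' when phased).
#'
#' @param sites data.frame with columns `contig`, `position`, `id`, `ref`, `alt`.
#' @param gt character matrix (`nrow(sites)` x samples) of GT strings; column
#'   names are sample names.
#' @param path output path.
#' @export
write_gt_vcf <- function(sites, gt, path) {
  stopifnot(nrow(sites) == nrow(gt), !is.null(colnames(gt)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lofase",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  ), con)
  body <- paste(sites$contig, sites$position, sites$id, sites$ref, sites$alt,
                ".", "PASS", ".", "GT", sep = "\t")
  for (j in seq_len(ncol(gt))) body <- paste(body, gt[, j], sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Thin wrapper over [vcfR::read.vcfR()] returning the site table and the GT
#' matrix. Multi-allelic records must be decomposed upstream; a comma in ALT
#' raises an error.
#'
#' @param path VCF path (plain or gzipped).
#' @return list with `sites` (contig, position, id, ref, alt) and `gt`
#'   (sites x samples character matrix of GT strings).
#' @export
read_gt_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multi-allelic VCF records must be decomposed upstream")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, "sample"))
  list(
    sites = data.frame(contig = fix[, "CHROM"],
                       position = as.integer(fix[, "POS"]),
                       id = fix[, "ID"],
                       ref = fix[, "REF"],
                       alt = fix[, "ALT"],
                       stringsAsFactors = FALSE),
    gt = gt
  )
}

#' Write exon models as BED12
#'
#' One BED12 line per transcript; block coordinates are converted from the
#' package-internal 1-based inclusive exon table to BED's 0-based half-open
#' convention.
#'
#' @param exons data.frame with columns `gene`, `contig`, `strand`, `start`,
#'   `end` (1-based inclusive, one row per exon, exons of a gene sorted by
#'   start).
#' @param path output path.
#' @export
write_exon_bed12 <- function(exons, path) {
  lines <- vapply(split(exons, exons$gene), function(e) {
    e <- e[order(e$start), ]
    chrom_start <- min(e$start) - 1L
    chrom_end <- max(e$end)
    sizes <- e$end - e$start + 1L
    starts <- e$start - 1L - chrom_start
    paste(e$contig[1], chrom_start, chrom_end, e$gene[1], 0, e$strand[1],
          chrom_start, chrom_end, "0,0,0", nrow(e),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read BED12 exon models
#'
#' @param path BED12 path.
#' @return exon data.frame (`gene`, `contig`, `strand`, `start`, `end`,
#'   1-based inclusive).
#' @export
read_exon_bed12 <- function(path) {
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    sizes <- as.integer(strsplit(b[i, 11], ",")[[1]])
    offsets <- as.integer(strsplit(b[i, 12], ",")[[1]])
    start0 <- b[i, 2] + offsets
    data.frame(gene = b[i, 4], contig = b[i, 1], strand = b[i, 6],
               start = start0 + 1L, end = start0 + sizes,
               stringsAsFactors = FALSE)
  }))
}

#' Read a mapability BED track
#'
#' Expects BED with at least 4 columns where column 4 (or 5 if a name column
#' is present) carries the mapability score of the interval; intervals are
#' 0-based half-open.
#'
#' @param path BED path.
#' @return data.frame `contig`, `start0`, `end0`, `score`.
#' @export
read_mapability_bed <- function(path) {
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  score <- if (ncol(b) >= 5 && is.numeric(b[[5]])) b[[5]] else b[[4]]
  data.frame(contig = b[[1]], start0 = b[[2]], end0 = b[[3]],
             score = as.numeric(score), stringsAsFactors = FALSE)
}
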