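#' Classify second-hit status for one patient across genes
#'
#' Implements the two-hit consistency check for each gene carrying a
#' heterozygous loss-of-function (LOF) variant in the normal sample. The
#' second hit is, in priority order: `same_hom` — the same LOF site is
#' homozygous-alternative in the tumor; `compound_het` — a tumor-novel LOF
#' het site phased to the opposite haplotype of the normal LOF allele; `loh`
#' — a tumor copy-number segment with minor copy number 0 spanning the LOF
#' locus. Genes with no qualifying evidence are `none`. Unphased tumor-novel
#' LOF candidates are reported as `compound_candidate_unphased` rather than
#' asserted (they are not counted by [two_hit_rate()]): without phase the
#' new mutation could sit on the already-hit haplotype.
#'
#' @param variants data.frame `variantID`, `gene`, `contig`, `position`,
#'   `is_lof` (from [classify_lof()] in `"second-hit"` mode).
#' @param normal_gt,tumor_gt character vectors of GT strings named by
#'   `variantID` (`"0|1"` phased, `"0/1"` unphased); absent IDs are treated
#'   as missing genotypes.
#' @param segments tumor copy-number segments for this patient:
#'   `contig`, `start`, `end` (1-based inclusive), `major_cn`, `minor_cn`.
#' @return data.frame per gene with `verdict` and `evidence` (supporting
#'   site ids or `segment:<i>`); genes without a normal het LOF site are
#'   omitted (their verdict is trivially `none`).
#' @export
classify_second_hit <- function(variants, normal_gt, tumor_gt,
                                segments = NULL) {
  stopifnot(all(c("variantID", "gene", "contig", "position", "is_lof")
                %in% names(variants)))
  het <- c("0/1", "1/0", "0|1", "1|0")
  hom_alt <- c("1/1", "1|1")
  phased <- function(g) !is.na(g) & grepl("|", g, fixed = TRUE)
  alt_hap <- function(g) ifelse(g == "0|1", 2L, ifelse(g == "1|0", 1L, NA_integer_))

  ngt <- unname(normal_gt[variants$variantID])
  tgt <- unname(tumor_gt[variants$variantID])
  lof <- variants$is_lof

  out <- lapply(split(seq_len(nrow(variants)), variants$gene), function(rows) {
    seed_sites <- rows[lof[rows] & !is.na(ngt[rows]) & ngt[rows] %in% het]
    if (length(seed_sites) == 0) return(NULL)
    if (any(is.na(tgt[seed_sites]))) {
      warning("missing tumor genotype at normal LOF site(s): ",
              paste(variants$variantID[seed_sites[is.na(tgt[seed_sites])]],
                    collapse = ", "))
    }
    # 1) same mutation homozygous in the tumor
    sh <- seed_sites[!is.na(tgt[seed_sites]) & tgt[seed_sites] %in% hom_alt]
    if (length(sh) > 0) {
      return(data.frame(verdict = "same_hom",
                        evidence = variants$variantID[sh[1]],
                        stringsAsFactors = FALSE))
    }
    # 2) new LOF on the opposite haplotype (requires phase on both sites)
    novel <- rows[lof[rows] & !is.na(tgt[rows]) & tgt[rows] %in% het &
                  (is.na(ngt[rows]) | !(ngt[rows] %in% c(het, hom_alt)))]
    candidate <- FALSE
    for (s in seed_sites) {
      for (v in novel) {
        if (phased(ngt[s]) && phased(tgt[v])) {
          if (alt_hap(tgt[v]) != alt_hap(ngt[s])) {
            return(data.frame(
              verdict = "compound_het",
              evidence = paste(variants$variantID[s], variants$variantID[v],
                               sep = "+"),
              stringsAsFactors = FALSE))
          }
        } else candidate <- TRUE
      }
    }
    # 3) loss of the wild-type allele: minor copy number 0 over the locus
    if (!is.null(segments) && nrow(segments) > 0) {
      for (s in seed_sites) {
        ov <- which(segments$contig == variants$contig[s] &
                    segments$start <= variants$position[s] &
                    variants$position[s] <= segments$end &
                    segments$minor_cn == 0)
        if (length(ov) > 0) {
          return(data.frame(verdict = "loh",
                            evidence = paste0("segment:", ov[1]),
                            stringsAsFactors = FALSE))
        }
      }
    }
    if (candidate) {
      return(data.frame(verdict = "compound_candidate_unphased",
                        evidence = variants$variantID[seed_sites[1]],
                        stringsAsFactors = FALSE))
    }
    data.frame(verdict = "none", evidence = variants$variantID[seed_sites[1]],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(gene = character(0), verdict = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- cbind(data.frame(gene = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Fraction of patients with a confirmed second hit
#'
#' @param calls data.frame with `patient` and `verdict` (pooled
#'   [classify_second_hit()] outputs).
#' @return list: `n_patients`, `n_hit`, `fraction`, and `by_verdict`
#'   breakdown. Only `same_hom`, `compound_het`, and `loh` count as hits;
#'   unphased compound candidates do not.
#' @export
two_hit_rate <- function(calls) {
  hit_set <- c("same_hom", "compound_het", "loh")
  per_patient <- tapply(calls$verdict, calls$patient,
                        function(v) any(v %in% hit_set))
  n <- length(per_patient)
  list(n_patients = n,
       n_hit = sum(per_patient),
       fraction = if (n > 0) sum(per_patient) / n else 0,
       by_verdict = table(factor(calls$verdict,
                                 levels = c(hit_set,
                                            "compound_candidate_unphased",
                                            "none"))))
}
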