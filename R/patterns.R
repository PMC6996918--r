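#' Fisher's exact test for a paired normal/tumor allelic difference
#'
#' Two-sided Fisher exact p on the 2x2 table `[[refN, altN], [refT, altT]]`.
#' A zero margin (no reads on one allele in both samples, or an empty sample)
#' carries no information about a ratio difference; such sites return p = 1
#' and are logged.
#'
#' @param ref_n,alt_n,ref_t,alt_t count vectors (normal ref/alt, tumor
#'   ref/alt).
#' @return numeric p-value vector with attribute `"degenerate"` marking
#'   zero-margin sites.
#' @export
fisher_diff <- function(ref_n, alt_n, ref_t, alt_t) {
  m <- length(ref_n)
  degenerate <- (ref_n + ref_t == 0) | (alt_n + alt_t == 0) |
    (ref_n + alt_n == 0) | (ref_t + alt_t == 0)
  p <- vapply(seq_len(m), function(i) {
    if (degenerate[i]) return(1)
    fisher.test(matrix(c(ref_n[i], alt_n[i], ref_t[i], alt_t[i]),
                       nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  attr(p, "degenerate") <- degenerate
  p
}

PAIRED_PATTERN_LEVELS <- c(PATTERN_LEVELS, "concordant", "no-change")

#' Map per-sample ASE states to the six paired patterns
#'
#' With directional states BAL/REF/ALT in normal and tumor:
#' (BAL,ALT) -> P1, (REF,BAL) -> P2, (REF,ALT) -> P3, (BAL,REF) -> P4,
#' (ALT,BAL) -> P5, (ALT,REF) -> P6 — each requiring Fisher p < `fisher_max`,
#' otherwise `no-change`. (BAL,BAL) is `no-change`; same-direction ASE in
#' both samples ((REF,REF) or (ALT,ALT)) is `concordant` and is folded into
#' "No ASE" in summary tables.
#'
#' @param state_normal,state_tumor character vectors in
#'   `c("BAL","REF","ALT")`.
#' @param fisher_p Fisher p-values from [fisher_diff()].
#' @param fisher_max significance threshold (default 0.05).
#' @return character vector of pattern labels.
#' @export
classify_pattern <- function(state_normal, state_tumor, fisher_p,
                             fisher_max = 0.05) {
  stopifnot(all(state_normal %in% c("BAL", "REF", "ALT")),
            all(state_tumor %in% c("BAL", "REF", "ALT")))
  key <- paste(state_normal, state_tumor, sep = ",")
  map <- c("BAL,ALT" = "P1", "REF,BAL" = "P2", "REF,ALT" = "P3",
           "BAL,REF" = "P4", "ALT,BAL" = "P5", "ALT,REF" = "P6")
  pattern <- unname(map[key])
  pattern[is.na(pattern)] <- ifelse(
    state_normal[is.na(pattern)] == "BAL", "no-change", "concordant")
  pattern[pattern %in% PATTERN_LEVELS & fisher_p >= fisher_max] <- "no-change"
  pattern
}

#' Pair normal and tumor ASE calls and classify paired patterns
#'
#' Joins the two per-sample call tables on site identity, computes the
#' Fisher difference test, and applies [classify_pattern()]. Only sites
#' present (post-filter) in both samples are classified; every classified
#' site receives exactly one label.
#'
#' @param normal_calls,tumor_calls [ase_calls()] outputs for the matched
#'   normal and tumor samples.
#' @param fisher_max Fisher threshold (default 0.05).
#' @return data.frame with per-site counts, states, `fisher_p`, and
#'   `pattern`.
#' @export
paired_patterns <- function(normal_calls, tumor_calls, fisher_max = 0.05) {
  keep <- intersect(c("variantID", "gene", "refCount", "altCount",
                      "state", "ref_ratio"), names(normal_calls))
  m <- merge(normal_calls[, keep, drop = FALSE],
             tumor_calls[, setdiff(keep, "gene"), drop = FALSE],
             by = "variantID", suffixes = c("_normal", "_tumor"))
  if (nrow(m) == 0) return(m)
  m$fisher_p <- as.numeric(fisher_diff(m$refCount_normal, m$altCount_normal,
                                       m$refCount_tumor, m$altCount_tumor))
  m$pattern <- classify_pattern(m$state_normal, m$state_tumor, m$fisher_p,
                                fisher_max = fisher_max)
  m
}

#' Cohort pattern percentage table
#'
#' Percentage of paired sites in each pattern (P1-P6) and in "No ASE"
#' (no-change plus concordant), for each gene-role category: all sites,
#' census genes (any role), and the tumor-suppressor / oncogene / fusion
#' subsets. Columns sum to 100 up to rounding; empty categories are omitted
#' with a message.
#'
#' @param sites classified paired sites (rows pooled over patients) with a
#'   `gene` column.
#' @param gene_roles optional data.frame `gene`, `role` with role in
#'   `c("TSG", "oncogene", "fusion", "other")`; genes with role != "other"
#'   form the census category.
#' @param digits decimal places (half-up rounding, default 1).
#' @return data.frame: `pattern` rows P1..P6 + `No ASE`, one percentage
#'   column per non-empty category.
#' @export
pattern_table <- function(sites, gene_roles = NULL, digits = 1) {
  pat <- ifelse(sites$pattern %in% PATTERN_LEVELS, sites$pattern, "No ASE")
  pat <- factor(pat, levels = c(PATTERN_LEVELS, "No ASE"))
  cats <- list("Total SNPs" = rep(TRUE, nrow(sites)))
  if (!is.null(gene_roles)) {
    role <- gene_roles$role[match(sites$gene, gene_roles$gene)]
    cats[["All COSMIC"]] <- !is.na(role) & role != "other"
    cats[["TSG"]] <- !is.na(role) & role == "TSG"
    cats[["Oncogene"]] <- !is.na(role) & role == "oncogene"
    cats[["Fusion"]] <- !is.na(role) & role == "fusion"
  }
  out <- data.frame(pattern = levels(pat), stringsAsFactors = FALSE)
  for (nm in names(cats)) {
    sel <- cats[[nm]]
    if (!any(sel)) {
      message("pattern_table: empty category omitted: ", nm)
      next
    }
    out[[nm]] <- round_half_up(100 * as.numeric(table(pat[sel])) / sum(sel),
                               digits)
  }
  out
}
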