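test_that("DNA concordance needs significance and matching direction", {
  # DNA 30/10 is significantly REF-skewed (exact p ~ 0.0022), RNA 75/25 REF
  expect_true(dna_concordance(75, 25, 30, 10))
  # balanced DNA explains nothing
  expect_false(dna_concordance(80, 20, 20, 20))
  # significant DNA skew in the opposite direction does not explain
  expect_false(dna_concordance(75, 25, 10, 30))
  # shallow DNA is undetermined, not false
  expect_true(is.na(dna_concordance(75, 25, 3, 2)))
})

test_that("copy-number duplication needs >2 total copies and unequal alleles", {
  seg <- function(maj, min) data.frame(contig = "chr1", start = 1L,
                                       end = 1000L, major_cn = maj,
                                       minor_cn = min)
  expect_true(cnv_duplication_check("chr1", 500L, seg(2L, 1L)))
  expect_false(cnv_duplication_check("chr1", 500L, seg(1L, 1L)))
  expect_false(cnv_duplication_check("chr1", 500L, seg(2L, 2L)))
  expect_false(cnv_duplication_check("chr2", 500L, seg(2L, 1L)))  # no overlap
})

test_that("eQTL attribution requires an eGene, phase agreement, and LD", {
  expect_equal(eqtl_attribution("alternative", NULL),
               list(eqtl_egene = FALSE, eqtl_in_phase = FALSE))
  eq <- data.frame(variant = "rs10", slope = 0.8, stringsAsFactors = FALSE)
  # het eQTL, alt allele drives high expression, alt haplotype over-expressed
  r <- eqtl_attribution("alternative", eq, eqtl_gt = c(rs10 = "0|1"),
                        ld = c(rs10 = 0.5))
  expect_equal(r, list(eqtl_egene = TRUE, eqtl_in_phase = TRUE))
  # below the LD threshold
  r2 <- eqtl_attribution("alternative", eq, eqtl_gt = c(rs10 = "0|1"),
                         ld = c(rs10 = 0.3))
  expect_equal(r2, list(eqtl_egene = TRUE, eqtl_in_phase = FALSE))
  # wrong haplotype
  r3 <- eqtl_attribution("reference", eq, eqtl_gt = c(rs10 = "0|1"),
                         ld = c(rs10 = 0.5))
  expect_equal(r3$eqtl_in_phase, FALSE)
  # negative slope points at the reference allele
  eqn <- data.frame(variant = "rs10", slope = -0.8, stringsAsFactors = FALSE)
  r4 <- eqtl_attribution("reference", eqn, eqtl_gt = c(rs10 = "0|1"),
                         ld = c(rs10 = 0.5))
  expect_true(r4$eqtl_in_phase)
  # homozygous eQTL cannot be phase-informative
  r5 <- eqtl_attribution("alternative", eq, eqtl_gt = c(rs10 = "1|1"),
                         ld = c(rs10 = 0.9))
  expect_false(r5$eqtl_in_phase)
  # missing LD leaves in-phase undetermined
  r6 <- eqtl_attribution("alternative", eq, eqtl_gt = c(rs10 = "0|1"))
  expect_true(is.na(r6$eqtl_in_phase))
})

test_that("methylation change uses a symmetric fold threshold", {
  expect_true(methylation_change(0.20, 0.30))   # 1.5-fold up
  expect_false(methylation_change(0.25, 0.30))  # 1.2-fold
  expect_false(methylation_change(0.4, 0.4))
  expect_false(methylation_change(0.39, 0.30))  # exactly 1.3-fold: not > 1.3
  expect_true(methylation_change(0.40, 0.30))   # 1.33-fold down
  expect_true(is.na(methylation_change(NA, 0.3)))
})

test_that("splice-site overlap hits the intronic dinucleotides, strand-aware", {
  exons <- data.frame(gene = "G", contig = "chr1", strand = "+",
                      start = c(100L, 200L), end = c(150L, 250L),
                      stringsAsFactors = FALSE)
  # intron spans 151..199: donor 151-152, acceptor 198-199
  expect_true(splice_site_overlap("chr1", 151L, exons))
  expect_true(splice_site_overlap("chr1", 152L, exons))
  expect_true(splice_site_overlap("chr1", 199L, exons))
  expect_false(splice_site_overlap("chr1", 153L, exons))
  expect_false(splice_site_overlap("chr1", 120L, exons))  # mid-exon
  expect_false(splice_site_overlap("chr2", 151L, exons))  # outside any gene

  # minus strand mirrors donor/acceptor roles; the dinucleotide union is the
  # mirror image of the plus-strand gene laid out in reversed coordinates
  minus <- data.frame(gene = "Gm", contig = "chr1", strand = "-",
                      start = c(100L, 200L), end = c(150L, 250L),
                      stringsAsFactors = FALSE)
  for (pos in c(151L, 152L, 198L, 199L)) {
    expect_true(splice_site_overlap("chr1", pos, minus))
  }
  expect_false(splice_site_overlap("chr1", 197L, minus))
})

test_that("skipping and antisense flags follow the 1.5-fold rule", {
  # equal library sizes; folds in CPM with pseudocount 1
  r <- skipping_antisense(iso1_normal = 99, iso1_tumor = 379,
                          lib_normal = 1e5, lib_tumor = 1e5,
                          as_donor_normal = 49, as_donor_tumor = 89,
                          as_acceptor_normal = 49, as_acceptor_tumor = 84)
  expect_equal(r$iso1_fold, 3.8)
  expect_equal(r$antisense_donor_fold, 1.8)
  expect_equal(r$antisense_acceptor_fold, 1.7)
  expect_true(r$exon_skipping)
  expect_true(r$antisense_supported)

  # skipping without antisense support
  r2 <- skipping_antisense(99, 379, 1e5, 1e5, 49, 60, 49, 89)
  expect_true(r2$exon_skipping)
  expect_false(r2$antisense_supported)

  # below the ISO1 threshold nothing is flagged, antisense cannot rescue
  r3 <- skipping_antisense(99, 119, 1e5, 1e5, 9, 99, 9, 99)
  expect_false(r3$exon_skipping)
  expect_false(r3$antisense_supported)

  # library-size normalization matters
  r4 <- skipping_antisense(99, 99, 1e5, 5e4)
  expect_equal(r4$iso1_fold, 2)
  expect_true(r4$exon_skipping)
})

test_that("DNA-concordance summary reproduces its own count ratios", {
  tab <- summarize_dna_concordance(patient = c("A", "B"),
                                   explained = c(0, 7), total = c(10, 20))
  expect_equal(tab$percentage, c(0.0, 35.0, round(100 * 7 / 30, 1)))
  expect_equal(tab$patient[3], "Total")
  expect_error(summarize_dna_concordance(character(0), numeric(0), numeric(0)),
               "empty")
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(round_half_up(35.15, 1), 35.2)  # round() would give 35.1
  expect_equal(round_half_up(46.25, 1), 46.3)
  expect_equal(round_half_up(c(0.04, 0.05, 0.06) * 100, 0), c(4, 5, 6))
})

test_that("mechanism_summary cells equal hand-computed ratios", {
  att <- data.frame(
    patient = rep(c("A", "B"), each = 4),
    pattern = rep(c("P1", "P1", "P4", "P4"), 2),
    dna_explained = c(TRUE, FALSE, TRUE, NA, FALSE, FALSE, TRUE, TRUE),
    exon_skipping = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    antisense_supported = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                            FALSE),
    stringsAsFactors = FALSE)
  s <- mechanism_summary(att)
  expect_equal(s$dna_table$explained, c(2, 2, 4))
  expect_equal(s$dna_table$total, c(3, 4, 7))  # NA excluded from denominators
  expect_equal(s$dna_table$percentage,
               round_half_up(100 * c(2/3, 2/4, 4/7), 1))
  p1 <- s$skipping_table[s$skipping_table$pattern == "P1", ]
  expect_equal(p1$total, 4)
  expect_equal(p1$iso1, 3)
  expect_equal(p1$iso1_pct, 75.0)
  expect_equal(p1$iso1_antisense, 2)
  expect_error(mechanism_summary(att[0, ]), "empty")
})
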