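test_that("truncating, missense, and benign-override rules classify correctly", {
  v <- classify_lof(
    consequence = c("stop_gained", "missense_variant", "missense_variant",
                    "synonymous_variant", "frameshift_variant",
                    "missense_variant"),
    sift = c(NA, "deleterious", "deleterious", NA, NA, "tolerated"),
    polyphen = c(NA, "probably_damaging", "probably_damaging", NA, NA,
                 "probably_damaging"),
    clinvar = c(NA, NA, "benign", NA, NA, NA))
  expect_equal(v$is_lof, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(v$reason,
               c("truncating-class", "missense-concordant-damaging",
                 "clinvar-benign-override", "not-lof", "truncating-class",
                 "not-lof"))
})

test_that("second-hit mode extends the truncating set to start/stop lost", {
  pop <- classify_lof(c("start_lost", "stop_lost"), mode = "population")
  sh <- classify_lof(c("start_lost", "stop_lost"), mode = "second-hit")
  expect_equal(pop$is_lof, c(FALSE, FALSE))
  expect_equal(sh$is_lof, c(TRUE, TRUE))
})

test_that("consequence synonyms normalize and unknown vocabulary warns", {
  v <- classify_lof(c("non-sense", "frameshift", "splice_acceptor"))
  expect_true(all(v$is_lof))
  expect_warning(out <- classify_lof("made_up_term"), "unknown consequence")
  expect_false(out$is_lof)
  expect_error(classify_lof(""), "empty consequence")
})

test_that("ClinVar benign dominates every other annotation", {
  cons <- c("stop_gained", "frameshift_variant", "missense_variant",
            "splice_donor_variant")
  for (cq in cons) {
    for (cv in c("benign", "likely_benign", "Benign")) {
      v <- classify_lof(cq, sift = "deleterious",
                        polyphen = "probably_damaging", clinvar = cv)
      expect_false(v$is_lof)
      expect_equal(v$reason, "clinvar-benign-override")
    }
  }
})

make_pop_vcf <- function(path, sites, gt) {
  write_gt_vcf(sites, gt, path)
  path
}

test_that("population intersection counts burden and carrier fractions", {
  dir <- withr::local_tempdir()
  sites <- data.frame(contig = "chr1", position = c(100L, 200L),
                      id = c("rs1", "rs2"), ref = c("A", "C"),
                      alt = c("T", "G"), stringsAsFactors = FALSE)
  gt <- matrix(c("0/0", "0/1", "1/1",    # rs1 over 3 individuals
                 "0/0", "0/0", "0/0"),   # rs2 (non-LOF, should not count)
               nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("I1", "I2", "I3")))
  vcf <- make_pop_vcf(file.path(dir, "pop.vcf"), sites, gt)
  census <- data.frame(contig = "chr1", position = c(100L, 200L),
                       ref = c("A", "C"), alt = c("T", "G"),
                       gene = c("TSG1", "TSG2"),
                       consequence = c("stop_gained", "synonymous_variant"),
                       sift = NA, polyphen = NA, clinvar = NA,
                       stringsAsFactors = FALSE)
  res <- intersect_population(census, vcf)
  expect_equal(res$matched_sites, 1L)
  expect_equal(res$burden$hom_count, c(0L, 0L, 1L))
  expect_equal(res$burden$het_count, c(0L, 1L, 0L))
  expect_equal(res$gene_carriers$carrier_fraction, 2 / 3)
  expect_equal(res$genes_per_individual$n_genes, c(0L, 1L, 1L))
})

test_that("no overlapping sites yields an all-zero burden", {
  dir <- withr::local_tempdir()
  sites <- data.frame(contig = "chr9", position = 5L, id = "rsX",
                      ref = "G", alt = "A", stringsAsFactors = FALSE)
  gt <- matrix("0/1", 1, 2, dimnames = list(NULL, c("I1", "I2")))
  vcf <- make_pop_vcf(file.path(dir, "pop.vcf"), sites, gt)
  census <- data.frame(contig = "chr1", position = 100L, ref = "A",
                       alt = "T", gene = "TSG1",
                       consequence = "stop_gained", sift = NA,
                       polyphen = NA, clinvar = NA, stringsAsFactors = FALSE)
  res <- intersect_population(census, vcf)
  expect_equal(res$matched_sites, 0L)
  expect_true(all(res$burden$hom_count == 0L & res$burden$het_count == 0L))
})

test_that("carrier fractions match Hardy-Weinberg expectation", {
  set.seed(81)
  n_ind <- 300
  q <- c(0.1, 0.3, 0.5)
  sites <- data.frame(contig = "chr1", position = c(100L, 200L, 300L),
                      id = paste0("rs", 1:3), ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  gt <- matrix(NA_character_, 3, n_ind,
               dimnames = list(NULL, sprintf("I%03d", 1:n_ind)))
  for (j in 1:3) {
    dose <- rbinom(n_ind, 2, q[j])
    gt[j, ] <- c("0/0", "0/1", "1/1")[dose + 1]
  }
  dir <- withr::local_tempdir()
  vcf <- make_pop_vcf(file.path(dir, "pop.vcf"), sites, gt)
  census <- data.frame(contig = "chr1", position = c(100L, 200L, 300L),
                       ref = "A", alt = "T", gene = paste0("G", 1:3),
                       consequence = "stop_gained", sift = NA, polyphen = NA,
                       clinvar = NA, stringsAsFactors = FALSE)
  res <- intersect_population(census, vcf)
  cf <- res$gene_carriers
  for (j in 1:3) {
    expected <- 1 - (1 - q[j])^2
    se <- sqrt(expected * (1 - expected) / n_ind)
    expect_lt(abs(cf$carrier_fraction[cf$gene == paste0("G", j)] - expected),
              3 * se)
  }
})

test_that("burden is invariant to record and sample order", {
  dir <- withr::local_tempdir()
  sites <- data.frame(contig = "chr1", position = c(100L, 200L),
                      id = c("rs1", "rs2"), ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  gt <- matrix(c("0/1", "1/1", "0/0", "0/1"), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("I1", "I2")))
  census <- data.frame(contig = "chr1", position = c(100L, 200L),
                       ref = "A", alt = "T", gene = c("G1", "G2"),
                       consequence = "stop_gained", sift = NA, polyphen = NA,
                       clinvar = NA, stringsAsFactors = FALSE)
  v1 <- make_pop_vcf(file.path(dir, "a.vcf"), sites, gt)
  v2 <- make_pop_vcf(file.path(dir, "b.vcf"), sites[2:1, ],
                     gt[2:1, c("I2", "I1")])
  r1 <- intersect_population(census, v1)
  r2 <- intersect_population(census, v2)
  b1 <- r1$burden[order(r1$burden$individual), ]
  b2 <- r2$burden[order(r2$burden$individual), ]
  rownames(b1) <- rownames(b2) <- NULL
  expect_equal(b1, b2)
  expect_equal(r1$gene_carriers, r2$gene_carriers)
})

test_that("multi-allelic genotypes are rejected", {
  expect_error(lofase:::gt_alt_dose(c("0/1", "1/2")), "multi-allelic")
})
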