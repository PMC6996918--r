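test_that("degenerate pattern mixes force the planted ratios", {
  flat_bias <- setNames(rep(0.5, 12), NUCLEOTIDE_PAIRS)
  cfg <- sim_config(n_patients = 2, n_genes = 10,
                    pattern_mix = c(P1 = 0, P2 = 0, P3 = 0, P4 = 0,
                                    P5 = 0, P6 = 0, "no-change" = 1),
                    bias_table = flat_bias, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$normal_ratio == 0.5))
  expect_true(all(sim$truth$tumor_ratio == 0.5))

  cfg4 <- sim_config(n_patients = 2, n_genes = 10, effect_ratio = 0.75,
                     pattern_mix = c(P1 = 0, P2 = 0, P3 = 0, P4 = 1,
                                     P5 = 0, P6 = 0, "no-change" = 0),
                     seed = 3)
  sim4 <- simulate_cohort(cfg4)
  expect_true(all(sim4$truth$pattern == "P4"))
  expect_true(all(sim4$truth$normal_ratio == 0.5))
  expect_true(all(sim4$truth$tumor_ratio == 0.75))
})

test_that("count conservation and one truth record per locus hold", {
  sim <- small_sim()
  expect_true(all(sim$rna_counts$refCount + sim$rna_counts$altCount ==
                  sim$rna_counts$totalCount))
  expect_true(all(sim$dna_counts$refCount + sim$dna_counts$altCount ==
                  sim$dna_counts$totalCount))
  key <- paste(sim$truth$patient, sim$truth$variantID)
  expect_false(any(duplicated(key)))
  # every emitted RNA locus has its truth record
  expect_true(all(paste(sim$rna_counts$patient, sim$rna_counts$variantID)
                  %in% key))
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_patients = 3, n_genes = 15, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$rna_counts, s2$rna_counts)
  expect_identical(s1$isoform, s2$isoform)
  expect_identical(s1$truth, s2$truth)
})

test_that("adding patients does not perturb earlier patients' draws", {
  cfg_small <- sim_config(n_patients = 3, n_genes = 15, seed = 42)
  cfg_big <- sim_config(n_patients = 5, n_genes = 15, seed = 42)
  s_small <- simulate_cohort(cfg_small)
  s_big <- simulate_cohort(cfg_big)
  first3 <- s_big$rna_counts[s_big$rna_counts$patient %in%
                             c("P01", "P02", "P03"), ]
  rownames(first3) <- NULL
  rownames(s_small$rna_counts) <- NULL
  expect_identical(s_small$rna_counts, first3)
})

test_that("observed ref ratios at no-change loci match the bias table", {
  cfg <- sim_config(n_patients = 20, n_genes = 100, seed = 7)
  sim <- simulate_cohort(cfg)
  null_ids <- sim$truth[sim$truth$pattern == "no-change", ]
  rna <- sim$rna_counts
  rna <- rna[paste(rna$patient, rna$variantID) %in%
             paste(null_ids$patient, null_ids$variantID), ]
  pair <- paste0(rna$refAllele, ">", rna$altAllele)
  for (pr in NUCLEOTIDE_PAIRS) {
    sel <- pair == pr
    reads <- sum(rna$totalCount[sel])
    p0 <- cfg$bias_table[pr]
    se <- sqrt(p0 * (1 - p0) / reads)
    expect_lt(abs(sum(rna$refCount[sel]) / reads - p0), 3 * se)
  }
})

test_that("null site simulation is calibrated, conserved, and deterministic", {
  one <- simulate_null_sites(1, list(mean = 100, dispersion = Inf),
                             setNames(rep(0.5, 12), NUCLEOTIDE_PAIRS), seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$refCount + one$altCount, 100)

  tab6 <- setNames(rep(0.6, 12), NUCLEOTIDE_PAIRS)
  x <- simulate_null_sites(10000, list(mean = 100, dispersion = 5), tab6,
                           seed = 5)
  reads <- sum(x$totalCount)
  se <- sqrt(0.6 * 0.4 / reads)
  expect_lt(abs(sum(x$refCount) / reads - 0.6), 3 * se)

  expect_identical(x, simulate_null_sites(10000, list(mean = 100, dispersion = 5),
                                          tab6, seed = 5))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(pattern_mix = c(P1 = 0.5, P2 = 0, P3 = 0, P4 = 0,
                                          P5 = 0, P6 = 0, "no-change" = 0.6)),
               "sum to 1")
  expect_error(sim_config(effect_ratio = 0.4), "effect_ratio")
  expect_error(sim_config(rna_depth = list(mean = -5, dispersion = 5)),
               "depth")
  expect_error(sim_config(cnv_fraction = 0.8, skip_fraction = 0.5),
               "cnv_fraction")
})

test_that("written cohort files round-trip through the readers", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_sim(sim, dir)

  s1 <- "P01_normal"
  rt <- read_allele_counts(file.path(dir, paste0("rna_", s1, ".tsv")),
                           sample = s1, assay = "RNA")
  orig <- sim$rna_counts[sim$rna_counts$sample == s1,
                         c("contig", "position", "variantID", "refAllele",
                           "altAllele", "refCount", "altCount", "totalCount")]
  rownames(orig) <- NULL
  expect_equal(rt[, names(orig)], orig)

  v <- read_gt_vcf(file.path(dir, "genotypes.vcf"))
  expect_equal(nrow(v$sites), nrow(sim$vcf_sites))
  expect_equal(v$sites$position, sim$vcf_sites$position)
  expect_true(all(v$gt == "0|1"))

  ex <- read_exon_bed12(file.path(dir, "exons.bed12"))
  g1 <- sim$exons[sim$exons$gene == "G001", c("gene", "contig", "strand",
                                              "start", "end")]
  rt1 <- ex[ex$gene == "G001", c("gene", "contig", "strand", "start", "end")]
  rownames(g1) <- rownames(rt1) <- NULL
  expect_equal(rt1, g1)
})
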