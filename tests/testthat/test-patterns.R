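test_that("Fisher difference test matches hypergeometric enumeration", {
  expect_equal(as.numeric(fisher_diff(10, 10, 10, 10)), 1)
  p_strong <- as.numeric(fisher_diff(50, 50, 20, 80))
  expect_equal(p_strong, oracle_fisher_p(50, 50, 20, 80), tolerance = 1e-10)
  expect_lt(p_strong, 0.05)
  p_weak <- as.numeric(fisher_diff(5, 5, 6, 4))
  expect_equal(p_weak, oracle_fisher_p(5, 5, 6, 4), tolerance = 1e-10)
  expect_gt(p_weak, 0.05)
})

test_that("zero-margin tables are uninformative and flagged", {
  p <- fisher_diff(c(0, 10), c(10, 0), c(0, 20), c(30, 0))
  expect_equal(as.numeric(p), c(1, 1))
  expect_true(all(attr(p, "degenerate")))
})

test_that("the state-pair to pattern mapping is exhaustive and exact", {
  states <- expand.grid(normal = c("BAL", "REF", "ALT"),
                        tumor = c("BAL", "REF", "ALT"),
                        stringsAsFactors = FALSE)
  got <- classify_pattern(states$normal, states$tumor,
                          fisher_p = rep(0.01, 9))
  want <- c("BAL,BAL" = "no-change", "REF,BAL" = "P2", "ALT,BAL" = "P5",
            "BAL,REF" = "P4", "REF,REF" = "concordant", "ALT,REF" = "P6",
            "BAL,ALT" = "P1", "REF,ALT" = "P3", "ALT,ALT" = "concordant")
  expect_equal(got, unname(want[paste(states$normal, states$tumor, sep = ",")]))
  # every site gets exactly one label
  expect_false(any(is.na(got)))
})

test_that("an insignificant Fisher test demotes any pattern to no-change", {
  got <- classify_pattern(c("BAL", "REF", "ALT"), c("ALT", "ALT", "REF"),
                          fisher_p = c(0.2, 0.06, 0.05))
  expect_equal(got, c("no-change", "no-change", "no-change"))
  # concordant and no-change are unaffected by Fisher
  expect_equal(classify_pattern("REF", "REF", 0.9), "concordant")
  expect_equal(classify_pattern("BAL", "BAL", 0.001), "no-change")
})

test_that("label swap maps P1<->P5, P2<->P4, P3<->P6 and fixes no-change", {
  set.seed(14)
  st <- c("BAL", "REF", "ALT")
  normal <- sample(st, 200, replace = TRUE)
  tumor <- sample(st, 200, replace = TRUE)
  fp <- runif(200)
  fwd <- classify_pattern(normal, tumor, fp)
  rev <- classify_pattern(tumor, normal, fp)
  swap <- c(P1 = "P5", P2 = "P4", P3 = "P6", P4 = "P2", P5 = "P1",
            P6 = "P3", concordant = "concordant", "no-change" = "no-change")
  expect_equal(rev, unname(swap[fwd]))
})

test_that("allele swap maps P1<->P4, P2<->P5, P3<->P6", {
  set.seed(15)
  st <- c("BAL", "REF", "ALT")
  flip <- c(BAL = "BAL", REF = "ALT", ALT = "REF")
  normal <- sample(st, 200, replace = TRUE)
  tumor <- sample(st, 200, replace = TRUE)
  fp <- runif(200)
  fwd <- classify_pattern(normal, tumor, fp)
  swapped <- classify_pattern(unname(flip[normal]), unname(flip[tumor]), fp)
  swap <- c(P1 = "P4", P2 = "P5", P3 = "P6", P4 = "P1", P5 = "P2",
            P6 = "P3", concordant = "concordant", "no-change" = "no-change")
  expect_equal(swapped, unname(swap[fwd]))
})

test_that("allele swap with p0 -> 1 - p0 mirrors states and p-values exactly", {
  x <- make_counts(ref = c(80, 20, 50, 65), alt = c(20, 80, 50, 35))
  xs <- x
  xs$refCount <- x$altCount; xs$altCount <- x$refCount
  b <- structure(list(p0 = setNames(rep(0.55, 12), NUCLEOTIDE_PAIRS)),
                 class = "bias_model")
  bs <- structure(list(p0 = setNames(rep(0.45, 12), NUCLEOTIDE_PAIRS)),
                  class = "bias_model")
  c1 <- ase_calls(x, b)
  c2 <- ase_calls(xs, bs)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
  flip <- c(BAL = "BAL", REF = "ALT", ALT = "REF")
  expect_equal(c2$state, unname(flip[c1$state]))
})

test_that("paired classification joins on site identity post-filter", {
  nc <- ase_calls(make_counts(ref = c(50, 48), alt = c(50, 52),
                              sample = "N"))
  tc <- ase_calls(make_counts(ref = c(20, 47), alt = c(80, 53),
                              sample = "T"))
  pp <- paired_patterns(nc, tc)
  expect_equal(nrow(pp), 2)
  expect_equal(pp$pattern[pp$variantID == "v001"], "P1")
  expect_equal(pp$pattern[pp$variantID == "v002"], "no-change")
  expect_lt(pp$fisher_p[1], 0.05)
})

test_that("pattern percentage tables sum to 100 and respect gene roles", {
  sites <- data.frame(
    variantID = sprintf("v%02d", 1:10),
    gene = c(rep("TSG_A", 5), rep("ONC_B", 5)),
    pattern = c("P1", rep("no-change", 9)),
    stringsAsFactors = FALSE)
  roles <- data.frame(gene = c("TSG_A", "ONC_B"),
                      role = c("TSG", "oncogene"), stringsAsFactors = FALSE)
  tab <- pattern_table(sites, roles)
  expect_equal(tab[["Total SNPs"]][tab$pattern == "P1"], 10.0)
  expect_equal(tab[["Total SNPs"]][tab$pattern == "No ASE"], 90.0)
  expect_equal(tab[["TSG"]][tab$pattern == "P1"], 20.0)
  expect_equal(tab[["Oncogene"]][tab$pattern == "P1"], 0.0)
  expect_equal(sum(tab[["Total SNPs"]]), 100)
  expect_false("Fusion" %in% names(suppressMessages(pattern_table(sites, roles))))
})

test_that("concordant sites fold into the No ASE row", {
  sites <- data.frame(variantID = c("a", "b"), gene = "G",
                      pattern = c("concordant", "no-change"),
                      stringsAsFactors = FALSE)
  tab <- pattern_table(sites)
  expect_equal(tab[["Total SNPs"]][tab$pattern == "No ASE"], 100.0)
})
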