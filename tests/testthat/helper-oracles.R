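# Independent oracles: brute-force enumerations kept deliberately separate
# from the package's code paths.

# two-sided exact binomial: total probability of outcomes no more likely
# than the observed one, probabilities via log-factorials (not dbinom)
oracle_binom_p <- function(x, n, p) {
  lp <- lchoose(n, 0:n) + (0:n) * log(p) + (n - (0:n)) * log1p(-p)
  probs <- exp(lp)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# two-sided Fisher exact by hypergeometric enumeration over the 2x2 table
# [[a, b], [c, d]] with fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  k <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- dhyper(k, c1, n - c1, r1)
  sum(probs[probs <= dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
}

# minimal allele-count table builder
make_counts <- function(ref, alt, pair = "A>G", sample = "S1",
                        contig = "chr1") {
  n <- length(ref)
  if (n == 0) {
    return(data.frame(contig = character(0), position = integer(0),
                      variantID = character(0), refAllele = character(0),
                      altAllele = character(0), refCount = integer(0),
                      altCount = integer(0), totalCount = integer(0),
                      sample = character(0), stringsAsFactors = FALSE))
  }
  data.frame(contig = contig, position = seq_len(n) * 100L,
             variantID = sprintf("v%03d", seq_len(n)),
             refAllele = substr(pair, 1, 1), altAllele = substr(pair, 3, 3),
             refCount = ref, altCount = alt, totalCount = ref + alt,
             sample = sample, stringsAsFactors = FALSE)
}

# small cohort used by several end-to-end tests (shared to amortise runtime)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 6, n_genes = 60,
                        rna_depth = list(mean = 100, dispersion = Inf),
                        pattern_mix = c(P1 = .06, P2 = .04, P3 = .04,
                                        P4 = .06, P5 = .04, P6 = .04,
                                        "no-change" = .72),
                        seed = 202L)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
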