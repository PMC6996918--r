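#' Ordered nucleotide pairs used by the bias model
#'
#' The 12 ordered ref->alt single-base substitutions, in the fixed order used
#' everywhere in the package.
#' @export
NUCLEOTIDE_PAIRS <- c("A>C", "A>G", "A>T",
                      "C>A", "C>G", "C>T",
                      "G>A", "G>C", "G>T",
                      "T>A", "T>C", "T>G")

PATTERN_LEVELS <- c("P1", "P2", "P3", "P4", "P5", "P6")
PATTERN_MIX_LEVELS <- c(PATTERN_LEVELS, "no-change")
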