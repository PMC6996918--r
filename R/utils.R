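#' Round half away from zero
#'
#' Printed summary tables in this field round 0.05 up (35.15 -> 35.2), whereas
#' [base::round()] rounds half to even. Used for all percentage tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed. Per-unit streams
#' (per patient, per gene, per replicate) are derived by integer hashing so
#' that adding units never perturbs the draws of earlier units. The hash is
#' computed in double precision (exact below 2^53) and reduced mod 2^31 - 1,
#' keeping every derived seed a valid 32-bit R integer.
#'
#' @param seed master seed (integer).
#' @param ... one or more integer keys identifying the stream
#'   (e.g. patient index, gene index).
#' @return a single integer seed.
#' @export
sub_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) {
    h <- (h * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Counts-per-million with pseudocount
#'
#' @param count raw count vector.
#' @param library_size total reads in the library.
#' @param pseudocount added before scaling to tolerate zeros (default 1).
#' @return normalized counts per million.
#' @export
cpm1 <- function(count, library_size, pseudocount = 1) {
  (count + pseudocount) / library_size * 1e6
}

# internal: accumulate machine-readable rejection/skip records
new_log <- function() {
  data.frame(id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

add_log <- function(log, id, reason) {
  rbind(log, data.frame(id = as.character(id), reason = reason,
                        stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
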