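#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (A/C/G/T,
#' case preserved, other letters passed through unchanged).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

# Random DNA string(s); relies on the caller having seeded the RNG.
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Run `expr` under `seed` when given, leaving the global RNG untouched;
# otherwise use the current RNG stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, min))
  }
  invisible(x)
}
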