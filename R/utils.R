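# Internal string / RNG helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a fixed RNG seed when `seed` is non-NULL, leaving the
# caller's RNG stream untouched; otherwise use the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Random DNA string of length n at the given GC fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# substring with 0-based, half-open coordinates (the package-wide convention)
substr0 <- function(x, start, end) substr(x, start + 1L, end)

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# longest k such that the last k characters of `a` equal the first k of `b`
longest_suffix_prefix <- function(a, b, kmax) {
  kmax <- min(kmax, nchar(a), nchar(b))
  for (k in rev(seq_len(kmax))) {
    if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) return(k)
  }
  0L
}

assert_fraction <- function(x, name, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || x > 1) {
    abort(sprintf("`%s` must be a single fraction in %s", name,
                  if (allow_zero) "[0, 1]" else "(0, 1]"))
  }
  invisible(x)
}

assert_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] || x[1] < 0) {
    abort(sprintf("`%s` must be a non-empty range c(lo, hi) with 0 <= lo <= hi", name))
  }
  invisible(x)
}

sample_range <- function(range) {
  if (range[1] == range[2]) return(as.integer(range[1]))
  sample(seq.int(range[1], range[2]), 1L)
}
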