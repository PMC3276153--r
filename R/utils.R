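#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA as a character vector of single bases (uses the current RNG state).
random_bases <- function(n) {
  sample(DNA_BASES, n, replace = TRUE)
}

random_dna <- function(n) paste(random_bases(n), collapse = "")

# Reverse complement of a plain character string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Replace the base at `pos` (1-based, in a character vector of bases) with a
# different base, chosen deterministically from the RNG.
mutate_base <- function(bases, pos) {
  bases[pos] <- sample(setdiff(DNA_BASES, bases[pos]), 1L)
  bases
}

# Longest common prefix length of two strings.
lcp_len <- function(x, y) {
  xa <- charToRaw(x); ya <- charToRaw(y)
  n <- min(length(xa), length(ya))
  if (n == 0L) return(0L)
  neq <- which(xa[seq_len(n)] != ya[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Longest common suffix length of two strings.
lcs_len <- function(x, y) {
  lcp_len(rev_string(x), rev_string(y))
}

rev_string <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Round half away from zero (commercial rounding), as opposed to base R's
# round-half-to-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# 0-based half-open interval helpers ------------------------------------------
# All user-facing coordinates in this package are 0-based, half-open [start,
# end); GFF3 export converts to 1-based inclusive.

# Substring of `seq` over the 0-based half-open interval [start, end).
subseq0 <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

interval_len <- function(start, end) end - start

stopif_not_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# All exact (0-based) start positions of `pattern` in `seq`.
find_all <- function(seq, pattern) {
  if (nchar(pattern) == 0L || nchar(seq) < nchar(pattern)) return(integer(0))
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}
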