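# Independent oracles used to freeze expected values; each is deliberately a
# different algorithm from the implementation it checks.

# Brute-force affine-gap global alignment score (3-state Gotoh DP, dense
# matrices). Gap of length L costs open + L * extend.
affine_dp_score <- function(a, b, match = 1, mismatch = -1,
                            open = 5, extend = 1) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L) # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L) # gap in a (consumes b)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - extend,
                               X[i, j + 1L] - extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - extend,
                               Y[i + 1L, j] - extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Exact two-sided Mann-Whitney p-value by bitmask enumeration of all group
# assignments (independent of the combn-based implementation).
mw_enumeration_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  rk <- rank(c(a, b))
  mu <- na * nb / 2
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1L))) > 0L)
    if (length(idx) != na) next
    total <- total + 1L
    u <- sum(rk[idx]) - na * (na + 1) / 2
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# O(n) column scan for the longest run of match columns (loop, no rle).
longest_run_scan <- function(state) {
  best <- 0L; cur <- 0L
  for (s in state) {
    if (s == "match") {
      cur <- cur + 1L
      if (cur > best) best <- cur
    } else cur <- 0L
  }
  best
}

# Brute-force all-pairs exact k-mer comparison (quadratic).
kmer_pairs_bruteforce <- function(seq, k) {
  n <- nchar(seq)
  km <- substring(seq, 1:(n - k + 1), k:n)
  out <- list()
  for (i in seq_along(km)) {
    for (j in seq_along(km)) {
      if (j > i && km[i] == km[j]) out[[length(out) + 1L]] <- c(i - 1L, j - 1L)
    }
  }
  if (length(out) == 0) {
    matrix(integer(0), ncol = 2)
  } else do.call(rbind, out)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Small but complete scenario used by most fixture tests: ~4 kb copies, two
# junction modules (one reversed), one signature of each kind.
toy_scenario <- function(...) {
  dup_scenario(
    dup_length = 4000, dup_start = 800, n_modules = 2,
    te_length = 300, rist_length = 100, te_site_offset = 60,
    identical_tract = c(1000, 1500),
    planted_signatures = tibble::tibble(
      kind = c("microhomology_jump", "tandem_repeat", "deletion"),
      pos = c(300, 3300, 2800), size = c(12, 9, 30), mh_len = c(3, NA, NA),
      copy = c("proximal", "distal", "distal")),
    planted_genes = tibble::tibble(
      name = c("gA", "gB"), start = c(100, 2600), end = c(900, 3100),
      strand = c("+", "-")),
    ...)
}
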