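#' Exact k-mer self-matches of a sequence (dot-plot substrate)
#'
#' Enumerates all pairs of positions carrying identical k-mers
#' (forward-strand matches) and all pairs where one k-mer equals the reverse
#' complement of the other (flagged `"-"`), excluding the trivial main
#' diagonal. Positions are 0-based k-mer start coordinates with
#' `pos_i < pos_j`.
#'
#' @param seq Nucleotide string.
#' @param k Word size (>= 8).
#' @return A tibble with columns `pos_i`, `pos_j`, `strand` (`"+"`/`"-"`),
#'   sorted by `pos_i`, `pos_j`.
#' @examples
#' kmer_self_matches(strrep("ACGT", 8), k = 8)
#' @export
kmer_self_matches <- function(seq, k = 16L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (k < 8) abort("`k` must be >= 8")
  if (n < k) abort("`k` exceeds the sequence length")
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)

  pair_up <- function(groups) {
    out <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      pos <- groups[[gi]]
      if (length(pos) == 2L) {
        out[[gi]] <- cbind(pos[1L], pos[2L])
      } else {
        cmb <- utils::combn(sort(pos), 2L)
        out[[gi]] <- cbind(cmb[1L, ], cmb[2L, ])
      }
    }
    do.call(rbind, out)
  }

  idx0 <- starts - 1L # 0-based
  grp <- split(idx0, kmers)
  grp_f <- grp[lengths(grp) > 1L]
  fwd <- if (length(grp_f) > 0) pair_up(grp_f) else NULL

  # reverse-complement matches: forward k-mer at j equals rc of k-mer at i
  rcseq <- revcomp(seq)
  rckmers <- substring(rcseq, starts, starts + k - 1L)
  # rc k-mer of the word starting at 0-based i sits at rcseq position n-i-k
  rc_of <- rckmers[n - idx0 - k + 1L]
  hit <- which(rc_of %in% names(grp))
  rev_pairs <- NULL
  if (length(hit) > 0) {
    pl <- lapply(hit, function(h) {
      i <- idx0[h]
      js <- grp[[rc_of[h]]]
      js <- js[js > i] # keep i < j; drops self-palindromes and mirror dups
      if (length(js) == 0) return(NULL)
      cbind(i, js)
    })
    rev_pairs <- do.call(rbind, pl)
  }

  res <- dplyr::bind_rows(
    if (!is.null(fwd)) tibble(pos_i = fwd[, 1L], pos_j = fwd[, 2L], strand = "+"),
    if (!is.null(rev_pairs)) tibble(pos_i = rev_pairs[, 1L],
                                    pos_j = rev_pairs[, 2L], strand = "-"))
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(pos_i = integer(), pos_j = integer(), strand = character()))
  }
  res <- dplyr::arrange(res, .data$pos_i, .data$pos_j)
  attr(res, "k") <- as.integer(k)
  res
}

#' Call a tandem duplication from k-mer self-matches
#'
#' Chains collinear forward-strand matches (offsets within `offset_tol` of
#' one another belong to one chain; chains separated by less than `merge_gap`
#' along both axes are merged, which bridges indels between the copies) into
#' a duplication candidate. The copy intervals are the extents of the merged
#' chain; when `seq` is supplied, boundaries are refined by gapless X-drop
#' extension (+1 match / -3 mismatch, drop 20) so the call reaches the exact
#' ends of homology. The reported `copy_length` is the length of the distal
#' (first) copy; the junction is the gap between the two copy intervals.
#'
#' @param matches Tibble from [kmer_self_matches()].
#' @param min_copy_length Minimum copy length in bp for a call.
#' @param seq Optional sequence (enables boundary refinement).
#' @param k Word size used to produce `matches` (defaults to its `k`
#'   attribute).
#' @param offset_tol Offset tolerance within a chain (bp).
#' @param merge_gap Maximum axis gap between chains to merge (bp).
#' @param min_chain_matches Minimum matches for a chain to be considered.
#' @return A one-row tibble of class `dup_call` with columns `distal_start`,
#'   `distal_end`, `proximal_start`, `proximal_end`, `copy_length`,
#'   `junction_start`, `junction_end`, `orientation`, `n_matches`
#'   (coordinates 0-based half-open), or `NULL` when nothing passes
#'   `min_copy_length`.
#' @export
detect_tandem_duplication <- function(matches, min_copy_length = 1000L,
                                      seq = NULL, k = attr(matches, "k"),
                                      offset_tol = 50L, merge_gap = 2000L,
                                      min_chain_matches = 5L) {
  if (is.null(k)) k <- 16L
  fwd <- matches[matches$strand == "+", , drop = FALSE]
  if (nrow(fwd) == 0) return(NULL)
  off <- fwd$pos_j - fwd$pos_i
  ord <- order(off)
  gaps <- which(diff(off[ord]) > offset_tol)
  cluster_of <- integer(length(off))
  cluster_of[ord] <- rep(seq_len(length(gaps) + 1L),
                         diff(c(0L, gaps, length(off))))
  ch <- dplyr::summarise(
    dplyr::group_by(tibble(i = fwd$pos_i, j = fwd$pos_j, cl = cluster_of), .data$cl),
    i_min = min(.data$i), i_max = max(.data$i),
    j_min = min(.data$j), j_max = max(.data$j),
    o_min = min(.data$j - .data$i), o_max = max(.data$j - .data$i),
    n = dplyr::n(),
    .groups = "drop")
  ch <- ch[ch$n >= min_chain_matches, , drop = FALSE]
  if (nrow(ch) == 0) return(NULL)

  # merge chains whose extents are within merge_gap on both axes and whose
  # offsets are compatible (indels between the copies shift the offset by at
  # most their summed length, far less than merge_gap)
  ch <- dplyr::arrange(ch, .data$i_min)
  comp <- seq_len(nrow(ch))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(ch) - 1L)) {
      for (b in (a + 1L):nrow(ch)) {
        if (comp[a] == comp[b]) next
        gi <- max(ch$i_min[b], ch$i_min[a]) - min(ch$i_max[b] + k, ch$i_max[a] + k)
        gj <- max(ch$j_min[b], ch$j_min[a]) - min(ch$j_max[b] + k, ch$j_max[a] + k)
        go <- max(ch$o_min[a], ch$o_min[b]) - min(ch$o_max[a], ch$o_max[b])
        if (gi < merge_gap && gj < merge_gap && go < merge_gap) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cand <- dplyr::summarise(
    dplyr::group_by(ch, comp = comp),
    i_min = min(.data$i_min), i_max = max(.data$i_max),
    j_min = min(.data$j_min), j_max = max(.data$j_max), n = sum(.data$n),
    .groups = "drop")
  cand$span <- cand$i_max + k - cand$i_min
  cand <- cand[cand$span >= min_copy_length & cand$j_min >= cand$i_max + k, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  best <- cand[which.max(cand$span), ]

  d_start <- best$i_min; d_end <- best$i_max + k
  p_start <- best$j_min; p_end <- best$j_max + k
  if (!is.null(seq)) {
    bases <- strsplit(toupper(seq), "")[[1L]]
    ext_l <- xdrop_extend(bases, d_start, p_start, dir = -1L)
    d_start <- d_start - ext_l; p_start <- p_start - ext_l
    ext_r <- xdrop_extend(bases, d_end - 1L, p_end - 1L, dir = 1L)
    d_end <- min(d_end + ext_r, p_start)
    p_end <- p_end + ext_r
  }
  out <- tibble(
    distal_start = d_start, distal_end = d_end,
    proximal_start = p_start, proximal_end = p_end,
    copy_length = d_end - d_start,
    junction_start = d_end, junction_end = p_start,
    orientation = "direct", n_matches = best$n)
  class(out) <- c("dup_call", class(out))
  out
}

# Gapless X-drop extension from 0-based positions i, j (exclusive of the
# seed pair itself): returns how many bases the best-scoring extension adds.
xdrop_extend <- function(bases, i, j, dir, match = 1L, mismatch = -3L,
                         drop = 20L) {
  n <- length(bases)
  score <- 0L; best <- 0L; best_t <- 0L; t <- 0L
  repeat {
    t <- t + 1L
    ii <- i + dir * t; jj <- j + dir * t
    if (ii < 0L || jj < 0L || ii >= n || jj >= n) break
    score <- score + if (bases[ii + 1L] == bases[jj + 1L]) match else mismatch
    if (score > best) { best <- score; best_t <- t }
    if (score < best - drop) break
  }
  best_t
}

#' Globally align the two copies of a duplication
#'
#' Optimal global alignment under affine-gap scoring (a gap of length `L`
#' costs `|gap_open| + L * |gap_extend|`). Short inputs are aligned by full
#' dynamic programming (Biostrings); longer inputs by anchor-and-fill: exact
#' 20-mer matches unique in both copies are chained (weighted longest
#' increasing subsequence over same-diagonal runs) and the inter-anchor
#' segments are aligned by full DP, so around any local difference the result
#' equals the full dynamic program.
#'
#' @param copy_a,copy_b Nucleotide strings (copy A is the reference axis for
#'   downstream coordinate reporting).
#' @param scoring Named numeric vector `c(match, mismatch, gap_open,
#'   gap_extend)`.
#' @param anchor_k Anchor word size for long inputs.
#' @param max_dp Maximum length for direct full-DP alignment.
#' @return An object of class `pairwise_alignment`: a list with `a`, `b`
#'   (gapped strings of equal length), `n_col`, `state` (per-column
#'   `"match"`, `"mismatch"`, `"gap_in_a"`, `"gap_in_b"`), `a_pos`, `b_pos`
#'   (0-based source coordinate per column; `NA` at gaps), and `score`.
#' @examples
#' aln <- align_copies("ACGTACGT", "ACGTTCGT")
#' table(aln$state)
#' @export
align_copies <- function(copy_a, copy_b,
                         scoring = c(match = 1, mismatch = -1,
                                     gap_open = -5, gap_extend = -1),
                         anchor_k = 20L, max_dp = 4000L) {
  copy_a <- toupper(copy_a); copy_b <- toupper(copy_b)
  if (!nzchar(copy_a) || !nzchar(copy_b)) abort("both copies must be non-empty")
  if (max(nchar(copy_a), nchar(copy_b)) <= max_dp) {
    parts <- dp_align(copy_a, copy_b, scoring)
  } else {
    parts <- anchored_align(copy_a, copy_b, scoring, anchor_k, max_dp)
  }
  new_pairwise_alignment(parts$a, parts$b, copy_a, copy_b, scoring)
}

# Full affine-gap DP via Biostrings; returns gapped strings.
dp_align <- function(a, b, scoring) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring[["match"]], mismatch = scoring[["mismatch"]],
    baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = submat,
    gapOpening = abs(scoring[["gap_open"]]),
    gapExtension = abs(scoring[["gap_extend"]]),
    type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

# Anchor-and-fill alignment for long, highly similar copies.
anchored_align <- function(a, b, scoring, k, max_dp) {
  runs <- anchor_runs(a, b, k)
  if (nrow(runs) == 0) {
    if (max(nchar(a), nchar(b)) > 5L * max_dp) {
      abort("no alignment anchors found and the inputs are too long for full DP")
    }
    return(dp_align(a, b, scoring))
  }
  runs <- select_chain(runs)
  a_parts <- character(0); b_parts <- character(0)
  pa <- 0L; pb <- 0L # 0-based consumed prefix
  align_segment <- function(sa, sb) {
    if (!nzchar(sa) && !nzchar(sb)) return(c("", ""))
    if (!nzchar(sa)) return(c(strrep("-", nchar(sb)), sb))
    if (!nzchar(sb)) return(c(sa, strrep("-", nchar(sa))))
    g <- dp_align(sa, sb, scoring)
    c(g$a, g$b)
  }
  for (r in seq_len(nrow(runs))) {
    seg <- align_segment(subseq0(a, pa, runs$a_start[r]),
                         subseq0(b, pb, runs$b_start[r]))
    anc <- subseq0(a, runs$a_start[r], runs$a_end[r])
    a_parts <- c(a_parts, seg[1L], anc)
    b_parts <- c(b_parts, seg[2L], anc)
    pa <- runs$a_end[r]; pb <- runs$b_end[r]
  }
  seg <- align_segment(subseq0(a, pa, nchar(a)), subseq0(b, pb, nchar(b)))
  list(a = paste(c(a_parts, seg[1L]), collapse = ""),
       b = paste(c(b_parts, seg[2L]), collapse = ""))
}

# Maximal runs of exact k-mer matches unique in both sequences, grouped by
# diagonal; 0-based half-open extents.
anchor_runs <- function(a, b, k) {
  ka <- substring(a, seq_len(nchar(a) - k + 1L), seq_len(nchar(a) - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(nchar(b) - k + 1L), seq_len(nchar(b) - k + 1L) + k - 1L)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  m <- match(ka, kb)
  keep <- which(!is.na(m) & ua & ub[pmax(m, 1L)])
  if (length(keep) == 0) {
    return(tibble(a_start = integer(), a_end = integer(),
                  b_start = integer(), b_end = integer(), len = integer()))
  }
  ai <- keep - 1L; bi <- m[keep] - 1L
  d <- bi - ai
  o <- order(d, ai)
  ai <- ai[o]; bi <- bi[o]; d <- d[o]
  new_run <- c(TRUE, diff(ai) != 1L | diff(d) != 0L)
  run_id <- factor(cumsum(new_run)) # cumsum is sorted, so levels stay ordered
  tibble(
    a_start = ai[new_run],
    a_end = as.integer(tapply(ai, run_id, max)) + k,
    b_start = bi[new_run],
    b_end = as.integer(tapply(bi, run_id, max)) + k,
    len = as.integer(tapply(ai, run_id, length)) + k - 1L)
}

# Weighted longest-increasing-subsequence selection of compatible runs,
# followed by overlap trimming; O(n^2) in the number of runs.
select_chain <- function(runs) {
  runs <- dplyr::arrange(runs, .data$a_start, .data$b_start)
  n <- nrow(runs)
  best <- runs$len
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (runs$a_start[j] < runs$a_start[i] && runs$b_start[j] < runs$b_start[i] &&
          best[j] + runs$len[i] > best[i]) {
        best[i] <- best[j] + runs$len[i]
        prev[i] <- j
      }
    }
  }
  path <- integer(0)
  i <- which.max(best)
  while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
  runs <- runs[path, , drop = FALSE]
  # trim overlaps between consecutive runs (keep the earlier run intact)
  if (nrow(runs) > 1) {
    drop <- logical(nrow(runs))
    for (i in 2:nrow(runs)) {
      ov <- max(runs$a_end[i - 1L] - runs$a_start[i],
                runs$b_end[i - 1L] - runs$b_start[i], 0L)
      runs$a_start[i] <- runs$a_start[i] + ov
      runs$b_start[i] <- runs$b_start[i] + ov
      if (runs$a_start[i] >= runs$a_end[i] || runs$b_start[i] >= runs$b_end[i]) {
        drop[i] <- TRUE
      }
    }
    runs <- runs[!drop, , drop = FALSE]
  }
  runs
}

# Construct the column-addressable alignment object from gapped strings.
new_pairwise_alignment <- function(ga, gb, a, b, scoring) {
  ca <- strsplit(ga, "")[[1L]]
  cb <- strsplit(gb, "")[[1L]]
  if (length(ca) != length(cb)) abort("internal: ragged alignment")
  gap_a <- ca == "-"; gap_b <- cb == "-"
  if (any(gap_a & gap_b)) abort("internal: double-gap column")
  state <- ifelse(gap_a, "gap_in_a",
                  ifelse(gap_b, "gap_in_b",
                         ifelse(ca == cb, "match", "mismatch")))
  a_pos <- rep(NA_integer_, length(ca)); a_pos[!gap_a] <- seq_len(sum(!gap_a)) - 1L
  b_pos <- rep(NA_integer_, length(cb)); b_pos[!gap_b] <- seq_len(sum(!gap_b)) - 1L
  if (paste(ca[!gap_a], collapse = "") != a ||
      paste(cb[!gap_b], collapse = "") != b) {
    abort("internal: alignment does not round-trip to its inputs")
  }
  score <- alignment_score(state, scoring)
  structure(
    list(a = ga, b = gb, n_col = length(ca), state = state,
         a_pos = a_pos, b_pos = b_pos, score = score, scoring = scoring),
    class = "pairwise_alignment")
}

# Score an alignment column-state vector under the affine convention used
# throughout: gap of length L costs |open| + L * |extend|.
alignment_score <- function(state, scoring) {
  n_match <- sum(state == "match")
  n_mm <- sum(state == "mismatch")
  gap_runs <- rle(state)
  gaps <- gap_runs$lengths[gap_runs$values %in% c("gap_in_a", "gap_in_b")]
  n_match * scoring[["match"]] + n_mm * scoring[["mismatch"]] -
    sum(abs(scoring[["gap_open"]]) + gaps * abs(scoring[["gap_extend"]]))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "Pairwise alignment: %d columns (%d match, %d mismatch, %d gap), score %g\n",
    x$n_col, sum(x$state == "match"), sum(x$state == "mismatch"),
    sum(x$state %in% c("gap_in_a", "gap_in_b")), x$score))
  invisible(x)
}

#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble(column = seq_len(x$n_col) - 1L,
         a = strsplit(x$a, "")[[1L]], b = strsplit(x$b, "")[[1L]],
         state = x$state, a_pos = x$a_pos, b_pos = x$b_pos)
}

#' @export
glance.pairwise_alignment <- function(x, ...) {
  tibble(n_col = x$n_col,
         n_match = sum(x$state == "match"),
         n_mismatch = sum(x$state == "mismatch"),
         n_gap_col = sum(x$state %in% c("gap_in_a", "gap_in_b")),
         pct_identity = round(100 * sum(x$state == "match") / x$n_col, 2),
         score = x$score)
}
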