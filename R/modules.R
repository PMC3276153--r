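#' Scan a sequence for copies of a consensus element
#'
#' Seeds candidate locations with exact 12-mers shared with the consensus (on
#' both strands), groups seeds into diagonal clusters, and evaluates each
#' candidate. Clusters whose dominant diagonal carries most of the consensus
#' are scored by direct (gapless) comparison at that diagonal; otherwise the
#' candidate window is re-aligned to the consensus with affine-gap DP. Hits
#' below `min_identity` are discarded and overlaps resolved greedily by
#' score.
#'
#' @param seq Nucleotide string to scan.
#' @param consensus Consensus element sequence.
#' @param min_identity Minimum percent identity of a reported hit.
#' @param seed_k Seed word size.
#' @return A tibble with columns `start`, `end` (0-based half-open),
#'   `strand` (`"+"` forward, `"-"` reversed), `identity` (percent),
#'   `score` (matching bases).
#' @export
scan_te_copies <- function(seq, consensus, min_identity = 90, seed_k = 12L) {
  seq <- toupper(seq); consensus <- toupper(consensus)
  if (!nzchar(consensus)) abort("`consensus` must be non-empty")
  hits <- dplyr::bind_rows(
    scan_one_strand(seq, consensus, "+", min_identity, seed_k),
    scan_one_strand(seq, revcomp(consensus), "-", min_identity, seed_k))
  if (nrow(hits) == 0) return(hits)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score))
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(hits)) > i)
    ov <- hits$start[later] < hits$end[i] & hits$end[later] > hits$start[i]
    keep[later[ov]] <- FALSE
  }
  dplyr::arrange(hits[keep, , drop = FALSE], .data$start)
}

scan_one_strand <- function(seq, cons, strand, min_identity, seed_k) {
  empty <- tibble(start = integer(), end = integer(), strand = character(),
                  identity = numeric(), score = numeric())
  n <- nchar(seq); lc <- nchar(cons)
  if (n < seed_k || lc < seed_k) return(empty)
  cs <- seq_len(lc - seed_k + 1L)
  ck <- substring(cons, cs, cs + seed_k - 1L)
  ss <- seq_len(n - seed_k + 1L)
  sk <- substring(seq, ss, ss + seed_k - 1L)
  grp <- split(cs - 1L, ck)
  hit_i <- which(sk %in% names(grp))
  if (length(hit_i) == 0) return(empty)
  seeds <- purrr::map_dfr(hit_i, function(h) {
    tibble(i = h - 1L, j = grp[[sk[h]]])
  })
  seeds$diag <- seeds$i - seeds$j # implied element start in seq
  # cluster: seeds whose implied starts are within half an element length
  seeds <- dplyr::arrange(seeds, .data$diag, .data$i)
  cl <- cumsum(c(TRUE, diff(seeds$diag) > lc %/% 2L))
  bases <- strsplit(seq, "")[[1L]]
  cbase <- strsplit(cons, "")[[1L]]
  out <- purrr::map_dfr(split(seeds, cl), function(s) {
    est <- sort(s$diag)[ceiling(length(s$diag) / 2)] # median implied start
    dominant <- max(tabulate(factor(s$diag))) * seed_k
    if (dominant >= 0.5 * lc || length(unique(s$diag)) == 1L) {
      # gapless evaluation at the dominant diagonal
      d <- as.integer(names(sort(table(s$diag), decreasing = TRUE))[1L])
      lo <- max(0L, d); hi <- min(n, d + lc)
      if (hi - lo < 0.5 * lc) return(NULL)
      w <- bases[(lo + 1L):hi]
      cmp <- cbase[(lo - d + 1L):(hi - d)]
      m <- sum(w == cmp)
      tibble(start = lo, end = hi, strand = strand,
             identity = round(100 * m / lc, 2), score = m)
    } else {
      # indel-tolerant: re-align the candidate window to the consensus
      lo <- max(0L, est - 30L); hi <- min(n, est + lc + 30L)
      if (hi - lo < 0.3 * lc) return(NULL)
      submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cons), Biostrings::DNAString(subseq0(seq, lo, hi)),
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 1,
        type = "global-local")
      m <- Biostrings::nmatch(pa)
      sj <- Biostrings::subject(pa)
      tibble(start = lo + Biostrings::start(sj) - 1L,
             end = lo + Biostrings::end(sj), strand = strand,
             identity = round(100 * m / lc, 2), score = m)
    }
  })
  out[out$identity >= min_identity, , drop = FALSE]
}

#' Annotate terminal inverted repeats and target-site duplications
#'
#' For each element hit, `tir_left` is `TRUE` iff `tir` occurs exactly at the
#' element's first bases and `tir_right` iff its reverse complement occurs at
#' the last bases (a TIR-bounded element reads the same way on its reverse
#' complement, so the test is orientation-independent). The TSD is the
#' longest exact repeat, with length within `tsd_range`, immediately
#' flanking both element ends.
#'
#' @param hits Tibble of element hits with `start`, `end` columns
#'   (0-based half-open), e.g. from [scan_te_copies()].
#' @param seq The sequence the hits address.
#' @param tir Terminal inverted repeat to look for.
#' @param tsd_range `c(min, max)` TSD length in bp.
#' @return `hits` with added columns `tir_left`, `tir_right`, `tsd`
#'   (string or `NA`), `tsd_len`.
#' @export
detect_tir_tsd <- function(hits, seq, tir = "TAGTGTTGGGT",
                           tsd_range = c(4L, 12L)) {
  seq <- toupper(seq); tir <- toupper(tir)
  rc_tir <- revcomp(tir)
  nt <- nchar(tir)
  n <- nchar(seq)
  res <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    s <- hits$start[i]; e <- hits$end[i]
    tir_left <- subseq0(seq, s, min(e, s + nt)) == tir
    tir_right <- subseq0(seq, max(s, e - nt), e) == rc_tir
    tsd <- NA_character_
    for (L in seq(tsd_range[2], tsd_range[1])) {
      if (s - L < 0 || e + L > n) next
      left <- subseq0(seq, s - L, s)
      if (left == subseq0(seq, e, e + L)) { tsd <- left; break }
    }
    tibble(tir_left = tir_left, tir_right = tir_right, tsd = tsd,
           tsd_len = ifelse(is.na(tsd), NA_integer_, nchar(tsd)))
  })
  dplyr::bind_cols(hits, res)
}

#' Decompose a junction into TE/repeat modules
#'
#' Scans the junction for TE and repeat-unit (rIST) copies, then tiles it
#' into modules: each module starts at a TE hit and extends to the next TE
#' hit (or the junction end), carrying its trailing repeat tandem; repeat
#' copies preceding the first TE form a TE-less leading element. A warning
#' attribute is recorded when the hits cover less than 95% of the junction.
#'
#' @param junction_seq Junction nucleotide string.
#' @param te_consensus,rist_consensus Consensus sequences.
#' @param min_identity Minimum hit identity (percent).
#' @return A tibble with one row per module: `module` (0-based; `-1` for a
#'   leading TE-less element), `start`, `end`, `te_start`, `te_end` (`NA`
#'   when TE-less), `orientation`, `n_rist`, plus attributes `coverage`
#'   (fraction of junction covered by hits) and `rist_hits` (the underlying
#'   repeat-unit hit tibble).
#' @export
decompose_junction <- function(junction_seq, te_consensus, rist_consensus,
                               min_identity = 90) {
  n <- nchar(junction_seq)
  empty <- tibble(module = integer(), start = integer(), end = integer(),
                  te_start = integer(), te_end = integer(),
                  orientation = character(), n_rist = integer())
  if (n == 0) {
    attr(empty, "coverage") <- 1
    return(empty)
  }
  te_hits <- scan_te_copies(junction_seq, te_consensus, min_identity)
  rist_hits <- scan_te_copies(junction_seq, rist_consensus, min_identity)
  covered <- rep(FALSE, n)
  for (h in list(te_hits, rist_hits)) {
    for (i in seq_len(nrow(h))) covered[(h$start[i] + 1L):h$end[i]] <- TRUE
  }
  coverage <- mean(covered)
  if (coverage < 0.95) {
    warn(sprintf("module decomposition covers only %.1f%% of the junction",
                 100 * coverage))
  }
  mods <- if (nrow(te_hits) == 0) {
    if (nrow(rist_hits) == 0) empty else {
      tibble(module = -1L, start = 0L, end = n, te_start = NA_integer_,
             te_end = NA_integer_, orientation = NA_character_,
             n_rist = nrow(rist_hits))
    }
  } else {
    bounds <- c(te_hits$start, n)
    lead <- if (te_hits$start[1L] > 0L) {
      tibble(module = -1L, start = 0L, end = te_hits$start[1L],
             te_start = NA_integer_, te_end = NA_integer_,
             orientation = NA_character_,
             n_rist = sum(rist_hits$end <= te_hits$start[1L]))
    } else NULL
    body <- purrr::map_dfr(seq_len(nrow(te_hits)), function(k) {
      tibble(module = k - 1L, start = bounds[k], end = bounds[k + 1L],
             te_start = te_hits$start[k], te_end = te_hits$end[k],
             orientation = ifelse(te_hits$strand[k] == "+",
                                  "forward", "reversed"),
             n_rist = sum(rist_hits$start >= te_hits$end[k] &
                            rist_hits$end <= bounds[k + 1L]))
    })
    dplyr::bind_rows(lead, body)
  }
  attr(mods, "coverage") <- coverage
  attr(mods, "rist_hits") <- rist_hits
  attr(mods, "te_hits") <- te_hits
  mods
}

#' Module count implied by a Southern fragment size range
#'
#' Converts an observed restriction-fragment size range into a junction
#' module count: `(fragment - flank_total) / module size`, reported to one
#' decimal for both ends of the range.
#'
#' @param fragment_kb `c(low, high)` observed fragment size in kb.
#' @param flank_kb_total Total flanking (non-module) sequence between the
#'   restriction sites, in kb.
#' @param module_kb Module size in kb.
#' @return A tibble with `low` and `high` module counts.
#' @examples
#' southern_module_count(c(26, 36), flank_kb_total = 11.7)
#' @export
southern_module_count <- function(fragment_kb, flank_kb_total,
                                  module_kb = 3.6) {
  if (length(fragment_kb) != 2 || fragment_kb[1] > fragment_kb[2]) {
    abort("`fragment_kb` must be c(low, high) with low <= high")
  }
  if (module_kb <= 0) abort("`module_kb` must be positive")
  if (fragment_kb[1] <= flank_kb_total) {
    abort("fragment size does not exceed the flank total: no junction material")
  }
  tibble(low = round((fragment_kb[1] - flank_kb_total) / module_kb, 1),
         high = round((fragment_kb[2] - flank_kb_total) / module_kb, 1))
}

#' In silico restriction digest
#'
#' Cuts before each occurrence of `site` (convention: fragment boundaries at
#' site starts). Occurrences are searched on both strands; for palindromic
#' sites each position is counted once. Fragment lengths always sum to the
#' template length.
#'
#' @param seq Template nucleotide string.
#' @param site Recognition site.
#' @return Integer vector of ordered fragment lengths.
#' @examples
#' insilico_digest("AAGGATCCAA", "GGATCC")  # c(2, 8)
#' @export
insilico_digest <- function(seq, site) {
  seq <- toupper(seq); site <- toupper(site)
  if (!nzchar(site)) abort("`site` must be non-empty")
  cuts <- sort(unique(c(find_all(seq, site), find_all(seq, revcomp(site)))))
  cuts <- cuts[cuts > 0]
  diff(c(0L, cuts, nchar(seq)))
}

#' In silico PCR
#'
#' Reports the end-to-end length of every amplicon supported by an exact
#' forward-primer match and a downstream exact reverse-complement match of
#' the reverse primer, up to `max_len`.
#'
#' @param template Template nucleotide string.
#' @param fwd_primer,rev_primer Primer sequences (>= 15 bp), the reverse
#'   primer given 5'->3' on the opposite strand as usual.
#' @param max_len Maximum amplicon length considered.
#' @return Integer vector of amplicon lengths (possibly empty).
#' @export
insilico_pcr <- function(template, fwd_primer, rev_primer, max_len = 5000L) {
  template <- toupper(template)
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  if (nchar(fwd_primer) < 15 || nchar(rev_primer) < 15) {
    abort("primers must be >= 15 bp")
  }
  f <- find_all(template, fwd_primer)
  rc <- revcomp(rev_primer)
  r <- find_all(template, rc)
  if (length(f) == 0 || length(r) == 0) return(integer(0))
  out <- integer(0)
  for (fs in f) {
    ends <- r[r >= fs + nchar(fwd_primer)] + nchar(rc)
    lens <- ends - fs
    out <- c(out, lens[lens <= max_len])
  }
  sort(out)
}
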