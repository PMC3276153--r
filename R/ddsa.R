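#' Extract indel features from a copy-to-copy alignment
#'
#' One feature per maximal gap run. For each gap the copy *carrying the gap*
#' lost (or never had) the segment; the other copy carries the segment
#' `segment` plus its `context` bp of flanking sequence on both sides, the
#' substrate for repair-signature classification. Adjacent gap runs in
#' different copies are distinct features.
#'
#' @param aln A [align_copies()] result.
#' @param context Flank width in bp taken from the segment-carrying copy.
#' @return A tibble with columns `gap_copy` (`"a"`/`"b"`), `col_start`,
#'   `col_end` (0-based half-open alignment columns), `length`, `a_pos`,
#'   `b_pos` (0-based position of the feature in each copy: segment start in
#'   the carrier, gap locus in the gapped copy), `segment`, `left_ctx`,
#'   `right_ctx`.
#' @export
extract_indels <- function(aln, context = 30L) {
  r <- rle(aln$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_gap <- r$values %in% c("gap_in_a", "gap_in_b")
  if (!any(is_gap)) {
    return(tibble(gap_copy = character(), col_start = integer(),
                  col_end = integer(), length = integer(),
                  a_pos = integer(), b_pos = integer(), segment = character(),
                  left_ctx = character(), right_ctx = character()))
  }
  a_str <- gsub("-", "", aln$a, fixed = TRUE)
  b_str <- gsub("-", "", aln$b, fixed = TRUE)
  anchor_a <- column_a_anchor(aln)
  # anchor on the B axis, for gap loci in B
  anchor_b <- {
    pos <- aln$b_pos; last <- 0L
    for (i in seq_along(pos)) if (is.na(pos[i])) pos[i] <- last else last <- pos[i]
    pos
  }
  purrr::map_dfr(which(is_gap), function(ri) {
    cs <- starts[ri]; ce <- ends[ri]
    g <- r$lengths[ri]
    gap_copy <- if (r$values[ri] == "gap_in_a") "a" else "b"
    if (gap_copy == "a") {
      seg_start <- aln$b_pos[cs]
      carrier <- b_str
      a_locus <- if (cs > 1L) anchor_a[cs - 1L] + 1L else 0L
      b_locus <- seg_start
    } else {
      seg_start <- aln$a_pos[cs]
      carrier <- a_str
      a_locus <- seg_start
      b_locus <- if (cs > 1L) anchor_b[cs - 1L] + 1L else 0L
    }
    tibble(
      gap_copy = gap_copy, col_start = cs - 1L, col_end = ce,
      length = g, a_pos = a_locus, b_pos = b_locus,
      segment = subseq0(carrier, seg_start, seg_start + g),
      left_ctx = subseq0(carrier, max(0L, seg_start - context), seg_start),
      right_ctx = subseq0(carrier, seg_start + g,
                          min(nchar(carrier), seg_start + g + context)))
  })
}

# Slide a gap window through its score-equivalent placements: dir = -1 shifts
# it leftmost, dir = +1 rightmost. Returns the (segment, left, right) triple
# of the extreme placement. Classification runs on both extremes so that the
# call does not depend on where the aligner happened to put the gap.
normalize_gap <- function(seg, left, right, dir, max_shift = 200L) {
  g <- nchar(seg)
  for (s in seq_len(max_shift)) {
    if (dir < 0) {
      nl <- nchar(left)
      if (nl == 0L || substring(left, nl, nl) != substring(seg, g, g)) break
      right <- paste0(substring(seg, g, g), right)
      seg <- paste0(substring(left, nl, nl), substring(seg, 1L, g - 1L))
      left <- substring(left, 1L, nl - 1L)
    } else {
      if (nchar(right) == 0L ||
          substring(right, 1L, 1L) != substring(seg, 1L, 1L)) break
      left <- paste0(left, substring(seg, 1L, 1L))
      seg <- paste0(substring(seg, 2L, g), substring(right, 1L, 1L))
      right <- substring(right, 2L)
    }
  }
  list(seg = seg, left = left, right = right)
}

# Smallest tandem period of `seg` (>= min_unit) whose unit equals the
# immediately adjacent upstream or downstream sequence; NA when none.
tandem_unit <- function(seg, left_ctx, right_ctx, min_unit) {
  g <- nchar(seg)
  divisors <- seq_len(g)[g %% seq_len(g) == 0L]
  for (u in divisors[divisors >= min_unit]) {
    unit <- substring(seg, 1L, u)
    if (strrep(unit, g / u) != seg) next
    up <- if (nchar(left_ctx) >= u) {
      substring(left_ctx, nchar(left_ctx) - u + 1L, nchar(left_ctx))
    } else ""
    down <- if (nchar(right_ctx) >= u) substring(right_ctx, 1L, u) else ""
    if (identical(up, unit) || identical(down, unit)) return(unit)
  }
  NA_character_
}

#' Classify indels into double-strand-break repair signatures
#'
#' Implements the two alignment-gap signatures expected from
#' duplication-dependent strand annealing (DDSA), a synthesis-dependent
#' strand-annealing variant: a template jump during repair synthesis deletes
#' a segment and leaves *microhomology* (the deleted segment shares a
#' terminal `>= min_mh` bp with the retained flank, but less than the whole
#' segment), voting the gap-carrying copy as neosynthesized; a reinvasion
#' upstream of the dissociation site inserts a *tandem repeat* (the extra
#' segment is an exact repetition of the adjacent unit of `>= min_unit` bp),
#' voting the copy carrying the insertion as neosynthesized, with a
#' `slippage_caveat` because replication slippage after the duplication can
#' mimic it. A fully periodic tandem-unit gap is classified as
#' `tandem_repeat` (its full-length flank homology is explained by the
#' periodicity); otherwise flank homology in `[min_mh, max_mh]` and shorter
#' than the gap yields `microhomology_jump`; anything else is unclassified.
#'
#' @param indels Tibble from [extract_indels()].
#' @param min_mh,max_mh Accepted microhomology length range in bp.
#' @param min_unit Minimum tandem unit length in bp.
#' @param copy_roles Named character mapping aligned copies to duplication
#'   roles, e.g. `c(a = "distal", b = "proximal")` (copy A distal).
#' @return The input tibble with added columns `kind`
#'   (`"microhomology_jump"`, `"tandem_repeat"`, or `NA`), `evidence`
#'   (microhomology or tandem-unit string), `neosynthesized_vote`
#'   (`"proximal"`/`"distal"`/`NA`), `slippage_caveat`.
#' @examples
#' aln <- align_copies("ACGTAGGCTAGTAGCA", "ACGTAGTAGCA")
#' classify_indels(extract_indels(aln))[, c("kind", "evidence")]
#' @export
classify_indels <- function(indels, min_mh = 2L, max_mh = 25L, min_unit = 3L,
                            copy_roles = c(a = "distal", b = "proximal")) {
  if (nrow(indels) == 0) {
    return(dplyr::mutate(indels, kind = character(), evidence = character(),
                         neosynthesized_vote = character(),
                         slippage_caveat = logical()))
  }
  res <- purrr::map_dfr(seq_len(nrow(indels)), function(i) {
    x <- indels[i, ]
    g <- x$length
    variants <- list(
      list(seg = x$segment, left = x$left_ctx, right = x$right_ctx),
      normalize_gap(x$segment, x$left_ctx, x$right_ctx, dir = -1L),
      normalize_gap(x$segment, x$left_ctx, x$right_ctx, dir = 1L))
    unit <- NA_character_
    lcp <- 0L; lcs <- 0L
    for (v in variants) {
      if (is.na(unit)) unit <- tandem_unit(v$seg, v$left, v$right, min_unit)
      vl <- lcp_len(v$seg, v$right)
      vs <- lcs_len(v$seg, v$left)
      if (vl > lcp) { lcp <- vl; mh_seg <- v$seg }
      if (vs > lcs) { lcs <- vs; mh_seg_s <- v$seg }
    }
    mh <- max(lcp, lcs)
    if (!is.na(unit)) {
      # insertion carried by the non-gapped copy
      carrier <- setdiff(c("a", "b"), x$gap_copy)
      tibble(kind = "tandem_repeat", evidence = unit,
             neosynthesized_vote = unname(copy_roles[carrier]),
             slippage_caveat = TRUE)
    } else if (mh >= min_mh && mh <= max_mh && mh < g) {
      ev <- if (lcp >= lcs) substring(mh_seg, 1L, lcp) else {
        substring(mh_seg_s, g - lcs + 1L, g)
      }
      tibble(kind = "microhomology_jump", evidence = ev,
             neosynthesized_vote = unname(copy_roles[x$gap_copy]),
             slippage_caveat = FALSE)
    } else {
      tibble(kind = NA_character_, evidence = NA_character_,
             neosynthesized_vote = NA_character_, slippage_caveat = FALSE)
    }
  })
  dplyr::bind_cols(indels, res)
}

#' Infer the neosynthesized copy by majority vote over signatures
#'
#' @param signatures Tibble from [classify_indels()] (unclassified rows are
#'   ignored).
#' @return An object of class `neosyn_verdict`: list with `verdict`
#'   (`"proximal"`, `"distal"`, or `"undetermined"`), `votes` (tibble of
#'   counts per copy and kind), `n_proximal`, `n_distal`, `n_slippage`.
#' @export
infer_neosynthesized <- function(signatures) {
  sig <- signatures[!is.na(signatures$kind), , drop = FALSE]
  n_p <- sum(sig$neosynthesized_vote == "proximal")
  n_d <- sum(sig$neosynthesized_vote == "distal")
  verdict <- if (n_p == n_d) "undetermined" else if (n_p > n_d) "proximal" else "distal"
  votes <- if (nrow(sig) > 0) {
    dplyr::count(sig, .data$neosynthesized_vote, .data$kind, name = "n")
  } else {
    tibble(neosynthesized_vote = character(), kind = character(), n = integer())
  }
  structure(
    list(verdict = verdict, votes = votes, n_proximal = n_p, n_distal = n_d,
         n_slippage = sum(sig$slippage_caveat)),
    class = "neosyn_verdict")
}

#' @export
print.neosyn_verdict <- function(x, ...) {
  cat(sprintf(
    "Neosynthesized copy: %s (%d proximal vs %d distal vote(s); %d with slippage caveat)\n",
    x$verdict, x$n_proximal, x$n_distal, x$n_slippage))
  invisible(x)
}

#' @export
tidy.neosyn_verdict <- function(x, ...) x$votes

#' @export
glance.neosyn_verdict <- function(x, ...) {
  tibble(verdict = x$verdict, n_proximal = x$n_proximal,
         n_distal = x$n_distal, n_slippage = x$n_slippage)
}
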