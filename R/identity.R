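# Assign every alignment column to a copy-A coordinate: gap-in-A columns are
# attributed to their left-flanking A position (leading gaps to position 0).
column_a_anchor <- function(aln) {
  pos <- aln$a_pos
  filled <- pos
  last <- 0L
  for (i in seq_along(filled)) {
    if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
  }
  filled
}

#' Sliding-window identity between the two aligned copies
#'
#' Percent identity in windows anchored on copy-A coordinates: each window
#' `[start, start + window)` counts the alignment columns attributed to those
#' A positions; gap columns count as differences and are attributed to their
#' left-flanking A coordinate. Percentages are reported to 2 decimals.
#'
#' @param aln A [align_copies()] result.
#' @param window Window size in copy-A bp.
#' @param step Step size in bp.
#' @return A tibble of class `identity_profile` with columns `start`, `end`
#'   (0-based half-open, copy-A coordinates) and `pct_identity`. If `window`
#'   exceeds copy A, a single truncated window is returned with attribute
#'   `truncated = TRUE`.
#' @examples
#' aln <- align_copies(strrep("ACGT", 30), strrep("ACGT", 30))
#' sliding_identity(aln, window = 20, step = 20)
#' @export
sliding_identity <- function(aln, window = 50L, step = 10L) {
  if (window < 1 || step < 1) abort("`window` and `step` must be >= 1")
  len_a <- sum(!is.na(aln$a_pos))
  anchor <- column_a_anchor(aln)
  n_cols <- tabulate(anchor + 1L, nbins = len_a)
  n_match <- tabulate((anchor + 1L)[aln$state == "match"], nbins = len_a)
  truncated <- window > len_a
  w <- min(window, len_a)
  starts <- seq(0L, len_a - w, by = step)
  ccols <- c(0L, cumsum(n_cols))
  cmatch <- c(0L, cumsum(n_match))
  tot <- ccols[starts + w + 1L] - ccols[starts + 1L]
  hit <- cmatch[starts + w + 1L] - cmatch[starts + 1L]
  out <- tibble(start = starts, end = starts + w,
                pct_identity = round(100 * hit / tot, 2))
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  attr(out, "truncated") <- truncated
  class(out) <- c("identity_profile", class(out))
  out
}

#' Longest run of consecutive identical columns
#'
#' The maximal run of `match` columns in the alignment, reported in copy-A
#' coordinates; ties are broken leftmost. Its length in bp equals the number
#' of match columns in the run.
#'
#' @param aln A [align_copies()] result.
#' @return A one-row tibble with `start`, `end` (0-based half-open in copy A)
#'   and `length`.
#' @export
longest_identical_run <- function(aln) {
  if (aln$n_col == 0) abort("empty alignment")
  r <- rle(aln$state == "match")
  if (!any(r$values)) {
    return(tibble(start = NA_integer_, end = NA_integer_, length = 0L))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which(r$values)[which.max(r$lengths[r$values])]
  col_s <- starts[best]; col_e <- ends[best]
  tibble(start = aln$a_pos[col_s], end = aln$a_pos[col_e] + 1L,
         length = r$lengths[best])
}

#' Mean identity outside an excluded copy-A interval
#'
#' `100 * matches / columns` over all alignment columns whose copy-A anchor
#' lies outside `excluded` (0-based half-open). Gap columns count as
#' differences.
#'
#' @param aln A [align_copies()] result.
#' @param excluded Numeric `c(start, end)` in copy-A coordinates; `c(0, 0)`
#'   excludes nothing.
#' @return Percent identity (numeric scalar, 2 decimals).
#' @export
mean_identity_excluding <- function(aln, excluded = c(0, 0)) {
  if (length(excluded) != 2 || excluded[2] < excluded[1]) {
    abort("`excluded` must be c(start, end) with start <= end")
  }
  anchor <- column_a_anchor(aln)
  keep <- anchor < excluded[1] | anchor >= excluded[2]
  if (!any(keep)) abort("`excluded` covers the whole alignment")
  round(100 * sum(aln$state[keep] == "match") / sum(keep), 2)
}

#' Plot a sliding-window identity profile
#'
#' @param object An [sliding_identity()] profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
autoplot.identity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$pct_identity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "position in copy A (bp)", y = "% identity") +
    ggplot2::coord_cartesian(ylim = c(min(object$pct_identity) - 1, 100)) +
    ggplot2::theme_minimal()
}

#' Dot-plot of k-mer self-matches
#'
#' @param matches A [kmer_self_matches()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_self_matches <- function(matches, ...) {
  ggplot2::ggplot(matches, ggplot2::aes(x = .data$pos_i, y = .data$pos_j,
                                        colour = .data$strand)) +
    ggplot2::geom_point(size = 0.2) +
    ggplot2::scale_colour_manual(values = c("+" = "black", "-" = "red")) +
    ggplot2::labs(x = "position (bp)", y = "position (bp)") +
    ggplot2::theme_minimal()
}
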