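#' Relative quantification by the delta-delta-Ct method
#'
#' For each sample, `dCt = Ct(target) - mean(Ct(references))` per replicate
#' (references aggregated by arithmetic mean of their Cts, i.e. geometric
#' mean of quantities); `ddCt = dCt(sample) - dCt(calibrator)`; the ratio is
#' `base^(-ddCt)` with `base = 2` corresponding to 100% amplification
#' efficiency. Replicates are paired by index when the sample and calibrator
#' have equally many; otherwise all pairings are formed.
#'
#' @param ct Tibble with columns `sample`, `gene`, `replicate`, `ct`.
#' @param target Target gene id.
#' @param references Character vector of reference gene ids.
#' @param sample,calibrator Sample ids.
#' @param base Amplification base; 2 for 100% efficiency.
#' @return A tibble with one row per replicate pairing: `replicate_sample`,
#'   `replicate_calibrator`, `ddct`, `ratio`.
#' @examples
#' ct <- generate_ct_table(2.76, n_replicates = 3, ct_noise_sd = 0, seed = 1)
#' ddct_ratio(ct, "Hosim1", c("GAPDH", "RPL17"), "XSR6", "XST8")
#' @export
ddct_ratio <- function(ct, target, references, sample, calibrator, base = 2) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    abort(paste("`ct` must have columns", paste(need, collapse = ", ")))
  }
  for (s in c(sample, calibrator)) {
    for (g in c(target, references)) {
      if (!any(ct$sample == s & ct$gene == g)) {
        abort(sprintf("no Ct rows for sample '%s', gene '%s'", s, g))
      }
    }
  }
  dct <- function(s) {
    d <- ct[ct$sample == s & ct$gene %in% c(target, references), , drop = FALSE]
    tg <- d[d$gene == target, ]
    rf <- dplyr::summarise(dplyr::group_by(d[d$gene %in% references, ],
                                           .data$replicate),
                           ref_ct = mean(.data$ct), .groups = "drop")
    out <- dplyr::inner_join(tg[, c("replicate", "ct")], rf, by = "replicate")
    if (nrow(out) == 0) abort(sprintf(
      "sample '%s': target and reference replicates do not overlap", s))
    dplyr::mutate(out, dct = .data$ct - .data$ref_ct)
  }
  ds <- dct(sample); dc <- dct(calibrator)
  pairs <- if (nrow(ds) == nrow(dc)) {
    tibble(replicate_sample = ds$replicate, dct_s = ds$dct,
           replicate_calibrator = dc$replicate, dct_c = dc$dct)
  } else {
    tidyr::expand_grid(s = seq_len(nrow(ds)), c = seq_len(nrow(dc))) |>
      dplyr::mutate(replicate_sample = ds$replicate[.data$s],
                    dct_s = ds$dct[.data$s],
                    replicate_calibrator = dc$replicate[.data$c],
                    dct_c = dc$dct[.data$c]) |>
      dplyr::select(-"s", -"c")
  }
  dplyr::transmute(pairs,
                   replicate_sample = .data$replicate_sample,
                   replicate_calibrator = .data$replicate_calibrator,
                   ddct = .data$dct_s - .data$dct_c,
                   ratio = base^(-.data$ddct))
}

#' Mean ratio and Student-t confidence interval on the log2 scale
#'
#' Ratios from cycle measurements are log-normal under Gaussian cycle noise,
#' so the mean and the confidence interval are computed on the `log2(ratio)`
#' (i.e. `-ddCt`) scale and back-transformed; the reported point estimate is
#' therefore the geometric mean of the replicate ratios.
#'
#' @param ratios Numeric vector of replicate ratios (length >= 2), or a
#'   [ddct_ratio()] tibble.
#' @param conf Confidence level.
#' @return A one-row tibble: `ratio`, `ci_low`, `ci_high`, `n`.
#' @examples
#' ratio_ci(c(2, 8))  # geometric mean 4
#' @export
ratio_ci <- function(ratios, conf = 0.95) {
  if (is.data.frame(ratios)) ratios <- ratios$ratio
  if (length(ratios) < 2) abort("need >= 2 replicate ratios")
  if (any(ratios <= 0)) abort("ratios must be positive")
  l <- log2(ratios)
  m <- mean(l)
  se <- stats::sd(l) / sqrt(length(l))
  tq <- stats::qt(1 - (1 - conf) / 2, df = length(l) - 1)
  tibble(ratio = 2^m, ci_low = 2^(m - tq * se), ci_high = 2^(m + tq * se),
         n = length(l))
}

#' Mann-Whitney rank-sum test with exact small-sample enumeration
#'
#' Computes the U statistic with mid-ranks for ties. For
#' `length(a) + length(b) <= exact_max` the two-sided p-value is exact:
#' every assignment of the pooled values into groups of the observed sizes
#' is enumerated and `p = P(|U - n_a n_b / 2| >= |U_obs - n_a n_b / 2|)`.
#' Larger samples use the normal approximation with tie correction and
#' continuity correction, flagged in `method`.
#'
#' @param a,b Numeric vectors.
#' @param exact_max Maximum pooled size for exact enumeration.
#' @return A one-row tibble: `statistic` (U of the first group), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_max = 12L) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled) # mid-ranks
  u_of <- function(idx_a) sum(rk[idx_a]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  if (na + nb <= exact_max) {
    sets <- utils::combn(na + nb, na)
    us <- apply(sets, 2L, u_of)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- na + nb
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal_approx"
  }
  tibble(statistic = u_obs, p_value = p, method = method)
}

#' Copy-number estimate from a relative quantification ratio
#'
#' Scales a target-to-calibrator ratio by the calibrator's known copy count:
#' `total = ratio * baseline`, `extra = total - baseline`. Both raw and
#' rounded (half away from zero) values are reported so that a near-1 ratio
#' can be read as "no extra copy".
#'
#' @param ratio Positive ratio (sample relative to calibrator).
#' @param baseline_copies Copies in the calibrator genome (>= 1).
#' @param ci Optional `c(low, high)` ratio confidence interval to propagate.
#' @return An object of class `copy_estimate`; its [tidy()] method gives a
#'   one-row tibble with `ratio`, `total_copies`, `extra_copies`,
#'   `rounded_total`, `rounded_extra` (and CI columns when supplied).
#' @examples
#' copies_from_ratio(2.76, 4)  # ~11 total, 7 extra
#' @export
copies_from_ratio <- function(ratio, baseline_copies, ci = NULL) {
  stopif_not_scalar_number(ratio, "ratio", min = .Machine$double.xmin)
  stopif_not_scalar_number(baseline_copies, "baseline_copies", min = 1)
  total <- ratio * baseline_copies
  extra <- total - baseline_copies
  out <- structure(
    list(ratio = ratio, baseline_copies = baseline_copies,
         ci95 = ci, total_copies = total, extra_copies = extra,
         rounded_total = as.integer(round_half_away(total)),
         rounded_extra = as.integer(round_half_away(extra))),
    class = "copy_estimate")
  out
}

#' @export
print.copy_estimate <- function(x, ...) {
  cat(sprintf(
    "Copy-number estimate: ratio %.3g x %d baseline copies = %.2f total (~%d), %.2f extra (~%d)\n",
    x$ratio, x$baseline_copies, x$total_copies, x$rounded_total,
    x$extra_copies, x$rounded_extra))
  if (!is.null(x$ci95)) {
    cat(sprintf("  ratio 95%% CI: [%.3g, %.3g] -> total copies [%.2f, %.2f]\n",
                x$ci95[1], x$ci95[2], x$ci95[1] * x$baseline_copies,
                x$ci95[2] * x$baseline_copies))
  }
  invisible(x)
}

#' @export
tidy.copy_estimate <- function(x, ...) {
  out <- tibble(ratio = x$ratio, total_copies = x$total_copies,
                extra_copies = x$extra_copies,
                rounded_total = x$rounded_total,
                rounded_extra = x$rounded_extra)
  if (!is.null(x$ci95)) {
    out$ratio_ci_low <- x$ci95[1]
    out$ratio_ci_high <- x$ci95[2]
  }
  out
}

#' @export
glance.copy_estimate <- function(x, ...) tidy(x, ...)

#' One-call relative quantification of copy number from a Ct table
#'
#' Convenience pipeline: [ddct_ratio()] per-pairing ratios, [ratio_ci()],
#' a [mann_whitney()] comparison of the per-replicate dCt values of sample
#' vs calibrator, and [copies_from_ratio()].
#'
#' @inheritParams ddct_ratio
#' @param baseline_copies Calibrator copy count.
#' @return A one-row tibble: `ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `total_copies`, `extra_copies`, `rounded_total`, `rounded_extra`.
#' @export
quantify_copies <- function(ct, target, references, sample, calibrator,
                            baseline_copies = 4L, base = 2) {
  rr <- ddct_ratio(ct, target, references, sample, calibrator, base = base)
  ci <- ratio_ci(rr$ratio)
  # rank-sum on per-replicate dCt values
  dct_of <- function(s) {
    d <- ct[ct$sample == s, ]
    tg <- d[d$gene == target, ]
    rf <- dplyr::summarise(dplyr::group_by(d[d$gene %in% references, ],
                                           .data$replicate),
                           ref_ct = mean(.data$ct), .groups = "drop")
    j <- dplyr::inner_join(tg[, c("replicate", "ct")], rf, by = "replicate")
    j$ct - j$ref_ct
  }
  mw <- mann_whitney(dct_of(sample), dct_of(calibrator))
  est <- copies_from_ratio(ci$ratio, baseline_copies,
                           ci = c(ci$ci_low, ci$ci_high))
  tibble(ratio = ci$ratio, ci_low = ci$ci_low, ci_high = ci$ci_high,
         p_value = mw$p_value, total_copies = est$total_copies,
         extra_copies = est$extra_copies, rounded_total = est$rounded_total,
         rounded_extra = est$rounded_extra)
}
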