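#' Run the full duplication-characterization pipeline
#'
#' Orchestrates generate/read -> self-match -> duplication call -> copy
#' alignment -> identity profile -> repair-signature classification ->
#' junction module decomposition -> age dating, and returns one consolidated
#' report. Exactly one of `scenario` or `fasta` must be supplied. With a
#' scenario input, the fixture is generated with `seed` and the fixture
#' consensus sequences are used for the module stage; with a FASTA input,
#' consensus sequences can be passed via `te_consensus`/`rist_consensus`
#' (the module stage is skipped otherwise). The age stage uses the detected
#' longest identical run as the tract length `L`.
#'
#' @param scenario A [dup_scenario()], or `NULL`.
#' @param fasta Path to a FASTA file (first record is analysed), or `NULL`.
#' @param seed Integer seed controlling fixture generation.
#' @param k Self-match word size.
#' @param min_copy_length Minimum copy length for a duplication call (bp).
#' @param window,step Identity-profile window and step (bp).
#' @param context Indel flank context (bp).
#' @param min_mh,max_mh,min_unit Signature-classification thresholds (bp).
#' @param min_identity Minimum module-scan identity (percent).
#' @param tir Terminal inverted repeat for TE annotation.
#' @param tsd_range `c(min, max)` TSD length range (bp).
#' @param te_consensus,rist_consensus Optional consensus sequences for FASTA
#'   input.
#' @param r,mu,P,generations_per_year Age-model parameters (see
#'   [solve_age()]).
#' @param out_dir Optional output directory for `report.json`,
#'   `identity_profile.tsv`, `signatures.tsv`, `modules.tsv`.
#' @return An object of class `dup_report` (a nested list); see Details.
#' @details Report elements: `duplication` (the boundary call), `identity`
#'   (longest identical run in absolute and copy coordinates, mean identity
#'   outside it, the window profile), `ddsa` (classified signatures and the
#'   neosynthesized-copy verdict), `modules` (TE hits with TIR/TSD
#'   annotation and the module tiling), `age` (the dated event), and
#'   `provenance` (seed and parameters). When no duplication is found,
#'   `duplication` is `NULL` and downstream stages are skipped.
#' @export
run_characterization <- function(scenario = NULL, fasta = NULL, seed = 1L,
                                 k = 16L, min_copy_length = 1000L,
                                 window = 50L, step = 10L, context = 30L,
                                 min_mh = 2L, max_mh = 25L, min_unit = 3L,
                                 min_identity = 90, tir = "TAGTGTTGGGT",
                                 tsd_range = c(4L, 12L),
                                 te_consensus = NULL, rist_consensus = NULL,
                                 r = 2e-8, mu = 1e-8, P = 0.05,
                                 generations_per_year = 10,
                                 out_dir = NULL) {
  if (is.null(scenario) == is.null(fasta)) {
    abort("supply exactly one of `scenario` or `fasta`")
  }
  if (!is.null(scenario)) {
    fixture <- generate_fixture(scenario, seed = seed)
    seq <- fixture$sequence
    if (is.null(te_consensus) && !is.na(fixture$te_consensus)) {
      te_consensus <- fixture$te_consensus
      rist_consensus <- fixture$rist_consensus
      tir <- scenario$tir_seq
    }
    input <- "scenario"
  } else {
    fa <- Biostrings::readDNAStringSet(fasta)
    seq <- as.character(fa[[1L]])
    input <- fasta
  }

  params <- list(seed = seed, k = k, min_copy_length = min_copy_length,
                 window = window, step = step, context = context,
                 min_mh = min_mh, max_mh = max_mh, min_unit = min_unit,
                 min_identity = min_identity, tir = tir,
                 tsd_range = tsd_range, r = r, mu = mu, P = P,
                 generations_per_year = generations_per_year)

  matches <- kmer_self_matches(seq, k = k)
  call <- detect_tandem_duplication(matches, min_copy_length = min_copy_length,
                                    seq = seq, k = k)
  report <- list(input = input, sequence_length = nchar(seq),
                 duplication = NULL, identity = NULL, ddsa = NULL,
                 modules = NULL, age = NULL, provenance = params)
  if (is.null(call)) {
    report$duplication <- "none"
    return(structure(report, class = "dup_report"))
  }
  report$duplication <- as.list(call)

  copy_a <- subseq0(seq, call$distal_start, call$distal_end)
  copy_b <- subseq0(seq, call$proximal_start, call$proximal_end)
  aln <- align_copies(copy_a, copy_b)
  run <- longest_identical_run(aln)
  profile <- sliding_identity(aln, window = window, step = step)
  mean_out <- mean_identity_excluding(aln, excluded = c(run$start, run$end))
  report$identity <- list(
    longest_run_start = call$distal_start + run$start,
    longest_run_end = call$distal_start + run$end,
    longest_run_length = run$length,
    mean_identity_outside_run = mean_out,
    profile = profile)

  signatures <- classify_indels(
    extract_indels(aln, context = context),
    min_mh = min_mh, max_mh = max_mh, min_unit = min_unit,
    copy_roles = c(a = "distal", b = "proximal"))
  verdict <- infer_neosynthesized(signatures)
  report$ddsa <- list(signatures = signatures,
                      n_classified = sum(!is.na(signatures$kind)),
                      verdict = verdict$verdict,
                      n_proximal = verdict$n_proximal,
                      n_distal = verdict$n_distal,
                      n_slippage = verdict$n_slippage)

  if (!is.null(te_consensus) && call$junction_end > call$junction_start) {
    junction_seq <- subseq0(seq, call$junction_start, call$junction_end)
    mods <- decompose_junction(junction_seq, te_consensus, rist_consensus,
                               min_identity = min_identity)
    te_hits <- attr(mods, "te_hits")
    if (!is.null(te_hits) && nrow(te_hits) > 0) {
      te_hits <- detect_tir_tsd(te_hits, junction_seq, tir = tir,
                                tsd_range = tsd_range)
    }
    report$modules <- list(
      n_te = if (is.null(te_hits)) 0L else nrow(te_hits),
      coverage = attr(mods, "coverage"),
      tiling = mods, te_hits = te_hits,
      tsd_lengths = if (!is.null(te_hits) && nrow(te_hits) > 0) {
        te_hits$tsd_len
      } else integer(0))
  }

  if (run$length > 0) {
    age <- solve_age(run$length, r = r, mu = mu, P = P,
                     generations_per_year = generations_per_year)
    report$age <- glance(age)
  }

  report <- structure(report, class = "dup_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Serialize the report: a stable JSON summary plus TSV tables.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- report
  json$identity$profile <- NULL
  json$ddsa$signatures <- NULL
  json$modules$tiling <- NULL
  json$modules$te_hits <- if (!is.null(report$modules$te_hits)) {
    as.data.frame(report$modules$te_hits)
  }
  jsonlite::write_json(unclass(json), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  if (!is.null(report$identity)) {
    readr::write_tsv(report$identity$profile,
                     file.path(out_dir, "identity_profile.tsv"))
  }
  if (!is.null(report$ddsa)) {
    readr::write_tsv(report$ddsa$signatures,
                     file.path(out_dir, "signatures.tsv"))
  }
  if (!is.null(report$modules)) {
    tiling <- report$modules$tiling
    attr(tiling, "rist_hits") <- NULL
    attr(tiling, "te_hits") <- NULL
    attr(tiling, "coverage") <- NULL
    readr::write_tsv(tiling, file.path(out_dir, "modules.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.dup_report <- function(x, ...) {
  cat("Duplication characterization report\n")
  cat(sprintf("  input: %s (%s bp)\n", x$input,
              format(x$sequence_length, big.mark = ",")))
  if (identical(x$duplication, "none")) {
    cat("  no tandem duplication detected\n")
    return(invisible(x))
  }
  d <- x$duplication
  cat(sprintf("  tandem duplication: copies [%s, %s) and [%s, %s), copy length %s bp\n",
              format(d$distal_start, big.mark = ","),
              format(d$distal_end, big.mark = ","),
              format(d$proximal_start, big.mark = ","),
              format(d$proximal_end, big.mark = ","),
              format(d$copy_length, big.mark = ",")))
  cat(sprintf("  longest identical run: %s bp; mean identity outside it: %.2f%%\n",
              format(x$identity$longest_run_length, big.mark = ","),
              x$identity$mean_identity_outside_run))
  cat(sprintf("  repair signatures: %d classified; neosynthesized copy: %s (%d vs %d)\n",
              x$ddsa$n_classified, x$ddsa$verdict, x$ddsa$n_proximal,
              x$ddsa$n_distal))
  if (!is.null(x$modules)) {
    cat(sprintf("  junction: %d TE copies; TSD length(s): %s\n",
                x$modules$n_te,
                paste(unique(x$modules$tsd_lengths), collapse = ", ")))
  }
  if (!is.null(x$age)) {
    cat(sprintf("  age: <= %.0f generations (~%d years, P = %g)\n",
                x$age$t_generations, x$age$t_years_rounded, x$provenance$P))
  }
  invisible(x)
}
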