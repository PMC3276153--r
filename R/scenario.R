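#' Describe a tandem-duplication scenario for the synthetic generator
#'
#' A scenario fixes every parameter of the synthetic region emitted by
#' [generate_fixture()]: a left flank, a distal copy, a junction of
#' transposable-element (TE) / repeat modules, a proximal copy, and a right
#' flank. All coordinates are 0-based, half-open. Positions of planted events,
#' the identical tract, and gene annotations are given in *template copy*
#' coordinates, i.e. on the shared pre-edit copy before the planted indels are
#' applied.
#'
#' Called with no arguments it returns the canonical `"xsr6-ref"` scenario
#' emulating the X-linked *sex-ratio* duplication of *Drosophila simulans*:
#' a 37,500 bp tandem duplication in direct orientation spanning six genes,
#' a 10,344 bp fully identical tract with 1.25% background divergence
#' elsewhere (mean identity 98.75%), a junction of six ~3.6 kb
#' TE/rIST/rIST modules (687 bp rISTs, 11 bp TIR `TAGTGTTGGGT`, 8 bp
#' target-site duplications, one module in reversed orientation), five
#' planted repair signatures (three microhomology-delimited deletions and one
#' tandem-repeat insertion in the proximal copy, one tandem-repeat insertion
#' in the distal copy), and a 65 bp deletion in the distal copy of the second
#' exon of the fourth spanned gene.
#'
#' `dup_length` is the length of the emitted distal copy; the shared template
#' is longer or shorter by the net planted indels in the distal copy. When
#' `dup_length` differs from the canonical 37,500 bp and signatures, genes or
#' the identical tract are not supplied, they default to none (an unmarked
#' exact scenario) rather than being rescaled.
#'
#' @param dup_length Length of the distal copy in bp.
#' @param dup_start 0-based start of the distal copy (= left flank length).
#' @param region_length Total emitted length; `NULL` (default) for a right
#'   flank equal in length to the left flank.
#' @param n_modules Number of TE/rIST/rIST junction modules; `0` gives an
#'   empty junction (exact tandem).
#' @param te_length TE element length in bp, terminal inverted repeats
#'   included. Default 2,226 so that a module is exactly 3.6 kb.
#' @param rist_length Length of the rIST repeat unit in bp.
#' @param tsd_length Target-site duplication length in bp.
#' @param tir_seq Terminal inverted repeat sequence.
#' @param identical_tract Numeric `c(offset, length)` of the fully identical
#'   tract, in template copy coordinates. `c(0, 0)` for none.
#' @param background_divergence Per-bp substitution probability between the
#'   copies outside the identical tract, in `[0, 1)`.
#' @param rist_divergence Per-bp substitution probability of each rIST copy
#'   relative to the rIST consensus.
#' @param te_divergence Per-bp substitution probability of each TE copy
#'   relative to the TE consensus.
#' @param te_site Restriction site planted once in the 5' region of the TE
#'   consensus (and scrubbed elsewhere in the junction components).
#' @param te_site_offset 0-based offset of the planted site within the TE.
#' @param planted_signatures Tibble of planted indel events with columns
#'   `kind` (`"microhomology_jump"`, `"tandem_repeat"`, or `"deletion"`),
#'   `pos` (0-based template position), `size` (deleted length, or tandem
#'   unit length for insertions), `mh_len` (microhomology length, `NA` unless
#'   `kind == "microhomology_jump"`), and `copy` (`"distal"`/`"proximal"`,
#'   the copy receiving the edit).
#' @param planted_genes Tibble with columns `name`, `start`, `end`, `strand`
#'   in template copy coordinates.
#' @param reversed_module_index 0-based index of the junction module whose TE
#'   is reversed, or `NULL` for none.
#' @param seed Default RNG seed used by [generate_fixture()].
#' @return A validated object of class `dup_scenario` (a named list).
#' @seealso [build_scenario()] for the key-value mapping interface.
#' @examples
#' sc <- dup_scenario()           # canonical xsr6-ref defaults
#' sc$dup_length                  # 37500
#' @export
dup_scenario <- function(dup_length = 37500L,
                         dup_start = 5000L,
                         region_length = NULL,
                         n_modules = 6L,
                         te_length = 2226L,
                         rist_length = 687L,
                         tsd_length = 8L,
                         tir_seq = "TAGTGTTGGGT",
                         identical_tract = NULL,
                         background_divergence = 0.0125,
                         rist_divergence = 0.003,
                         te_divergence = 0.005,
                         te_site = "GGATCC",
                         te_site_offset = 100L,
                         planted_signatures = NULL,
                         planted_genes = NULL,
                         reversed_module_index = 0L,
                         seed = 1859L) {
  canonical <- isTRUE(all.equal(as.numeric(dup_length), 37500))
  if (is.null(identical_tract)) {
    identical_tract <- if (canonical) c(13000, 10344) else c(0, 0)
  }
  if (is.null(planted_signatures)) {
    planted_signatures <- if (canonical) canonical_signatures() else empty_signatures()
  }
  if (is.null(planted_genes)) {
    planted_genes <- if (canonical) canonical_genes() else empty_genes()
  }
  sc <- structure(
    list(
      dup_length = as.integer(dup_length),
      dup_start = as.integer(dup_start),
      region_length = if (is.null(region_length)) NULL else as.integer(region_length),
      n_modules = as.integer(n_modules),
      te_length = as.integer(te_length),
      rist_length = as.integer(rist_length),
      tsd_length = as.integer(tsd_length),
      tir_seq = toupper(tir_seq),
      identical_tract = as.numeric(identical_tract),
      background_divergence = background_divergence,
      rist_divergence = rist_divergence,
      te_divergence = te_divergence,
      te_site = toupper(te_site),
      te_site_offset = as.integer(te_site_offset),
      planted_signatures = as_tibble(planted_signatures),
      planted_genes = as_tibble(planted_genes),
      reversed_module_index = if (is.null(reversed_module_index)) NULL else as.integer(reversed_module_index),
      seed = as.integer(seed)),
    class = "dup_scenario")
  validate_scenario(sc)
}

canonical_signatures <- function() {
  tibble(
    kind = c("microhomology_jump", "microhomology_jump", "microhomology_jump",
             "tandem_repeat", "tandem_repeat", "deletion"),
    pos = c(2400, 5200, 8100, 30300, 32600, 26300),
    size = c(12, 9, 15, 12, 9, 65),
    mh_len = c(3, 4, 2, NA, NA, NA),
    copy = c("proximal", "proximal", "proximal", "proximal", "distal", "distal"))
}

empty_signatures <- function() {
  tibble(kind = character(), pos = numeric(), size = numeric(),
         mh_len = numeric(), copy = character())
}

canonical_genes <- function() {
  # Analogue of the six genes spanned by the duplication: two truncated genes
  # at the copy ends and four complete genes in between; the 65 bp deletion
  # default falls inside gene4.
  tibble(
    name = c("gene1_Trf2", "gene2_CG12125", "gene3_CG1440",
             "gene4_CG32712_like", "gene5_CG12123", "gene6_org1"),
    start = c(0, 11000, 15000, 25500, 29000, 33800),
    end = c(9500, 13800, 19000, 28600, 31800, 37500),
    strand = c("+", "-", "+", "+", "-", "+"))
}

empty_genes <- function() {
  tibble(name = character(), start = numeric(), end = numeric(),
         strand = character())
}

#' Build a scenario from a key-value mapping
#'
#' Thin wrapper over [dup_scenario()]: fields present in `config` override the
#' canonical `"xsr6-ref"` defaults; unknown fields are an error.
#'
#' @param config Named list of scenario fields (possibly empty).
#' @return A validated `dup_scenario`.
#' @examples
#' build_scenario(list())                     # canonical defaults
#' build_scenario(list(dup_length = 500, identical_tract = c(0, 500),
#'                     background_divergence = 0, n_modules = 0))
#' @export
build_scenario <- function(config = list()) {
  if (!is.list(config)) abort("`config` must be a named list")
  known <- names(formals(dup_scenario))
  bad <- setdiff(names(config), known)
  if (length(bad) > 0) {
    abort(paste0("unknown scenario field(s): ", paste(bad, collapse = ", ")))
  }
  do.call(dup_scenario, config)
}

# Length of the junction implied by a scenario: one leading rIST plus
# n_modules x (TE + rIST + rIST); empty when n_modules == 0.
junction_length <- function(sc) {
  if (sc$n_modules == 0L) return(0L)
  module <- sc$te_length + 2L * sc$rist_length
  sc$rist_length + sc$n_modules * module
}

# Net length change of planted edits for one copy: insertions minus deletions.
copy_net_indel <- function(sig, copy) {
  s <- sig[sig$copy == copy, , drop = FALSE]
  if (nrow(s) == 0) return(0L)
  as.integer(sum(ifelse(s$kind == "tandem_repeat", s$size, -s$size)))
}

# Planted-event footprint on the template, including the divergence-protection
# margin, as an IRanges-style matrix of 0-based half-open intervals.
signature_masks <- function(sig, margin = 35L) {
  if (nrow(sig) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  start <- ifelse(sig$kind == "tandem_repeat", sig$pos - sig$size, sig$pos) - margin
  end <- ifelse(sig$kind == "tandem_repeat", sig$pos, sig$pos + sig$size) + margin
  cbind(start = start, end = end)
}

validate_scenario <- function(sc) {
  msg <- function(...) abort(paste0("invalid scenario: ", sprintf(...)))
  if (sc$dup_length <= 0) msg("`dup_length` must be positive")
  if (sc$dup_start < 0) msg("`dup_start` must be >= 0")
  if (sc$n_modules < 0) msg("`n_modules` must be >= 0")
  if (!nzchar(sc$tir_seq)) msg("`tir_seq` must be non-empty")
  if (grepl("[^ACGT]", sc$tir_seq)) msg("`tir_seq` must be A/C/G/T only")
  if (sc$tsd_length < 0) msg("`tsd_length` must be >= 0")
  if (sc$background_divergence < 0 || sc$background_divergence >= 1) {
    msg("`background_divergence` must lie in [0, 1)")
  }
  if (length(sc$identical_tract) != 2) msg("`identical_tract` must be c(offset, length)")
  tr <- sc$identical_tract
  if (tr[1] < 0 || tr[2] < 0 || tr[1] + tr[2] > sc$dup_length) {
    msg("`identical_tract` must lie fully within [0, dup_length)")
  }
  if (sc$n_modules > 0) {
    if (sc$rist_length <= 2 * sc$tsd_length + 2) {
      msg("`rist_length` must exceed 2*tsd_length + 2")
    }
    if (sc$te_length < 2 * nchar(sc$tir_seq) + 20) {
      msg("`te_length` too short for the configured TIRs")
    }
    if (sc$te_site_offset < nchar(sc$tir_seq) ||
        sc$te_site_offset + nchar(sc$te_site) > sc$te_length - nchar(sc$tir_seq)) {
      msg("`te_site_offset` must fall between the TIRs")
    }
    if (!is.null(sc$reversed_module_index) &&
        (sc$reversed_module_index < 0 || sc$reversed_module_index >= sc$n_modules)) {
      msg("`reversed_module_index` out of range")
    }
  }
  sig <- sc$planted_signatures
  if (nrow(sig) > 0) {
    need <- c("kind", "pos", "size", "mh_len", "copy")
    missing_cols <- setdiff(need, names(sig))
    if (length(missing_cols) > 0) {
      msg("`planted_signatures` lacks column(s): %s", paste(missing_cols, collapse = ", "))
    }
    if (!all(sig$kind %in% c("microhomology_jump", "tandem_repeat", "deletion"))) {
      msg("`planted_signatures$kind` has an unknown value")
    }
    if (!all(sig$copy %in% c("distal", "proximal"))) {
      msg("`planted_signatures$copy` must be distal/proximal")
    }
    mh <- sig$kind == "microhomology_jump"
    if (any(mh & (is.na(sig$mh_len) | sig$mh_len < 1))) {
      msg("microhomology_jump rows need `mh_len` >= 1")
    }
    if (any(mh & sig$mh_len >= sig$size)) {
      msg("`mh_len` must be strictly smaller than the deletion `size`")
    }
    if (any(sig$size < 1)) msg("`planted_signatures$size` must be >= 1")
    m <- signature_masks(sig, margin = 36L)
    if (any(m[, "start"] < 0) || any(m[, "end"] > sc$dup_length)) {
      msg("a planted signature (plus its 36 bp margin) falls outside the copy")
    }
    o <- order(m[, "start"])
    if (nrow(m) > 1 && any(m[o, "start"][-1] < m[o, "end"][-nrow(m)])) {
      msg("planted signatures overlap (36 bp margins included)")
    }
    if (tr[2] > 0 &&
        any(m[, "end"] > tr[1] & m[, "start"] < tr[1] + tr[2])) {
      msg("planted signatures must not overlap the identical tract")
    }
  }
  g <- sc$planted_genes
  if (nrow(g) > 0) {
    if (any(g$start < 0) || any(g$end > sc$dup_length) || any(g$end <= g$start)) {
      msg("`planted_genes` intervals must lie within [0, dup_length)")
    }
    if (!all(g$strand %in% c("+", "-"))) msg("gene `strand` must be +/-")
  }
  # total layout must fit in the region
  net_d <- copy_net_indel(sig, "distal")
  net_p <- copy_net_indel(sig, "proximal")
  template_len <- sc$dup_length - net_d
  if (template_len <= 0) msg("planted indels exceed `dup_length`")
  proximal_len <- template_len + net_p
  total <- sc$dup_start + sc$dup_length + junction_length(sc) + proximal_len
  if (is.null(sc$region_length)) {
    sc$region_length <- total + sc$dup_start
  } else if (sc$region_length < total) {
    msg("`region_length` (%d) smaller than layout total (%d)", sc$region_length, total)
  }
  sc
}

#' @export
print.dup_scenario <- function(x, ...) {
  cat(sprintf(
    paste0("Tandem-duplication scenario\n",
           "  region %s bp; distal copy [%s, %s); junction %s bp (%d modules); ",
           "divergence %.4g\n  identical tract offset %s, length %s; ",
           "%d planted signature(s); %d gene(s); seed %d\n"),
    format(x$region_length, big.mark = ","),
    format(x$dup_start, big.mark = ","),
    format(x$dup_start + x$dup_length, big.mark = ","),
    format(junction_length(x), big.mark = ","),
    x$n_modules, x$background_divergence,
    format(x$identical_tract[1], big.mark = ","),
    format(x$identical_tract[2], big.mark = ","),
    nrow(x$planted_signatures), nrow(x$planted_genes), x$seed))
  invisible(x)
}
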