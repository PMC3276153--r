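#' Generate a seeded, ground-truthed synthetic duplication fixture
#'
#' Emits one chromosome-like sequence realizing a [dup_scenario()]: left
#' flank, distal copy, junction (one leading rIST followed by `n_modules`
#' TE/rIST/rIST modules, one TE optionally reversed), proximal copy, right
#' flank. Background substitutions between the two copies are applied only
#' outside the identical tract and away from planted events; planted
#' repair-signature indels are engineered so that their microhomology or
#' tandem-unit evidence is exactly recoverable from the emitted sequence.
#' Every coordinate claimed by the returned ground truth addresses the
#' emitted sequence.
#'
#' Two deterministic adjustments keep the ground truth maximal, i.e. equal to
#' what an analysis of the emitted sequence should find: (i) when
#' `background_divergence > 0`, the template bases immediately flanking the
#' identical tract are forced to differ between the copies, so the recorded
#' tract is the *longest* identical run; (ii) the flank bases immediately
#' outside each copy boundary are forced to differ from their counterpart
#' position, so the recorded copy intervals are the maximal homologous
#' extents.
#'
#' @param scenario A `dup_scenario`.
#' @param seed Integer RNG seed; defaults to `scenario$seed`. The same
#'   (scenario, seed) pair always produces byte-identical output.
#' @return An object of class `dup_fixture`: a list with elements `sequence`
#'   (character), `te_consensus`, `rist_consensus`, `scenario`, `seed`, and
#'   `truth` (ground-truth coordinates; see Details). All truth coordinates
#'   are 0-based, half-open, on the emitted sequence.
#' @details The `truth` element contains: `region_length`; `distal`,
#'   `proximal`, `junction` intervals; `identical_tract` per copy; `modules`
#'   and `rists` tibbles describing the junction layout (with TSD string and
#'   TE orientation); `signatures` (planted events with per-copy coordinates
#'   and evidence strings); `genes`; `divergence` (substituted template sites
#'   with per-copy positions and the `forced` flag); and `n_eligible`, the
#'   number of template sites at which background substitutions could occur.
#' @examples
#' fx <- generate_fixture(dup_scenario(dup_length = 800, n_modules = 1,
#'   te_length = 120, rist_length = 60, te_site_offset = 40,
#'   identical_tract = c(100, 300), dup_start = 200), seed = 7)
#' nchar(fx$sequence)
#' @export
generate_fixture <- function(scenario, seed = scenario$seed) {
  if (!inherits(scenario, "dup_scenario")) abort("`scenario` must be a dup_scenario")
  sc <- validate_scenario(scenario)
  withr::local_seed(as.integer(seed))

  sig <- sc$planted_signatures
  net_d <- copy_net_indel(sig, "distal")
  La <- sc$dup_length - net_d # template copy length
  tmpl <- random_bases(La)
  tmpl <- engineer_template(tmpl, sig)

  # Background divergence outside the identical tract and planted-event masks
  tr <- sc$identical_tract
  protect <- rep(FALSE, La)
  if (tr[2] > 0) protect[(tr[1] + 1):(tr[1] + tr[2])] <- TRUE
  m <- signature_masks(sig, margin = 36L)
  for (i in seq_len(nrow(m))) {
    lo <- max(1L, m[i, "start"] + 1L)
    hi <- min(La, m[i, "end"])
    if (lo <= hi) protect[lo:hi] <- TRUE
  }
  eligible <- which(!protect)
  div_pos <- eligible[stats::runif(length(eligible)) < sc$background_divergence]
  carrier <- if (length(div_pos) > 0) {
    sample(c("distal", "proximal"), length(div_pos), replace = TRUE)
  } else character(0)
  forced <- rep(FALSE, length(div_pos))
  if (tr[2] > 0 && sc$background_divergence > 0) {
    for (p in c(tr[1], tr[1] + tr[2] + 1)) {   # 1-based template indices
      if (p >= 1 && p <= La && !(p %in% div_pos)) {
        div_pos <- c(div_pos, p)
        carrier <- c(carrier, "proximal")
        forced <- c(forced, TRUE)
      }
    }
  }
  ord <- order(div_pos)
  div_pos <- div_pos[ord]; carrier <- carrier[ord]; forced <- forced[ord]

  distal_b <- tmpl
  proximal_b <- tmpl
  for (i in seq_along(div_pos)) {
    if (carrier[i] == "distal") {
      distal_b <- mutate_base(distal_b, div_pos[i])
    } else {
      proximal_b <- mutate_base(proximal_b, div_pos[i])
    }
  }

  distal <- apply_copy_edits(distal_b, sig[sig$copy == "distal", , drop = FALSE])
  proximal <- apply_copy_edits(proximal_b, sig[sig$copy == "proximal", , drop = FALSE])
  stopifnot(length(distal$seq) == sc$dup_length)

  jn <- build_junction(sc)

  len_d <- length(distal$seq)
  len_p <- length(proximal$seq)
  len_j <- length(jn$seq)
  right_len <- sc$region_length - (sc$dup_start + len_d + len_j + len_p)
  left_flank <- random_bases(sc$dup_start)
  right_flank <- random_bases(right_len)
  # force copy-boundary mismatches so the recorded copy extents are maximal
  if (sc$dup_start >= 1) {
    prev_of_proximal <- if (len_j > 0) jn$seq[len_j] else distal$seq[len_d]
    if (left_flank[sc$dup_start] == prev_of_proximal) {
      left_flank <- mutate_base(left_flank, sc$dup_start)
    }
  }
  if (right_len >= 1) {
    next_of_distal <- if (len_j > 0) jn$seq[1] else proximal$seq[1]
    if (right_flank[1] == next_of_distal) {
      right_flank <- mutate_base(right_flank, 1L)
    }
  }

  seq <- paste(c(left_flank, distal$seq, jn$seq, proximal$seq, right_flank),
               collapse = "")

  # absolute offsets (0-based)
  d0 <- sc$dup_start
  j0 <- d0 + len_d
  p0 <- j0 + len_j
  truth <- build_truth(sc, tmpl, sig, distal, proximal, jn,
                       div_pos, carrier, forced, length(eligible),
                       d0, j0, p0, len_d, len_j, len_p)

  structure(
    list(sequence = seq,
         te_consensus = jn$te_consensus,
         rist_consensus = jn$rist_consensus,
         scenario = sc,
         seed = as.integer(seed),
         truth = truth),
    class = "dup_fixture")
}

# Deterministic template engineering so every planted event carries exactly
# the evidence its classification requires (positions are 0-based in `sig`,
# 1-based on the character vector `tmpl`).
engineer_template <- function(tmpl, sig) {
  force_diff <- function(tmpl, i, j) { # make tmpl[i] != tmpl[j] by editing i
    if (i >= 1 && j >= 1 && i <= length(tmpl) && j <= length(tmpl) &&
        tmpl[i] == tmpl[j]) {
      tmpl[i] <- sample(setdiff(DNA_BASES, tmpl[j]), 1L)
    }
    tmpl
  }
  for (i in seq_len(nrow(sig))) {
    s <- sig$pos[i]; g <- sig$size[i]
    switch(sig$kind[i],
      microhomology_jump = {
        mh <- sig$mh_len[i]
        # deleted segment's prefix repeats in the retained right flank
        tmpl[(s + g + 1):(s + g + mh)] <- tmpl[(s + 1):(s + mh)]
        tmpl <- force_diff(tmpl, s + g + mh + 1, s + mh + 1)  # cap homology at mh
        tmpl <- force_diff(tmpl, s, s + g)                    # no left-side homology
      },
      tandem_repeat = {
        # unit = tmpl[s-g .. s); block right extension of the tandem
        tmpl <- force_diff(tmpl, s + 1, s - g + 1)
      },
      deletion = {
        # neutral deletion: no flanking homology on either side
        tmpl <- force_diff(tmpl, s + g + 1, s + 1)
        tmpl <- force_diff(tmpl, s, s + g)
      })
  }
  tmpl
}

# Apply planted indels of one copy to its substituted base vector, returning
# the copy sequence plus the template->copy coordinate map (1-based; NA for
# deleted template positions).
apply_copy_edits <- function(bases, sig) {
  La <- length(bases)
  src <- seq_len(La)
  if (nrow(sig) > 0) {
    sig <- sig[order(sig$pos, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      s <- sig$pos[i]; g <- sig$size[i]
      if (sig$kind[i] == "tandem_repeat") {
        unit_idx <- (s - g + 1):s
        src <- append(src, -unit_idx, after = s)
      } else {
        src <- src[-((s + 1):(s + g))]
      }
    }
  }
  list(seq = bases[abs(src)], map = match(seq_len(La), src))
}

# Map a 0-based template position to a 0-based copy position, stepping
# forward over deleted sites.
map0 <- function(map, pos0) {
  i <- pos0 + 1L
  while (i <= length(map) && is.na(map[i])) i <- i + 1L
  if (i > length(map)) length(map) else map[i] - 1L
}

# Junction assembly: leading rIST + n_modules x (TE + rIST + rIST).
build_junction <- function(sc) {
  if (sc$n_modules == 0L) {
    return(list(seq = character(0), te_consensus = NA_character_,
                rist_consensus = NA_character_, modules = NULL, rists = NULL))
  }
  rist_cons <- draw_rist_consensus(sc)
  te_cons <- draw_te_consensus(sc)
  n_rist <- 1L + 2L * sc$n_modules
  rists <- replicate(n_rist, mutate_copy(
    rist_cons, sc$rist_divergence,
    mask = c(seq_len(sc$tsd_length + 1L),
             (sc$rist_length - sc$tsd_length):sc$rist_length),
    forbid = sc$te_site), simplify = FALSE)
  tes <- replicate(sc$n_modules, mutate_copy(
    te_cons, sc$te_divergence,
    mask = c(seq_len(nchar(sc$tir_seq)),
             (sc$te_site_offset + 1L):(sc$te_site_offset + nchar(sc$te_site)),
             (sc$te_length - nchar(sc$tir_seq) + 1L):sc$te_length),
    forbid = sc$te_site), simplify = FALSE)
  orientation <- rep("forward", sc$n_modules)
  if (!is.null(sc$reversed_module_index)) {
    k <- sc$reversed_module_index + 1L
    tes[[k]] <- strsplit(revcomp(paste(tes[[k]], collapse = "")), "")[[1L]]
    orientation[k] <- "reversed"
  }
  pieces <- list(rists[[1L]])
  for (k in seq_len(sc$n_modules)) {
    pieces <- c(pieces, list(tes[[k]], rists[[2L * k]], rists[[2L * k + 1L]]))
  }
  list(seq = unlist(pieces),
       te_consensus = paste(te_cons, collapse = ""),
       rist_consensus = paste(rist_cons, collapse = ""),
       orientation = orientation,
       tsd = paste(rist_cons[seq_len(sc$tsd_length)], collapse = ""))
}

# rIST consensus: ends share the tsd_length prefix (the TSD that flanks each
# TE insertion), the shared repeat must not extend past tsd_length, and the
# planted restriction site must be absent (also across a tandem boundary).
draw_rist_consensus <- function(sc) {
  rl <- sc$rist_length; tl <- sc$tsd_length
  site <- sc$te_site
  repeat {
    r <- random_bases(rl)
    if (tl > 0) r[(rl - tl + 1L):rl] <- r[seq_len(tl)]
    rs <- paste(r, collapse = "")
    ok <- TRUE
    if (tl > 0) {
      for (L in (tl + 1L):min(rl %/% 2L, tl + 6L)) {
        if (substring(rs, 1L, L) == substring(rs, rl - L + 1L, rl)) ok <- FALSE
      }
    }
    if (ok && nzchar(site)) {
      tandem <- paste0(rs, rs)
      if (length(find_all(tandem, site)) > 0 ||
          length(find_all(tandem, revcomp(site))) > 0) ok <- FALSE
    }
    if (ok) return(r)
  }
}

# TE consensus: TIR ... core (with one planted restriction site) ... rc(TIR);
# any other occurrence of the site (either strand) is scrubbed from the core.
draw_te_consensus <- function(sc) {
  tir <- strsplit(sc$tir_seq, "")[[1L]]
  nt <- length(tir)
  te <- random_bases(sc$te_length)
  te[seq_len(nt)] <- tir
  te[(sc$te_length - nt + 1L):sc$te_length] <- strsplit(revcomp(sc$tir_seq), "")[[1L]]
  site <- sc$te_site
  ns <- nchar(site)
  planted <- (sc$te_site_offset + 1L):(sc$te_site_offset + ns)
  te[planted] <- strsplit(site, "")[[1L]]
  repeat {
    s <- paste(te, collapse = "")
    occ <- sort(unique(c(find_all(s, site), find_all(s, revcomp(site)))))
    occ <- occ[occ != sc$te_site_offset]
    if (length(occ) == 0) break
    # mutate one base of the stray occurrence, outside TIRs and planted site
    cand <- setdiff((occ[1L] + 1L):(occ[1L] + ns),
                    c(seq_len(nt), planted, (sc$te_length - nt + 1L):sc$te_length))
    te <- mutate_base(te, cand[1L])
  }
  te
}

# Substitute bases at rate `rate`, skipping 1-based `mask` positions; redraw
# if a substitution creates an occurrence of `forbid` (either strand).
mutate_copy <- function(cons, rate, mask, forbid = "") {
  n <- length(cons)
  ok_pos <- setdiff(seq_len(n), mask)
  repeat {
    x <- cons
    hit <- ok_pos[stats::runif(length(ok_pos)) < rate]
    for (p in hit) x <- mutate_base(x, p)
    if (!nzchar(forbid)) return(x)
    s <- paste(x, collapse = "")
    n_now <- length(find_all(s, forbid)) + length(find_all(s, revcomp(forbid)))
    s0 <- paste(cons, collapse = "")
    n_ref <- length(find_all(s0, forbid)) + length(find_all(s0, revcomp(forbid)))
    if (n_now <= n_ref) return(x)
  }
}

build_truth <- function(sc, tmpl, sig, distal, proximal, jn,
                        div_pos, carrier, forced, n_eligible,
                        d0, j0, p0, len_d, len_j, len_p) {
  tmpl_s <- paste(tmpl, collapse = "")
  md <- distal$map; mp <- proximal$map
  tr <- sc$identical_tract

  tract <- if (tr[2] > 0) {
    list(distal = c(d0 + map0(md, tr[1]), d0 + map0(md, tr[1]) + tr[2]),
         proximal = c(p0 + map0(mp, tr[1]), p0 + map0(mp, tr[1]) + tr[2]),
         length = tr[2])
  } else {
    list(distal = c(NA_real_, NA_real_), proximal = c(NA_real_, NA_real_),
         length = 0)
  }

  signatures <- NULL
  if (nrow(sig) > 0) {
    rows <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
      s <- sig$pos[i]; g <- sig$size[i]; cp <- sig$copy[i]; kind <- sig$kind[i]
      cmap <- if (cp == "distal") md else mp
      omap <- if (cp == "distal") mp else md
      coff <- if (cp == "distal") d0 else p0
      ooff <- if (cp == "distal") p0 else d0
      if (kind == "tandem_repeat") {
        gap_copy <- setdiff(c("distal", "proximal"), cp)
        carrier_pos <- coff + map0(cmap, s) - g   # start of inserted unit
        other_pos <- ooff + map0(omap, s)
        evidence <- subseq0(tmpl_s, s - g, s)
      } else {
        gap_copy <- cp
        carrier_pos <- coff + map0(cmap, s)       # gap locus in carrier
        other_pos <- ooff + map0(omap, s)         # segment start in other copy
        evidence <- if (kind == "microhomology_jump") {
          subseq0(tmpl_s, s, s + sig$mh_len[i])
        } else NA_character_
      }
      tibble(kind = kind, copy = cp, gap_copy = gap_copy,
             template_pos = s, size = g, mh_len = sig$mh_len[i],
             evidence = evidence,
             segment = subseq0(tmpl_s, if (kind == "tandem_repeat") s - g else s,
                               if (kind == "tandem_repeat") s else s + g),
             carrier_pos = carrier_pos, other_pos = other_pos,
             distal_pos = if (cp == "distal") carrier_pos else other_pos,
             proximal_pos = if (cp == "proximal") carrier_pos else other_pos)
    })
    signatures <- rows
  } else {
    signatures <- tibble(kind = character(), copy = character(),
                         gap_copy = character(), template_pos = numeric(),
                         size = numeric(), mh_len = numeric(),
                         evidence = character(), segment = character(),
                         carrier_pos = numeric(), other_pos = numeric(),
                         distal_pos = numeric(), proximal_pos = numeric())
  }

  genes <- if (nrow(sc$planted_genes) > 0) {
    purrr::map_dfr(seq_len(nrow(sc$planted_genes)), function(i) {
      g <- sc$planted_genes[i, ]
      tibble(name = rep(g$name, 2), copy = c("distal", "proximal"),
             start = c(d0 + map0(md, g$start), p0 + map0(mp, g$start)),
             end = c(d0 + map0(md, g$end - 1) + 1, p0 + map0(mp, g$end - 1) + 1),
             strand = rep(g$strand, 2))
    })
  } else {
    tibble(name = character(), copy = character(), start = numeric(),
           end = numeric(), strand = character())
  }

  divergence <- tibble(
    template_pos = div_pos - 1,
    carrier = carrier,
    forced = forced,
    distal_pos = purrr::map_dbl(div_pos, ~ d0 + map0(md, .x - 1)),
    proximal_pos = purrr::map_dbl(div_pos, ~ p0 + map0(mp, .x - 1)))

  modules <- tibble(module = integer(), start = numeric(), end = numeric(),
                    te_start = numeric(), te_end = numeric(),
                    orientation = character(), tsd = character())
  rists <- tibble(module = integer(), start = numeric(), end = numeric())
  if (sc$n_modules > 0) {
    rl <- sc$rist_length; tel <- sc$te_length
    rists <- tibble(module = -1L, start = j0, end = j0 + rl)
    mods <- list()
    for (k in seq_len(sc$n_modules) - 1L) {
      ms <- j0 + rl + k * (tel + 2 * rl)
      mods[[k + 1L]] <- tibble(
        module = k, start = ms, end = ms + tel + 2 * rl,
        te_start = ms, te_end = ms + tel,
        orientation = jn$orientation[k + 1L], tsd = jn$tsd)
      rists <- dplyr::bind_rows(
        rists,
        tibble(module = k, start = ms + tel, end = ms + tel + rl),
        tibble(module = k, start = ms + tel + rl, end = ms + tel + 2 * rl))
    }
    modules <- dplyr::bind_rows(mods)
  }

  list(
    region_length = sc$region_length,
    distal = c(d0, d0 + len_d),
    proximal = c(p0, p0 + len_p),
    junction = c(j0, j0 + len_j),
    copy_length_distal = len_d,
    copy_length_proximal = len_p,
    identical_tract = tract,
    modules = modules,
    rists = rists,
    signatures = signatures,
    genes = genes,
    divergence = divergence,
    n_eligible = n_eligible,
    background_divergence = sc$background_divergence)
}

#' @export
print.dup_fixture <- function(x, ...) {
  t <- x$truth
  cat(sprintf(
    paste0("Synthetic duplication fixture (%s bp, seed %d)\n",
           "  distal copy [%s, %s); junction [%s, %s); proximal copy [%s, %s)\n",
           "  identical tract %s bp; %d planted signature(s); %d module(s)\n"),
    format(nchar(x$sequence), big.mark = ","), x$seed,
    format(t$distal[1], big.mark = ","), format(t$distal[2], big.mark = ","),
    format(t$junction[1], big.mark = ","), format(t$junction[2], big.mark = ","),
    format(t$proximal[1], big.mark = ","), format(t$proximal[2], big.mark = ","),
    format(t$identical_tract$length, big.mark = ","),
    nrow(t$signatures), nrow(t$modules)))
  invisible(x)
}

#' Simulate a qPCR Ct replicate table with a known true copy ratio
#'
#' Generates target and reference Ct values for a sample and a calibrator such
#' that, at 100% amplification efficiency (base 2), the expected
#' delta-delta-Ct ratio of the sample relative to the calibrator equals
#' `true_ratio`. Gaussian cycle noise of standard deviation `ct_noise_sd` is
#' added independently to every well.
#'
#' @param true_ratio True copy-number ratio (> 0).
#' @param n_replicates Replicates per (sample, gene) pair (>= 2).
#' @param ct_noise_sd Cycle noise standard deviation (cycles).
#' @param seed Integer RNG seed.
#' @param target_gene,reference_genes Gene labels used in the table.
#' @param sample,calibrator Sample labels.
#' @return A tibble with columns `sample`, `gene`, `replicate`, `ct`.
#' @examples
#' generate_ct_table(2.76, n_replicates = 3, ct_noise_sd = 0, seed = 1)
#' @export
generate_ct_table <- function(true_ratio, n_replicates = 6L, ct_noise_sd = 0.2,
                              seed = 1L,
                              target_gene = "Hosim1",
                              reference_genes = c("GAPDH", "RPL17"),
                              sample = "XSR6", calibrator = "XST8") {
  stopif_not_scalar_number(true_ratio, "true_ratio", min = .Machine$double.xmin)
  if (!is.numeric(n_replicates) || n_replicates < 2) {
    abort("`n_replicates` must be >= 2")
  }
  stopif_not_scalar_number(ct_noise_sd, "ct_noise_sd", min = 0)
  withr::local_seed(as.integer(seed))
  base_ct <- c(stats::setNames(rep(20, length(reference_genes)), reference_genes),
               stats::setNames(24, target_gene))
  grid <- tidyr::expand_grid(
    sample = c(sample, calibrator),
    gene = c(target_gene, reference_genes),
    replicate = seq_len(n_replicates))
  grid$ct <- unname(base_ct[grid$gene]) -
    ifelse(grid$sample == sample & grid$gene == target_gene,
           log2(true_ratio), 0) +
    stats::rnorm(nrow(grid), 0, ct_noise_sd)
  grid
}
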