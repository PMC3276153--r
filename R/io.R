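#' Write a synthetic fixture to disk
#'
#' Emits `region.fasta` (80-column FASTA of the region), `consensus.fasta`
#' (TE and rIST consensus sequences, when the scenario has a junction),
#' `features.gff3` (copies, junction, genes, junction modules and planted
#' signatures; 1-based inclusive coordinates per the GFF3 convention),
#' `truth.json` and `scenario.json`. Re-reading with [read_fixture()]
#' reproduces the in-memory truth coordinates exactly.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!inherits(fixture, "dup_fixture")) abort("`fixture` must be a dup_fixture")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))

  dna <- Biostrings::DNAStringSet(c(region = fixture$sequence))
  Biostrings::writeXStringSet(dna, file.path(dir, "region.fasta"), width = 80L)
  if (!is.na(fixture$te_consensus)) {
    cons <- Biostrings::DNAStringSet(c(te_consensus = fixture$te_consensus,
                                       rist_consensus = fixture$rist_consensus))
    Biostrings::writeXStringSet(cons, file.path(dir, "consensus.fasta"),
                                width = 80L)
  }
  rtracklayer::export(fixture_granges(fixture), file.path(dir, "features.gff3"),
                      format = "gff3")
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  sc <- fixture$scenario
  sc_list <- unclass(sc)
  jsonlite::write_json(sc_list, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

# Ground truth as a GRanges for GFF3 export (0-based half-open -> 1-based
# inclusive).
fixture_granges <- function(fixture) {
  t <- fixture$truth
  rows <- list(
    tibble(type = "duplication", ID = c("copy_distal", "copy_proximal"),
           start = c(t$distal[1], t$proximal[1]),
           end = c(t$distal[2], t$proximal[2]), strand = "+"),
    if (t$junction[2] > t$junction[1]) {
      tibble(type = "junction", ID = "junction",
             start = t$junction[1], end = t$junction[2], strand = "+")
    },
    if (nrow(t$genes) > 0) {
      tibble(type = "gene", ID = paste(t$genes$name, t$genes$copy, sep = "_"),
             start = t$genes$start, end = t$genes$end, strand = t$genes$strand)
    },
    if (nrow(t$modules) > 0) {
      tibble(type = "transposable_element",
             ID = paste0("te_", t$modules$module),
             start = t$modules$te_start, end = t$modules$te_end,
             strand = ifelse(t$modules$orientation == "forward", "+", "-"))
    },
    if (nrow(t$rists) > 0) {
      tibble(type = "repeat_region",
             ID = paste0("rist_", seq_len(nrow(t$rists)) - 1L),
             start = t$rists$start, end = t$rists$end, strand = "+")
    },
    if (nrow(t$signatures) > 0) {
      tibble(type = "sequence_alteration",
             ID = paste0("signature_", seq_len(nrow(t$signatures)) - 1L,
                         "_", t$signatures$kind),
             start = t$signatures$carrier_pos,
             end = pmax(t$signatures$carrier_pos + t$signatures$size,
                        t$signatures$carrier_pos + 1),
             strand = "+")
    })
  d <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = "region",
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
    strand = d$strand)
  S4Vectors::mcols(gr)$type <- d$type
  S4Vectors::mcols(gr)$ID <- d$ID
  gr
}

#' Read a fixture back from disk
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with `sequence`, `te_consensus`, `rist_consensus`,
#'   `scenario` (a rebuilt `dup_scenario`), and `truth` with the same
#'   structure (tibbles included) as the in-memory fixture.
#' @export
read_fixture <- function(dir) {
  fa <- Biostrings::readDNAStringSet(file.path(dir, "region.fasta"))
  sequence <- as.character(fa[[1L]])
  te_cons <- NA_character_; rist_cons <- NA_character_
  cons_path <- file.path(dir, "consensus.fasta")
  if (file.exists(cons_path)) {
    cons <- Biostrings::readDNAStringSet(cons_path)
    te_cons <- as.character(cons[["te_consensus"]])
    rist_cons <- as.character(cons[["rist_consensus"]])
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  for (f in c("modules", "rists", "signatures", "genes", "divergence")) {
    truth[[f]] <- as_tibble(truth[[f]])
  }
  sc_raw <- jsonlite::read_json(file.path(dir, "scenario.json"),
                                simplifyVector = TRUE)
  sc_raw$planted_signatures <- as_tibble(sc_raw$planted_signatures)
  sc_raw$planted_genes <- as_tibble(sc_raw$planted_genes)
  scenario <- do.call(dup_scenario, sc_raw)
  list(sequence = sequence, te_consensus = te_cons, rist_consensus = rist_cons,
       scenario = scenario, truth = truth)
}
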