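rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("the consensus scanner finds itself and nothing in noise", {
  set.seed(6)
  cons <- rand_dna(400)
  self <- scan_te_copies(cons, cons)
  expect_identical(nrow(self), 1L)
  expect_equal(c(self$start, self$end), c(0, 400))
  expect_identical(self$strand, "+")
  expect_equal(self$identity, 100)
  expect_identical(nrow(scan_te_copies(rand_dna(2000), cons)), 0L)
  expect_error(scan_te_copies("ACGT", ""), "non-empty")
})

test_that("the scanner reports orientation and tolerates divergence", {
  set.seed(7)
  cons <- rand_dna(300)
  ch <- strsplit(cons, "")[[1]]
  mut <- sample(300, 6)
  ch[mut] <- sample(c("A", "C", "G", "T"), 6, TRUE)
  diverged <- paste(ch, collapse = "")
  seq <- paste0(rand_dna(150), diverged, rand_dna(100), rc(cons), rand_dna(150))
  hits <- scan_te_copies(seq, cons)
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$strand, c("+", "-"))
  expect_equal(hits$start, c(150, 550))
  expect_gte(hits$identity[1], 98 - 1)
  expect_equal(hits$identity[2], 100)
})

test_that("TIR and TSD annotation recovers planted structure exactly", {
  set.seed(10)
  tir <- "TAGTGTTGGGT"
  core <- rand_dna(150)
  te <- paste0(tir, core, rc(tir))
  tsd <- "TTACCGGA"
  seq <- paste0(rand_dna(60), tsd, te, tsd, rand_dna(60))
  hits <- tibble::tibble(start = 68, end = 68 + nchar(te))
  ann <- detect_tir_tsd(hits, seq, tir = tir)
  expect_true(ann$tir_left && ann$tir_right)
  expect_identical(ann$tsd, tsd)
  expect_identical(ann$tsd_len, 8L)

  # mutated right TIR
  te_bad <- paste0(tir, core, "AAAAAAAAAAA")
  seq2 <- paste0(rand_dna(60), tsd, te_bad, tsd, rand_dna(60))
  ann2 <- detect_tir_tsd(tibble::tibble(start = 68, end = 68 + nchar(te_bad)),
                         seq2, tir = tir)
  expect_true(ann2$tir_left)
  expect_false(ann2$tir_right)

  # flanks without a shared >= 4-mer give no TSD
  seq3 <- paste0(strrep("A", 20), te, strrep("C", 20))
  ann3 <- detect_tir_tsd(tibble::tibble(start = 20, end = 20 + nchar(te)),
                         seq3, tir = tir)
  expect_true(is.na(ann3$tsd))
})

test_that("junction decomposition recovers the planted module layout", {
  fx <- generate_fixture(toy_scenario(), seed = 33)
  t <- fx$truth
  jseq <- substring(fx$sequence, t$junction[1] + 1, t$junction[2])
  mods <- decompose_junction(jseq, fx$te_consensus, fx$rist_consensus)
  expect_gte(attr(mods, "coverage"), 0.95)
  te_mods <- mods[!is.na(mods$te_start), ]
  expect_identical(nrow(te_mods), 2L)
  expect_identical(te_mods$orientation, c("reversed", "forward"))
  expect_equal(te_mods$te_start + t$junction[1], t$modules$te_start)
  expect_equal(te_mods$te_end + t$junction[1], t$modules$te_end)
  expect_identical(te_mods$n_rist, c(2L, 2L))
  # the leading TE-less element plus modules tile the junction exactly
  expect_equal(mods$start, c(0, t$modules$te_start - t$junction[1]))
  expect_equal(mods$end[nrow(mods)], t$junction[2] - t$junction[1])
  expect_true(all(mods$start[-1] == mods$end[-nrow(mods)]))
})

test_that("a junction of repeats only decomposes to a TE-less module", {
  set.seed(11)
  rist <- rand_dna(120)
  jseq <- strrep(rist, 4)
  mods <- decompose_junction(jseq, rand_dna(300), rist)
  expect_identical(nrow(mods), 1L)
  expect_true(is.na(mods$te_start))
  expect_identical(mods$n_rist, 4L)
  empty <- decompose_junction("", rand_dna(300), rist)
  expect_identical(nrow(empty), 0L)
})

test_that("Southern fragment arithmetic converts sizes to module counts", {
  counts <- southern_module_count(c(26, 36), flank_kb_total = 11.7,
                                  module_kb = 3.6)
  expect_equal(c(counts$low, counts$high), c(4.0, 6.8))
  one <- southern_module_count(c(3.6, 3.6), flank_kb_total = 0)
  expect_equal(c(one$low, one$high), c(1, 1))
  expect_error(southern_module_count(c(10, 20), 15), "junction")
  expect_error(southern_module_count(c(30, 20), 1), "low <= high")
})

test_that("in silico digestion cuts at site starts and conserves length", {
  expect_identical(insilico_digest("ACGTACGTAA", "GGATCC"), 10L)
  expect_identical(insilico_digest("AAGGATCCAA", "GGATCC"), c(2L, 8L))
  set.seed(14)
  for (i in 1:10) {
    s <- rand_dna(500)
    frags <- insilico_digest(s, "GGATCC")
    expect_identical(sum(frags), 500L)
  }
  # non-palindromic site: occurrences on both strands cut
  s <- paste0(strrep("A", 10), "TTCAGG", strrep("A", 4), "CCTGAA", strrep("A", 10))
  expect_identical(insilico_digest(s, "TTCAGG"), c(10L, 10L, 16L))
})

test_that("the fixture junction releases one ~module-sized fragment per interior module", {
  sc <- toy_scenario()
  fx <- generate_fixture(sc, seed = 44)
  t <- fx$truth
  jseq <- substring(fx$sequence, t$junction[1] + 1, t$junction[2])
  frags <- insilico_digest(jseq, sc$te_site)
  module_len <- sc$te_length + 2 * sc$rist_length
  # consecutive same-orientation sites are exactly one module apart
  expect_identical(sum(frags), nchar(jseq))
  expect_identical(length(frags), nrow(t$modules) + 1L)
})

test_that("in silico PCR reproduces the published band sizes by construction", {
  set.seed(16)
  fwd <- rand_dna(20)
  rev <- rand_dna(20)
  insert <- rand_dna(784 - 40)
  canonical <- paste0(rand_dna(30), fwd, insert, rc(rev), rand_dna(30))
  # the variant allele lacks 85 bp of the amplified interior
  sr <- paste0(rand_dna(30), fwd, substring(insert, 86), rc(rev), rand_dna(30))
  expect_identical(insilico_pcr(canonical, fwd, rev), 784L)
  expect_identical(insilico_pcr(sr, fwd, rev), 699L)
  expect_identical(insilico_pcr(canonical, fwd, "TTTTTTTTTTTTTTTT"), integer(0))
  # primers at the template ends amplify the whole template
  expect_identical(insilico_pcr(paste0(fwd, rand_dna(50), rc(rev)), fwd, rev),
                   as.integer(40 + 50))
  expect_error(insilico_pcr("ACGT", "SHORT", "SHORT"), "15")
})
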