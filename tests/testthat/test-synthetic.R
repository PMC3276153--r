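test_that("the canonical scenario carries the published region parameters", {
  sc <- build_scenario(list())
  expect_identical(sc$dup_length, 37500L)
  expect_equal(sc$identical_tract[2], 10344)
  expect_equal(sc$background_divergence, 0.0125)
  expect_identical(sc$n_modules, 6L)
  expect_identical(sc$rist_length, 687L)
  expect_identical(sc$tsd_length, 8L)
  expect_identical(sc$tir_seq, "TAGTGTTGGGT")
  expect_identical(sc$te_length + 2L * sc$rist_length, 3600L)
  sig <- sc$planted_signatures
  expect_identical(sum(sig$kind == "microhomology_jump" & sig$copy == "proximal"), 3L)
  expect_identical(sum(sig$kind == "tandem_repeat" & sig$copy == "proximal"), 1L)
  expect_identical(sum(sig$kind == "tandem_repeat" & sig$copy == "distal"), 1L)
  expect_identical(sig$size[sig$kind == "deletion"], 65)
  expect_identical(nrow(sc$planted_genes), 6L)
})

test_that("scenario validation names the offending field", {
  expect_s3_class(build_scenario(list(dup_length = 500,
                                      identical_tract = c(0, 500),
                                      background_divergence = 0)),
                  "dup_scenario")
  expect_error(dup_scenario(dup_length = 500, identical_tract = c(100, 500)),
               "identical_tract")
  expect_error(dup_scenario(background_divergence = 1), "background_divergence")
  expect_error(dup_scenario(tir_seq = ""), "tir_seq")
  expect_error(dup_scenario(region_length = 1000), "region_length")
  expect_error(build_scenario(list(bogus = 1)), "bogus")
})

test_that("fixtures are byte-identical under a fixed (scenario, seed)", {
  sc <- toy_scenario()
  f1 <- generate_fixture(sc, seed = 9)
  f2 <- generate_fixture(sc, seed = 9)
  expect_identical(f1$sequence, f2$sequence)
  expect_identical(f1$truth, f2$truth)
  f3 <- generate_fixture(sc, seed = 10)
  expect_false(identical(f1$sequence, f3$sequence))
})

test_that("an unmutated scenario yields character-identical copies", {
  sc <- dup_scenario(dup_length = 600, dup_start = 100, n_modules = 0,
                     identical_tract = c(0, 0), background_divergence = 0)
  fx <- generate_fixture(sc, seed = 3)
  t <- fx$truth
  expect_identical(t$junction[1], t$junction[2])
  a <- substring(fx$sequence, t$distal[1] + 1, t$distal[2])
  b <- substring(fx$sequence, t$proximal[1] + 1, t$proximal[2])
  expect_identical(a, b)
})

test_that("ground-truth coordinates slice out the elements they claim", {
  fx <- generate_fixture(toy_scenario(), seed = 21)
  seq <- fx$sequence
  sc <- fx$scenario
  slice <- function(iv) substring(seq, iv[1] + 1, iv[2])
  # TIRs at both TE ends (orientation-independent), TSD on both flanks
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (i in seq_len(nrow(fx$truth$modules))) {
    m <- fx$truth$modules[i, ]
    expect_identical(slice(c(m$te_start, m$te_start + nchar(sc$tir_seq))),
                     sc$tir_seq)
    expect_identical(slice(c(m$te_end - nchar(sc$tir_seq), m$te_end)),
                     rc(sc$tir_seq))
    expect_identical(slice(c(m$te_start - sc$tsd_length, m$te_start)),
                     slice(c(m$te_end, m$te_end + sc$tsd_length)))
    expect_identical(slice(c(m$te_start - sc$tsd_length, m$te_start)), m$tsd)
  }
  # rIST tandem copies exceed 99% pairwise identity
  rist <- fx$truth$rists
  seqs <- vapply(seq_len(nrow(rist)),
                 function(i) slice(c(rist$start[i], rist$end[i])), "")
  for (i in 2:length(seqs)) {
    d <- sum(strsplit(seqs[1], "")[[1]] != strsplit(seqs[i], "")[[1]])
    expect_gt(100 * (1 - d / nchar(seqs[1])), 99)
  }
  # planted signature evidence occurs where each kind requires it
  sig <- fx$truth$signatures
  mh <- sig[sig$kind == "microhomology_jump", ]
  for (i in seq_len(nrow(mh))) {
    seg_start <- mh$other_pos[i]
    seg <- slice(c(seg_start, seg_start + mh$size[i]))
    expect_identical(seg, mh$segment[i])
    # microhomology: deleted segment prefix repeats in the retained flank
    expect_identical(substring(seg, 1, mh$mh_len[i]),
                     slice(c(seg_start + mh$size[i],
                             seg_start + mh$size[i] + mh$mh_len[i])))
  }
  tr <- sig[sig$kind == "tandem_repeat", ]
  for (i in seq_len(nrow(tr))) {
    u <- tr$size[i]
    unit <- slice(c(tr$carrier_pos[i], tr$carrier_pos[i] + u))
    expect_identical(unit, slice(c(tr$carrier_pos[i] - u, tr$carrier_pos[i])))
    expect_identical(unit, tr$segment[i])
  }
  # identical tract slices are equal between the copies
  it <- fx$truth$identical_tract
  expect_identical(slice(it$distal), slice(it$proximal))
})

test_that("realized divergence stays within 3 binomial SDs of the target", {
  sc <- toy_scenario()
  fx <- generate_fixture(sc, seed = 31)
  p <- sc$background_divergence
  n <- fx$truth$n_eligible
  realized <- sum(!fx$truth$divergence$forced) / n
  expect_lt(abs(realized - p), 3 * sqrt(p * (1 - p) / n))
  # and every recorded divergent site really differs between the copies
  seq <- fx$sequence
  d <- fx$truth$divergence
  da <- substring(seq, d$distal_pos + 1, d$distal_pos + 1)
  db <- substring(seq, d$proximal_pos + 1, d$proximal_pos + 1)
  expect_true(all(da != db))
})

test_that("Ct tables hit the requested ratio exactly when noiseless", {
  ct <- generate_ct_table(1, n_replicates = 3, ct_noise_sd = 0, seed = 1)
  w <- tidyr::pivot_wider(ct, names_from = "gene", values_from = "ct")
  dct <- w$Hosim1 - (w$GAPDH + w$RPL17) / 2
  expect_equal(dct[w$sample == "XSR6"], dct[w$sample == "XST8"])
  ct2 <- generate_ct_table(2.76, n_replicates = 3, ct_noise_sd = 0, seed = 1)
  dd <- ddct_ratio(ct2, "Hosim1", c("GAPDH", "RPL17"), "XSR6", "XST8")
  expect_equal(unique(dd$ddct), -log2(2.76))
  expect_error(generate_ct_table(0), "true_ratio")
  expect_error(generate_ct_table(2, n_replicates = 1), "n_replicates")
})

test_that("fixtures round-trip through FASTA/GFF3/JSON on disk", {
  fx <- generate_fixture(toy_scenario(), seed = 5)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  expect_setequal(list.files(dir),
                  c("region.fasta", "consensus.fasta", "features.gff3",
                    "truth.json", "scenario.json"))
  fa <- readLines(file.path(dir, "region.fasta"))
  body <- fa[!startsWith(fa, ">")]
  expect_true(all(nchar(body[-length(body)]) == 80))
  expect_identical(sum(nchar(body)), nchar(fx$sequence))

  rt <- read_fixture(dir)
  expect_identical(rt$sequence, fx$sequence)
  expect_identical(rt$te_consensus, fx$te_consensus)
  expect_equal(rt$truth$distal, fx$truth$distal)
  expect_equal(rt$truth$proximal, fx$truth$proximal)
  expect_equal(as.data.frame(rt$truth$modules), as.data.frame(fx$truth$modules))
  expect_equal(as.data.frame(rt$truth$signatures),
               as.data.frame(fx$truth$signatures))
  expect_equal(as.data.frame(rt$truth$genes), as.data.frame(fx$truth$genes))
  expect_identical(rt$scenario$dup_length, fx$scenario$dup_length)

  # GFF3 is 1-based inclusive: the distal copy record starts at truth+1
  gff <- rtracklayer::import(file.path(dir, "features.gff3"))
  distal <- gff[gff$ID == "copy_distal"]
  expect_identical(BiocGenerics::start(distal), as.integer(fx$truth$distal[1] + 1))
  expect_identical(BiocGenerics::end(distal), as.integer(fx$truth$distal[2]))
})
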