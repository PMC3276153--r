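mk_aln2 <- function(ga, gb) {
  dupchar:::new_pairwise_alignment(
    ga, gb, gsub("-", "", ga), gsub("-", "", gb),
    c(match = 1, mismatch = -1, gap_open = -5, gap_extend = -1))
}

test_that("indel extraction reports one feature per maximal gap run", {
  set.seed(4)
  s <- rand_dna(80)
  expect_identical(nrow(extract_indels(align_copies(s, s))), 0L)

  aln <- mk_aln2("ACGTACGTACGTACGT", "ACGTAC------ACGT")
  ind <- extract_indels(aln, context = 4)
  expect_identical(nrow(ind), 1L)
  expect_identical(ind$gap_copy, "b")
  expect_identical(ind$length, 6L)
  expect_identical(ind$segment, "GTACGT")
  expect_identical(ind$left_ctx, "GTAC")

  # adjacent gaps in different copies stay distinct
  two <- mk_aln2("AACCGG--TTAACC", "AACC--GGTTAACC")
  expect_identical(nrow(extract_indels(two)), 2L)
})

test_that("microhomology-delimited deletions are classified with their evidence", {
  # template jump: deleted segment TAGGCTAG starts with TAG, and TAG is the
  # retained right flank -> microhomology "TAG", gap carrier votes
  left <- "GGCACCATGGACGT"
  del <- "TAGGCTAG"
  right <- "TAGCATTACGGAGG"
  a <- paste0(left, del, right)
  b <- paste0(left, right)
  aln <- align_copies(a, b)
  cls <- classify_indels(extract_indels(aln))
  expect_identical(nrow(cls), 1L)
  expect_identical(cls$kind, "microhomology_jump")
  expect_identical(cls$evidence, "TAG")
  # gap is in copy b -> copy b (proximal by default roles) is the vote
  expect_identical(cls$neosynthesized_vote, "proximal")
  expect_false(cls$slippage_caveat)

  # swapping the copies swaps the vote
  cls2 <- classify_indels(extract_indels(align_copies(b, a)))
  expect_identical(cls2$kind, "microhomology_jump")
  expect_identical(cls2$neosynthesized_vote, "distal")
})

test_that("tandem-unit insertions are classified as slippage-prone tandem repeats", {
  # insertion "CATCAT" where the template has a single "CAT"
  left <- "GGTACCTTGAAGGT"
  right <- "GTCAAGGTTTCAAC"
  with_ins <- paste0(left, "CAT", "CATCAT", right)
  without <- paste0(left, "CAT", right)
  aln <- align_copies(with_ins, without)
  cls <- classify_indels(extract_indels(aln))
  expect_identical(cls$kind, "tandem_repeat")
  expect_identical(cls$evidence, "CAT")
  expect_true(cls$slippage_caveat)
  # the copy carrying the insertion (a = distal) is the vote
  expect_identical(cls$neosynthesized_vote, "distal")
})

test_that("sub-threshold indels stay unclassified", {
  left <- "GGCACCATGGACGT"
  right <- "TTGCATTACGGAGG"
  a <- paste0(left, "C", right)
  aln <- align_copies(a, paste0(left, right))
  cls <- classify_indels(extract_indels(aln), min_mh = 2)
  expect_true(is.na(cls$kind))
  expect_true(is.na(cls$neosynthesized_vote))
})

test_that("classification is invariant to gap placement within a repeat", {
  # the same tandem insertion with the gap pushed to either extreme
  variants <- list(
    mk_aln2("GGTACCTTCATCATGTCAAGG", "GGTACCTT---CATGTCAAGG"),
    mk_aln2("GGTACCTTCATCATGTCAAGG", "GGTACCTTCAT---GTCAAGG"))
  for (aln in variants) {
    cls <- classify_indels(extract_indels(aln))
    expect_identical(cls$kind, "tandem_repeat")
    expect_identical(cls$evidence, "CAT")
  }
})

test_that("the neosynthesized verdict is a majority vote with honest ties", {
  sig <- tibble::tibble(
    kind = c(rep("microhomology_jump", 3), "tandem_repeat", "tandem_repeat"),
    neosynthesized_vote = c(rep("proximal", 4), "distal"),
    slippage_caveat = c(rep(FALSE, 3), TRUE, TRUE))
  v <- infer_neosynthesized(sig)
  expect_identical(v$verdict, "proximal")
  expect_identical(c(v$n_proximal, v$n_distal), c(4L, 1L))
  expect_identical(v$n_slippage, 2L)
  expect_identical(nrow(tidy(v)), 3L)

  empty <- infer_neosynthesized(sig[0, ])
  expect_identical(empty$verdict, "undetermined")
  tie <- infer_neosynthesized(sig[4:5, ])
  expect_identical(tie$verdict, "undetermined")
})

test_that("planted signatures in a fixture are recovered end to end", {
  fx <- generate_fixture(toy_scenario(), seed = 42)
  t <- fx$truth
  a <- substring(fx$sequence, t$distal[1] + 1, t$distal[2])
  b <- substring(fx$sequence, t$proximal[1] + 1, t$proximal[2])
  aln <- align_copies(a, b)
  ind <- extract_indels(aln)
  expect_identical(nrow(ind), nrow(t$signatures))
  cls <- classify_indels(ind)
  # detected loci match the planted ones up to gap-placement ambiguity
  for (i in seq_len(nrow(t$signatures))) {
    s <- t$signatures[i, ]
    local_a <- s$distal_pos - t$distal[1]
    hit <- which(abs(ind$a_pos - local_a) <= s$size & ind$length == s$size)
    expect_length(hit, 1L)
    expect_identical(
      cls$kind[hit],
      ifelse(s$kind == "deletion", NA_character_, s$kind))
    if (s$kind != "deletion") {
      expect_identical(cls$neosynthesized_vote[hit], s$copy)
    }
  }
  expect_identical(infer_neosynthesized(cls)$verdict, "undetermined") # 1 vs 1
})
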