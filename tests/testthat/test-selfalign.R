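test_that("k-mer self-matching agrees with brute-force comparison", {
  set.seed(5)
  expect_identical(nrow(kmer_self_matches(rand_dna(200), 16)), 0L)
  expect_error(kmer_self_matches("ACGT", 16), "exceeds")
  expect_error(kmer_self_matches(rand_dna(50), 4), ">= 8")

  # S + S: one off-diagonal run with pos_j - pos_i = |S| everywhere
  s <- rand_dna(300)
  m <- kmer_self_matches(paste0(s, s), 16)
  fwd <- m[m$strand == "+", ]
  expect_identical(nrow(fwd), 300L - 15L)
  expect_true(all(fwd$pos_j - fwd$pos_i == 300))
  # equals the quadratic all-pairs oracle
  bf <- kmer_pairs_bruteforce(paste0(s, s), 16)
  expect_identical(cbind(fwd$pos_i, fwd$pos_j), unname(bf))

  # homopolymer saturates: all pairs i < j <= n - k
  hp <- kmer_self_matches(strrep("A", 50), 16)
  expect_identical(nrow(hp), as.integer(choose(35, 2)))
  expect_true(all(hp$strand == "+"))

  # reverse-complement matches are flagged; every antidiagonal pair between
  # s and rc(s) must be present (chance matches across the spacer may add)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  m2 <- kmer_self_matches(paste0(s, rand_dna(40), rc), 16)
  expect_true(all(m2$strand == "-"))
  expected <- tibble::tibble(pos_i = 0:284, pos_j = 640L - 16L - (0:284))
  expect_identical(nrow(dplyr::semi_join(expected, m2,
                                         by = c("pos_i", "pos_j"))), 285L)
})

test_that("an exact tandem S+S is called with exact boundaries", {
  set.seed(8)
  s <- rand_dna(500)
  seq <- paste0(s, s)
  call <- detect_tandem_duplication(kmer_self_matches(seq, 16),
                                    min_copy_length = 400, seq = seq)
  expect_equal(call$distal_start, 0)
  expect_equal(call$distal_end, 500)
  expect_equal(call$proximal_start, 500)
  expect_equal(call$proximal_end, 1000)
  expect_equal(call$copy_length, 500)
  expect_equal(call$junction_end - call$junction_start, 0)
  expect_identical(call$orientation, "direct")
})

test_that("random sequence yields no duplication call", {
  set.seed(13)
  seq <- rand_dna(50000)
  expect_null(detect_tandem_duplication(kmer_self_matches(seq, 16),
                                        min_copy_length = 1000, seq = seq))
})

test_that("a mutation-free constructed tandem with junction is recovered exactly", {
  sc <- dup_scenario(dup_length = 3000, dup_start = 400, n_modules = 1,
                     te_length = 300, rist_length = 100, te_site_offset = 60,
                     identical_tract = c(0, 3000), background_divergence = 0)
  fx <- generate_fixture(sc, seed = 2)
  call <- detect_tandem_duplication(kmer_self_matches(fx$sequence, 16),
                                    min_copy_length = 1000, seq = fx$sequence)
  expect_equal(c(call$distal_start, call$distal_end), fx$truth$distal)
  expect_equal(c(call$proximal_start, call$proximal_end), fx$truth$proximal)
  expect_equal(c(call$junction_start, call$junction_end), fx$truth$junction)
})

test_that("alignment handles identical strings and the worked toy exactly", {
  aln <- align_copies("ACGTACGTAC", "ACGTACGTAC")
  expect_true(all(aln$state == "match"))
  expect_equal(aln$score, 10)

  aln2 <- align_copies("ACGT", "ACT")
  expect_equal(aln2$score, 3 - 5 - 1) # 3 matches, one 1-bp gap
  expect_equal(aln2$score, affine_dp_score("ACGT", "ACT"))
  expect_identical(sum(aln2$state == "gap_in_b"), 1L)
  expect_error(align_copies("", "ACGT"), "non-empty")
})

test_that("alignment score equals the brute-force affine DP on short strings", {
  set.seed(17)
  for (case in 1:25) {
    n <- sample(5:40, 1)
    a <- rand_dna(n)
    b <- a
    # perturb: substitutions and a small indel
    if (case %% 3 == 0) {
      cut <- sample(n - 3, 1)
      b <- paste0(substring(b, 1, cut), substring(b, cut + sample(1:3, 1) + 1))
    }
    chars <- strsplit(b, "")[[1]]
    mut <- sample(length(chars), min(3, length(chars)))
    chars[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
    b <- paste(chars, collapse = "")
    expect_equal(align_copies(a, b)$score, affine_dp_score(a, b),
                 info = sprintf("case %d: %s vs %s", case, a, b))
  }
})

test_that("anchored alignment equals full DP around local differences", {
  set.seed(23)
  a <- rand_dna(9000)
  # one deletion, one insertion, a few substitutions
  b <- paste0(substring(a, 1, 3000), substring(a, 3013, 6000),
              "TTACGGAT", substring(a, 6001))
  ch <- strsplit(b, "")[[1]]
  ch[c(1500, 4500, 7500)] <- c("A", "C", "G")
  b <- paste(ch, collapse = "")
  full <- align_copies(a, b, max_dp = 10000)     # direct DP
  anch <- align_copies(a, b, max_dp = 500)       # forced anchor-and-fill
  expect_identical(anch$a, full$a)
  expect_identical(anch$b, full$b)
  expect_equal(anch$score, full$score)
})

test_that("degapping an alignment recovers its inputs", {
  set.seed(29)
  for (i in 1:5) {
    a <- rand_dna(60)
    b <- rand_dna(55)
    aln <- align_copies(a, b)
    expect_identical(gsub("-", "", aln$a), a)
    expect_identical(gsub("-", "", aln$b), b)
    expect_identical(nchar(aln$a), nchar(aln$b))
    expect_identical(aln$n_col, nchar(aln$a))
  }
})
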