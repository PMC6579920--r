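test_that("protein identity/coverage match definition and oracle", {
  p <- strrep("ACDEFGHIKL", 10)
  expect_equal(unname(protein_identity_coverage(p, p)), c(1, 1))
  # exact prefix: identity 1 over the aligned region, coverage on the longer
  r <- protein_identity_coverage(p, substr(p, 1, 70))
  expect_equal(unname(r["identity"]), 1)
  expect_equal(unname(r["coverage"]), 0.70)
  expect_error(protein_identity_coverage("ACDB5", p), "amino-acid")
  expect_error(protein_identity_coverage("", p), "non-empty")
  # ends-free alignment score agrees with a dynamic-programming oracle
  set.seed(21)
  for (i in 1:3) {
    a <- rnd_protein(40); b <- sub_protein(a, 8)
    pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                        type = "overlap", substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(pa), nw_overlap_oracle(a, b))
  }
})

test_that("k-mer index stores every position and respects strand lookup", {
  set.seed(22)
  s <- rnd_dna(100)
  idx <- build_kmer_index(s, k = 11)
  expect_equal(nrow(idx$table), 90L)  # length - k + 1
  expect_error(build_kmer_index(s, k = 5), "k must be")
  # planted exact repeat found at both positions by exhaustive scan
  rep20 <- rnd_dna(20)
  s2 <- paste0(rnd_dna(50), rep20, rnd_dna(100), rep20, rnd_dna(30))
  idx2 <- build_kmer_index(s2, k = 13)
  km <- substr(rep20, 1, 13)
  found <- kmer_positions(idx2, km)
  oracle <- which(vapply(seq_len(nchar(s2) - 12), function(i)
    substr(s2, i, i + 12) == km, logical(1)))
  expect_equal(found, oracle)
  # minus-strand retrieval equals forward positions of the reverse complement
  expect_equal(kmer_positions(idx2, revcomp(km), strand = "-"), found)
  # N-containing k-mers are skipped
  sN <- paste0(rnd_dna(20), "N", rnd_dna(20))
  idxN <- build_kmer_index(sN, k = 13)
  expect_false(any(grepl("N", idxN$table$kmer)))
})

test_that("local_search finds exact and thresholded hits", {
  set.seed(23)
  subj <- rnd_dna(10000)
  q <- substr(subj, 4001, 7000)
  hits <- local_search(q, subj, min_length = 1000, min_identity = 0.95)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1)
  expect_gte(hits$length, 3000L)
  expect_lte(hits$s_start, 4001L)
  expect_gte(hits$s_end, 7000L)
  # 85% identity query rejected at a 0.90 threshold
  q85 <- sub_dna(q, round(0.15 * nchar(q)))
  expect_equal(nrow(local_search(q85, subj, min_length = 1000, min_identity = 0.90)), 0L)
  expect_error(local_search("", subj), "empty")
})

test_that("local_search matches the Smith-Waterman oracle on planted loci", {
  set.seed(24)
  el <- rnd_dna(800)
  pieces <- character(0)
  truth <- integer(0)
  pos <- 0L
  for (i in 1:3) {
    pad <- rnd_dna(650)
    copy <- sub_dna(el, round(runif(1, 0, 0.05) * nchar(el)))
    pieces <- c(pieces, pad, copy)
    truth <- c(truth, pos + nchar(pad) + 1L)
    pos <- pos + nchar(pad) + nchar(copy)
  }
  subj <- paste0(paste(pieces, collapse = ""), rnd_dna(500))
  expect_lte(nchar(subj), 5000L)
  hits <- local_search(el, subj, min_length = 400, min_identity = 0.90)
  expect_equal(nrow(hits), 3L)  # identical block count
  hits <- hits[order(hits$s_start), ]
  for (i in 1:3) {
    lo <- max(1L, truth[i] - 100L); hi <- min(nchar(subj), truth[i] + 900L)
    oracle <- sw_oracle(el, substr(subj, lo, hi))
    expect_equal(hits$score[i], oracle$score)  # score-equivalent locus
    expect_equal(hits$s_start[i], oracle$s_start + lo - 1L)
    expect_equal(hits$s_end[i], oracle$s_end + lo - 1L)
  }
})

test_that("strand symmetry: reverse-complement query flips labels only", {
  set.seed(25)
  subj <- rnd_dna(8000)
  q <- substr(subj, 2001, 3500)
  fwd <- local_search(q, subj, min_length = 500, min_identity = 0.95)
  rev <- local_search(revcomp(q), subj, min_length = 500, min_identity = 0.95)
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 1L)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_equal(rev$s_start, fwd$s_start)
  expect_equal(rev$s_end, fwd$s_end)
  expect_equal(rev$identity, fwd$identity)
})

test_that("merge_blocks bridges gaps up to max_gap and matches brute force", {
  b <- tibble::tibble(query_id = "q", subject_id = "s",
                      q_start = c(1L, 1201L), q_end = c(1000L, 2000L),
                      s_start = c(1L, 1201L), s_end = c(1000L, 2000L),
                      strand = "+", identity = 1,
                      length = c(1000L, 800L), matches = c(1000L, 800L),
                      columns = c(1000L, 800L), score = c(1000, 800))
  m1 <- merge_blocks(b, max_gap = 500)
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$q_start, m1$q_end), c(1L, 2000L))
  m2 <- merge_blocks(b, max_gap = 100)
  expect_equal(nrow(m2), 2L)
  # 50 random blocks against the interval-arithmetic oracle
  set.seed(26)
  for (rep in 1:3) {
    starts <- sample.int(5000, 50)
    ends <- starts + sample.int(300, 50)
    rb <- tibble::tibble(query_id = "q", subject_id = "s", q_start = starts,
                         q_end = ends, s_start = starts, s_end = ends,
                         strand = "+", identity = 1, length = ends - starts + 1L,
                         matches = ends - starts + 1L, columns = ends - starts + 1L,
                         score = 1)
    gap <- sample(c(10L, 100L, 400L), 1)
    got <- merge_blocks(rb, max_gap = gap)
    want <- merge_oracle(starts, ends, gap)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$q_start, as.integer(want[, 1]))
    expect_equal(got$q_end, as.integer(want[, 2]))
    # separation property
    if (nrow(got) > 1) {
      expect_true(all(got$q_start[-1] - got$q_end[-nrow(got)] - 1L > gap))
    }
  }
})

test_that("inverted repeat detection finds planted arms and matches the scan oracle", {
  set.seed(27)
  ir <- rnd_dna(14)
  elem <- paste0(ir, rnd_dna(700), revcomp(ir))
  hits <- find_inverted_repeats(elem, arm_min = 10, arm_max = 30,
                                max_mismatch = 0, window = 60)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$left_start[1], 1L)
  expect_equal(hits$right_end[1], nchar(elem))
  expect_equal(hits$mismatches[1], 0L)
  expect_gte(hits$repeat_length[1], 14L)
  # random sequence: results equal the exhaustive arm-pair oracle
  for (rep in 1:3) {
    s <- rnd_dna(300)
    got <- find_inverted_repeats(s, arm_min = 12, arm_max = 14,
                                 max_mismatch = 0, window = 80)
    oracle <- ir_oracle(s, 12, 14, 0, 80)
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      # every reported pair is in the oracle set
      for (i in seq_len(nrow(got))) {
        expect_true(any(oracle[, 1] == got$left_start[i] &
                          oracle[, 4] == got$right_end[i] &
                          oracle[, 6] >= got$repeat_length[i]))
      }
    }
  }
  # mirror symmetry on the reverse complement
  rc_hits <- find_inverted_repeats(revcomp(elem), arm_min = 10, arm_max = 30,
                                   max_mismatch = 0, window = 60)
  n <- nchar(elem)
  expect_equal(rc_hits$left_start[1], n - hits$right_end[1] + 1L)
  expect_equal(rc_hits$right_end[1], n - hits$left_start[1] + 1L)
})

test_that("direct repeat detection respects the mismatch budget", {
  set.seed(28)
  att <- "AGAAGTCCCAGT"
  core <- rnd_dna(3000)
  s <- paste0(rnd_dna(400), att, core, att, rnd_dna(400))
  island <- c(401L, 400L + 12L + nchar(core) + 12L)
  hits <- find_direct_repeats(s, island, repeat_length = 12, max_mismatch = 0,
                              window = 100)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$left_start[1], 401L)
  expect_equal(hits$right_start[1], island[2] - 11L)
  expect_gte(hits$repeat_length[1], 12L)
  # no repeat -> empty
  s2 <- paste0(rnd_dna(400), core, rnd_dna(400))
  expect_equal(nrow(find_direct_repeats(s2, c(401L, 400L + nchar(core)),
                                        repeat_length = 12, max_mismatch = 0,
                                        window = 100)), 0L)
  # one planted mismatch: found at budget 1, absent at budget 0
  att_mut <- sub_dna(att, 1)
  s3 <- paste0(rnd_dna(400), att, core, att_mut, rnd_dna(400))
  expect_gte(nrow(find_direct_repeats(s3, island, 12, max_mismatch = 1,
                                      window = 100)), 1L)
  expect_equal(nrow(find_direct_repeats(s3, island, 12, max_mismatch = 0,
                                        window = 100)), 0L)
})

test_that("in-silico PCR obeys orientation, topology and rotation invariance", {
  set.seed(29)
  t1 <- rnd_dna(1200)
  fwd <- substr(t1, 101, 120)
  rev <- revcomp(substr(t1, 581, 600))
  p <- in_silico_pcr(t1, fwd, rev, max_product = 1000, max_mismatch = 0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$product_length, 500L)
  expect_gte(p$product_length, nchar(fwd) + nchar(rev))
  # outward-pointing pair: nothing on the linear form, one product on the circle
  f2 <- substr(t1, 900, 921)
  r2 <- revcomp(substr(t1, 150, 171))
  expect_equal(nrow(in_silico_pcr(t1, f2, r2, 2000, 0)), 0L)
  circ <- replicon("c", t1, "circular")
  pc <- in_silico_pcr(circ, f2, r2, 2000, 0)
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$product_length, (1200L - 900L + 1L) + 171L)
  # rotation of a circular template never changes the product set
  for (sh in c(137L, 600L, 1100L)) {
    rot <- paste0(substr(t1, sh + 1, 1200), substr(t1, 1, sh))
    pr <- in_silico_pcr(replicon("c", rot, "circular"), f2, r2, 2000, 0)
    expect_equal(nrow(pr), 1L)
    expect_equal(pr$product_length, pc$product_length)
  }
  # 3'-terminal base must match exactly
  fwd_3mm <- paste0(substr(fwd, 1, 19), setdiff(c("A", "C", "G", "T"),
                                                substr(fwd, 20, 20))[1])
  expect_equal(nrow(in_silico_pcr(t1, fwd_3mm, rev, 1000, max_mismatch = 2)), 0L)
  expect_error(in_silico_pcr(t1, "ACGTACGTAC", rev), ">= 15")
})
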