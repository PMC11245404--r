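mk_windows <- function(seqs, flank) {
  junction_windows(circ_tbl(paste0("c", seq_along(seqs)), mature_seq = seqs),
                   flank = flank)
}

test_that("reads must cross the junction boundary to hit", {
  w <- mk_windows("AAAATTTT", 4)  # window TTTTAAAA, boundary after 4
  h <- match_reads_to_junctions(
    tibble::tibble(read_id = "r1", seq = "TTAA"), w)
  expect_equal(nrow(h), 1L)
  expect_equal(h$overhang5, 2L)
  expect_equal(h$overhang3, 2L)

  # AAAA matches only after the junction: no hit
  h2 <- match_reads_to_junctions(
    tibble::tibble(read_id = "r2", seq = "AAAA"), w)
  expect_equal(nrow(h2), 0L)

  # a read equal to the whole window overhangs by the full flank
  h3 <- match_reads_to_junctions(
    tibble::tibble(read_id = "r3", seq = "TTTTAAAA"), w)
  expect_equal(h3$overhang5, 4L)
  expect_equal(h3$overhang3, 4L)
})

test_that("mismatch budget and N handling are enforced", {
  w <- mk_windows("AAAATTTT", 4)
  r <- tibble::tibble(read_id = "r", seq = "TTGA")
  expect_equal(nrow(match_reads_to_junctions(r, w, max_mismatch = 0)), 0L)
  h <- match_reads_to_junctions(r, w, max_mismatch = 1)
  expect_gt(nrow(h), 0L)
  expect_true(all(h$mismatches == 1L))
  # N in the read never matches, even N-to-N
  rn <- tibble::tibble(read_id = "rn", seq = "TTNA")
  expect_equal(nrow(match_reads_to_junctions(rn, w, max_mismatch = 0)), 0L)
})

test_that("reads longer than the window are skipped with a counter", {
  w <- mk_windows("AAAATTTT", 4)
  h <- match_reads_to_junctions(
    tibble::tibble(read_id = "r", seq = strrep("A", 20)), w)
  expect_equal(nrow(h), 0L)
  expect_equal(attr(h, "n_skipped_long"), 1L)
})

test_that("matcher equals the brute-force all-offsets Hamming scan", {
  set.seed(211)
  for (i in 1:30) {
    L <- sample(26:60, 1)
    s <- random_circle(L)
    w <- junction_windows(circ_tbl("c1", mature_seq = s), flank = 25)
    m <- sample(15:36, 1)
    # half the reads are genuine junction substrings, half random
    read <- if (i %% 2 == 0) {
      start <- sample(seq_len(nchar(w$window_seq) - m + 1), 1)
      substr(w$window_seq, start, start + m - 1)
    } else {
      random_circle(m)
    }
    mm <- sample(0:2, 1)
    mine <- match_reads_to_junctions(
      tibble::tibble(read_id = "r", seq = read), w, max_mismatch = mm)
    oracle <- oracle_match_one(read, w$window_seq, w$junction_offset, mm)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine) > 0) {
      expect_equal(mine$window_offset, oracle$window_offset)
      expect_equal(mine$overhang5, oracle$overhang5)
      expect_equal(mine$overhang3, oracle$overhang3)
      expect_equal(mine$mismatches, oracle$mismatches)
    }
  }
})

test_that("hit counts agree with Biostrings pattern matching", {
  set.seed(223)
  for (i in 1:15) {
    s <- random_circle(sample(30:60, 1))
    w <- junction_windows(circ_tbl("c1", mature_seq = s), flank = 25)
    m <- sample(15:30, 1)
    start <- sample(seq_len(nchar(w$window_seq) - m + 1), 1)
    read <- substr(w$window_seq, start, start + m - 1)
    mine <- match_reads_to_junctions(
      tibble::tibble(read_id = "r", seq = read), w)
    bs <- Biostrings::matchPattern(read, Biostrings::DNAString(w$window_seq))
    crossing <- sum(Biostrings::start(bs) <= w$junction_offset &
                      Biostrings::end(bs) >= w$junction_offset + 1)
    expect_equal(nrow(mine), crossing)
  }
})

test_that("unique-read collapsing works per junction", {
  w <- mk_windows(c("AAAATTTT", "AACATTGT"), 4)
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    seq = c("TTAA", "TTAA", "TGTA")
  )
  hits <- match_reads_to_junctions(reads, w)
  ded <- dedupe_unique(hits, reads)
  c1 <- ded[ded$circ_id == "c1", ]
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$n_collapsed, 2L)
  expect_equal(nrow(dedupe_unique(hits[0, ], reads)), 0L)
})

test_that("a duplicated sequence hitting two junctions counts once per junction", {
  w <- mk_windows(c("AAAATTTT", "AAAATTTT"), 4)
  w$circ_id <- c("c1", "c2")
  reads <- tibble::tibble(read_id = c("r1", "r2"), seq = c("TTAA", "TTAA"))
  ded <- dedupe_unique(match_reads_to_junctions(reads, w), reads)
  expect_equal(sort(ded$circ_id), c("c1", "c2"))
  expect_equal(ded$n_collapsed, c(2L, 2L))
})

test_that("ribosome association applies the 2-unique/4-nt-overhang rule", {
  mk_hits <- function(ov) {
    tibble::tibble(read_id = paste0("r", seq_len(nrow(ov))), circ_id = "c1",
                   window_offset = 0L, overhang5 = ov[, 1], overhang3 = ov[, 2],
                   mismatches = 0L)
  }
  not_assoc <- call_ribosome_associated(mk_hits(rbind(c(10, 3), c(5, 5))))
  expect_false(not_assoc$ribosome_associated)
  expect_equal(not_assoc$n_unique_eligible, 1L)

  assoc <- call_ribosome_associated(mk_hits(rbind(c(4, 21), c(6, 19))))
  expect_true(assoc$ribosome_associated)

  none <- call_ribosome_associated(mk_hits(rbind(c(4, 21)))[0, ],
                                   circ_ids = "c1")
  expect_false(none$ribosome_associated)
  expect_equal(none$n_hits, 0L)
})

test_that("raising thresholds never increases associated calls", {
  set.seed(31)
  hits <- tibble::tibble(
    read_id = paste0("r", 1:200),
    circ_id = sample(paste0("c", 1:20), 200, replace = TRUE),
    window_offset = 0L,
    overhang5 = sample(1:20, 200, replace = TRUE),
    overhang3 = sample(1:20, 200, replace = TRUE),
    mismatches = 0L
  )
  n_assoc <- function(mu, mo) {
    sum(call_ribosome_associated(hits, min_unique = mu,
                                 min_overhang = mo)$ribosome_associated)
  }
  for (mu in 1:4) for (mo in 1:8) {
    expect_lte(n_assoc(mu + 1, mo), n_assoc(mu, mo))
    expect_lte(n_assoc(mu, mo + 1), n_assoc(mu, mo))
  }
})

test_that("candidate flagging needs two independent back-spliced reads", {
  counts <- tibble::tibble(circ_id = c("a", "b", "c"),
                           n_bsj_reads = c(1L, 2L, 0L))
  flags <- rna_junction_support(counts)
  expect_equal(flags$candidate, c(FALSE, TRUE, FALSE))

  # duplicated identical reads count once
  w <- mk_windows("AAAATTTT", 4)
  reads <- tibble::tibble(read_id = c("r1", "r2"), seq = c("TTAA", "TTAA"))
  hits <- match_reads_to_junctions(reads, w)
  flags2 <- rna_junction_support(hits, reads = reads)
  expect_equal(flags2$n_bsj_reads, 1L)
  expect_false(flags2$candidate)
})

test_that("read-length histogram reports exact counts and range fraction", {
  reads <- tibble::tibble(seq = strrep("A", c(28, 28, 30)))
  h <- read_length_histogram(reads)
  expect_equal(h$n[h$length == 28], 2L)
  expect_equal(h$n[h$length == 30], 1L)
  expect_equal(attr(h, "fraction_in_range"), 1)

  empty <- read_length_histogram(tibble::tibble(seq = character()))
  expect_equal(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "fraction_in_range")))
})

test_that("frame periodicity fractions behave at the extremes and in bulk", {
  all0 <- frame_periodicity(c(0, 3, 9, 300))
  expect_equal(all0$fraction, c(1, 0, 0))

  set.seed(5)
  unif <- frame_periodicity(sample(0:299, 30000, replace = TRUE))
  expect_true(all(abs(unif$fraction - 1 / 3) < 0.02))

  per <- frame_periodicity(simulate_frame_offsets(10000, 0.7, seed = 2))
  expect_lt(abs(per$fraction[1] - 0.7), 0.02)
  expect_equal(sum(per$fraction), 1)

  expect_error(frame_periodicity(integer()), class = "circpep_input_error")
})
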