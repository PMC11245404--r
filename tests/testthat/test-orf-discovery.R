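test_that("pseudo-circularisation replicates the sequence", {
  expect_equal(pseudo_circularize("ACG", 4), "ACGACGACGACG")
  s <- random_circle(37)
  expect_equal(nchar(pseudo_circularize(s)), 4L * 37L)
  expect_error(pseudo_circularize("ACG", 1), class = "circpep_parameter_error")
  expect_error(pseudo_circularize(""), class = "circpep_input_error")
})

test_that("only junction-spanning ORFs are retained", {
  # the ATG ORF of ATGTAA lies wholly within one copy
  expect_equal(nrow(find_circ_orfs(circ_tbl("a", mature_seq = "ATGTAA"),
                                   start_codons = "ATG")), 0L)

  orfs <- find_circ_orfs(circ_tbl("b", mature_seq = "TAAATGGCT"),
                         start_codons = "ATG")
  expect_equal(orfs$start, 3L)
  expect_equal(orfs$length_nt, 9L)
  expect_equal(orfs$peptide, "MA")
  expect_equal(orfs$wraps, 1L)
  expect_false(orfs$stopless)
})

test_that("stop-less rolling-circle ORFs are truncated and flagged", {
  orfs <- find_circ_orfs(circ_tbl("c", mature_seq = "ATGAAA"),
                         start_codons = "ATG")
  expect_equal(orfs$length_nt, 24L)
  expect_true(orfs$stopless)
  expect_equal(orfs$peptide, "MKMKMKMK")
  expect_equal(orfs$wraps, 3L)
})

test_that("ORF calls match the brute-force enumerator on random circles", {
  set.seed(101)
  for (i in 1:60) {
    L <- sample(6:60, 1)
    s <- random_circle(L)
    mine <- find_circ_orfs(circ_tbl("x", mature_seq = s))
    oracle <- oracle_find_orfs(s)
    expect_equal(orf_call_key(mine), orf_call_key(oracle), info = s)
  }
})

test_that("every retained ORF wraps and starts inside the first copy", {
  set.seed(103)
  for (i in 1:20) {
    s <- random_circle(sample(20:90, 1))
    orfs <- find_circ_orfs(circ_tbl("x", mature_seq = s))
    if (nrow(orfs) == 0) next
    expect_true(all(orfs$wraps >= 1))
    expect_true(all(orfs$start >= 0 & orfs$start < nchar(s)))
    expect_true(all(orfs$length_nt %% 3 == 0))
    # peptide length identity: length_nt/3 - 1 with a stop, length_nt/3 without
    expect_equal(nchar(orfs$peptide),
                 orfs$length_nt / 3 - as.integer(!orfs$stopless))
    # junction residue indices stay inside the peptide
    expect_true(all(unlist(orfs$junction_residues) >= 1))
    expect_true(all(purrr::map2_lgl(
      orfs$junction_residues, nchar(orfs$peptide),
      ~ all(.x <= .y)
    )))
  }
})

test_that("ORF calls on a rotated circle are the shifted intrinsic calls", {
  # Rotation moves the back-splice junction, so which ORFs span it is
  # origin-dependent by definition. The intrinsic call universe is not:
  # calls on the rotated circle must equal the shifted universe after
  # re-applying junction retention and longest-per-circular-stop
  # filtering under the new origin.
  set.seed(107)
  for (i in 1:15) {
    L <- sample(12:48, 1)
    s <- random_circle(L)
    universe <- oracle_raw_orfs(s)
    k <- sample(L - 1, 1)
    rot <- find_circ_orfs(circ_tbl("x", mature_seq = circpep:::rotate_seq(s, k)))

    shifted <- universe
    shifted$start <- (universe$start - k) %% L
    shifted$stop_pos <- ifelse(universe$stopless, NA, universe$end0 %% L)
    term <- shifted[!shifted$stopless &
                      shifted$start + shifted$length_nt > L, , drop = FALSE]
    if (nrow(term) > 0) {
      term <- do.call(rbind, lapply(split(term, term$stop_pos), function(g) {
        g[which.max(g$length_nt), ]
      }))
    }
    # stop-less chains always wrap, so every stop-less start survives
    sl_starts <- sort(shifted$start[shifted$stopless])

    expect_equal(sort(rot$start[!rot$stopless]), sort(term$start))
    expect_equal(sort(rot$length_nt[!rot$stopless]), sort(term$length_nt))
    expect_equal(sort(rot$start[rot$stopless]), sl_starts)
  }
})

test_that("translation uses the standard code with initiator M", {
  expect_equal(translate_orf("ATGGCTTAA"), "MA")
  expect_equal(translate_orf("CTGGCTTAA"), "MA")
  expect_equal(translate_orf("GTGGCTGCT"), "MAA")
  expect_error(translate_orf("ATGTAAGCT"),
               class = "circpep_consistency_error")
  expect_error(translate_orf("ATGC"), class = "circpep_input_error")
})

test_that("CEP database applies the length floor and groups ambiguity", {
  mk_orf <- function(circ, pep, start = 0L) {
    tibble::tibble(circ_id = circ, start = start,
                   length_nt = 3L * (nchar(pep) + 1L),
                   start_codon = "ATG", stopless = FALSE, peptide = pep,
                   junction_residues = list(1L),
                   junction_spans = list(list(c(1L, 1L))), wraps = 1L)
  }
  orfs <- dplyr::bind_rows(
    mk_orf("c1", strrep("A", 10)),            # exactly 10 aa: excluded
    mk_orf("c2", strrep("C", 11)),            # 11 aa: included
    mk_orf("c3", paste0("M", strrep("W", 11))),
    mk_orf("c3", paste0("M", strrep("W", 11)), start = 5L),  # duplicate pair
    mk_orf("c4", strrep("C", 11))             # same peptide as c2
  )
  db <- build_cep_db(orfs, min_peptide_len = 11)
  expect_false("c1" %in% db$circ_id)
  expect_true("c2" %in% db$circ_id)
  expect_equal(sum(db$circ_id == "c3"), 1L)   # deduped (circ, peptide)
  shared <- db[db$circ_id %in% c("c2", "c4"), ]
  expect_equal(dplyr::n_distinct(shared$ambiguity_group), 1L)
  expect_true(all(shared$shared))
})

test_that("entries whose only junction contact is the stop codon are excluded", {
  # TAAATGGCT: peptide MA never reaches past the junction
  orfs <- find_circ_orfs(circ_tbl("b", mature_seq = "TAAATGGCT"),
                         start_codons = "ATG")
  expect_equal(length(orfs$junction_spans[[1]]), 0L)
})

test_that("decoy pool matches target lengths and is reproducible", {
  db <- build_cep_db(
    dplyr::bind_rows(lapply(1:3, function(i) {
      tibble::tibble(circ_id = paste0("c", i), start = 0L,
                     length_nt = 3L * (c(11, 15, 40)[i] + 1L),
                     start_codon = "ATG", stopless = FALSE,
                     peptide = paste(sample(circpep:::.AA20, c(11, 15, 40)[i],
                                            replace = TRUE), collapse = ""),
                     junction_residues = list(1L),
                     junction_spans = list(list(c(1L, 1L))), wraps = 1L)
    })),
    min_peptide_len = 11
  )
  d1 <- build_decoy_pool(db, seed = 5)
  d2 <- build_decoy_pool(db, seed = 5)
  expect_identical(d1$peptide, d2$peptide)
  expect_equal(sort(nchar(d1$peptide)), sort(nchar(db$peptide)))
  expect_false(any(d1$peptide %in% db$peptide))
  expect_true(all(d1$provenance == "decoy"))
})

test_that("decoy composition tracks the target amino-acid frequencies", {
  set.seed(300)
  pep <- vapply(1:300, function(i) {
    paste(sample(circpep:::.AA20, 30, replace = TRUE,
                 prob = seq(1, 2, length.out = 20)), collapse = "")
  }, character(1))
  db <- tibble::tibble(entry_id = as.character(1:300), circ_id = "c",
                       peptide = pep)
  decoys <- build_decoy_pool(db, seed = 17)
  tab <- rbind(
    target = table(factor(strsplit(paste(db$peptide, collapse = ""), "")[[1]],
                          levels = circpep:::.AA20)),
    decoy = table(factor(strsplit(paste(decoys$peptide, collapse = ""), "")[[1]],
                         levels = circpep:::.AA20))
  )
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
})
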