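test_that("tryptic digestion follows the Keil rule", {
  expect_equal(digest_trypsin("AKRP"), c("AK", "RP"))
  expect_equal(digest_trypsin("AAAA"), "AAAA")
  expect_setequal(digest_trypsin("AKCK", missed_cleavages = 1),
                  c("AK", "CK", "AKCK"))
  expect_error(digest_trypsin("AB1"), class = "circpep_alphabet_error")
})

test_that("fully-cleaved peptides partition the protein", {
  set.seed(401)
  for (i in 1:20) {
    prot <- paste(sample(circpep:::.AA20, sample(20:200, 1), replace = TRUE),
                  collapse = "")
    peps <- digest_trypsin(prot)
    expect_equal(paste(peps, collapse = ""), prot)
    # every internal boundary: previous residue K/R, next not P
    ends <- cumsum(nchar(peps))
    for (b in utils::head(ends, -1)) {
      expect_true(substr(prot, b, b) %in% c("K", "R"))
      expect_false(substr(prot, b + 1, b + 1) == "P")
    }
  }
})

test_that("theoretical peptide counting respects the length range", {
  expect_equal(count_theoretical_peptides("AKCK", c(1, 35)), 2L)
  expect_equal(count_theoretical_peptides("AAAA", c(7, 35)), 0L)
})

make_toy_dbs <- function(canonical_has_junction_pep = FALSE) {
  cep_db <- tibble::tibble(
    entry_id = "c1|0|45|0", circ_id = "c1",
    peptide = "AAAKWWWCCCKDDD",           # tryptic: AAAK / WWWCCCK / DDD
    junction_residues = list(7L),
    junction_spans = list(list(c(7L, 7L))),
    provenance = "predicted", ambiguity_group = 1L, shared = FALSE
  )
  decoys <- tibble::tibble(
    entry_id = "decoy|1", circ_id = NA_character_,
    peptide = "PPPPFFFFPPPP",
    junction_residues = list(integer()), junction_spans = list(list()),
    provenance = "decoy", ambiguity_group = NA_integer_, shared = FALSE
  )
  canonical <- tibble::tibble(
    seq_id = "LEP1",
    seq = if (canonical_has_junction_pep) "MMMKWWWCCCKGGG" else "MMMKEEEKGGG"
  )
  list(cep_db = cep_db, decoys = decoys, canonical = canonical)
}

test_that("peptide classification applies the two criteria in order", {
  dbs <- make_toy_dbs()
  peps <- tibble::tibble(
    pep_seq = c("WWWCCCK", "AAAK", "FFFF", "HHHHHH", "EEEK"),
    score = c(30, 25, 12, 10, 28)
  )
  ev <- classify_peptides(peps, dbs$cep_db, dbs$decoys, dbs$canonical)
  expect_equal(ev$class,
               c("cep_junction", "cep_nonjunction", "decoy", "unmatched",
                 "canonical"))
  expect_equal(ev$matched_entries[[1]], "c1|0|45|0")

  # criterion (i) dominates: same peptide present in the canonical digest
  dbs2 <- make_toy_dbs(canonical_has_junction_pep = TRUE)
  ev2 <- classify_peptides(peps[1, ], dbs2$cep_db, dbs2$decoys,
                           dbs2$canonical)
  expect_equal(ev2$class, "canonical")
})

test_that("classification is order-independent", {
  dbs <- make_toy_dbs()
  peps <- tibble::tibble(
    pep_seq = c("WWWCCCK", "AAAK", "FFFF", "HHHHHH"),
    score = c(30, 25, 12, 10)
  )
  ev <- classify_peptides(peps, dbs$cep_db, dbs$decoys, dbs$canonical)
  perm <- c(3, 1, 4, 2)
  ev_perm <- classify_peptides(peps[perm, ], dbs$cep_db, dbs$decoys,
                               dbs$canonical)
  expect_equal(ev_perm$class, ev$class[perm])
})

mk_evidence <- function(t_scores, d_scores) {
  tibble::tibble(
    pep_seq = paste0("P", seq_len(length(t_scores) + length(d_scores))),
    score = c(t_scores, d_scores),
    sample = "S1",
    class = rep(c("cep_junction", "decoy"),
                c(length(t_scores), length(d_scores))),
    matched_entries = c(replicate(length(t_scores), "e1", simplify = FALSE),
                        replicate(length(d_scores), character(),
                                  simplify = FALSE))
  )
}

test_that("target-decoy FDR accepts by the decoy/target threshold scan", {
  # uncorrected decoy/target ratio: one decoy below three targets
  ev <- target_decoy_fdr(mk_evidence(c(10, 9, 8, 1), 7), alpha = 0.05,
                         correction = "none")
  acc <- ev[ev$accepted, ]
  expect_setequal(acc$score, c(10, 9, 8))

  # the conservative default refuses to accept a lone top target
  # (which the uncorrected ratio would assign FDR 0)
  ev1 <- target_decoy_fdr(mk_evidence(c(10, 9, 8, 1), 7), alpha = 0.05)
  expect_equal(sum(ev1$accepted), 0L)
  # ... but accepts a large well-separated target block: q = 1/T
  ev_big <- target_decoy_fdr(mk_evidence(seq(30, 35, length.out = 40),
                                         c(7, 6, 5)), alpha = 0.05)
  expect_equal(sum(ev_big$accepted), 40L)

  # all decoys outscore all targets: nothing accepted either way
  for (corr in c("plus1", "none")) {
    ev2 <- target_decoy_fdr(mk_evidence(c(3, 2, 1), c(10, 9)),
                            alpha = 0.05, correction = corr)
    expect_equal(sum(ev2$accepted), 0L)
  }

  expect_error(
    target_decoy_fdr(mk_evidence(c(3, 2), numeric())),
    class = "circpep_input_error"
  )
})

test_that("q-values are non-increasing in score and monotone in alpha", {
  set.seed(61)
  ev <- target_decoy_fdr(mk_evidence(rnorm(80, 1), rnorm(60)), alpha = 0.05)
  tg <- ev[ev$class == "cep_junction", ]
  tg <- tg[order(-tg$score), ]
  expect_true(all(diff(tg$q_value) >= -1e-12))
  for (a in c(0.01, 0.05, 0.2, 0.5)) {
    acc_a <- sum(target_decoy_fdr(mk_evidence(tg$score,
                                              ev$score[ev$class == "decoy"]),
                                  alpha = a)$accepted)
    acc_b <- sum(target_decoy_fdr(mk_evidence(tg$score,
                                              ev$score[ev$class == "decoy"]),
                                  alpha = a * 2)$accepted)
    expect_lte(acc_a, acc_b)
  }
})

test_that("MS support summary maps peptides to circRNAs with sharing flags", {
  db <- tibble::tibble(
    entry_id = c("e1", "e2", "e3"),
    circ_id = c("c1", "c1", "c2")
  )
  ev <- tibble::tibble(
    pep_seq = c("PEPTIDEK", "ANOTHERK", "SHAREDK"),
    score = c(30, 29, 28), sample = "S1",
    class = "cep_junction",
    matched_entries = list("e1", "e2", c("e1", "e3")),
    q_value = 0, accepted = TRUE
  )
  summ <- summarize_coding_circs(ev, db)
  expect_setequal(summ$circ_id, c("c1", "c2"))
  c1 <- summ[summ$circ_id == "c1", ]
  expect_equal(c1$n_peptides_unique, 2L)
  expect_equal(c1$n_peptides_shared, 1L)
  c2 <- summ[summ$circ_id == "c2", ]
  expect_equal(c2$n_peptides_unique, 0L)
  expect_equal(c2$n_peptides_shared, 1L)
  expect_true(all(summ$ms_supported))

  expect_equal(nrow(summarize_coding_circs(ev[0, ], db)), 0L)
})

test_that("non-junction CEP matches never contribute MS support", {
  db <- tibble::tibble(entry_id = "e1", circ_id = "c1")
  ev <- tibble::tibble(
    pep_seq = "AAAK", score = 30, sample = "S1",
    class = "cep_nonjunction", matched_entries = list("e1"),
    q_value = NA_real_, accepted = FALSE
  )
  expect_equal(nrow(summarize_coding_circs(ev, db)), 0L)
})
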