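test_that("molecular weight is residue masses plus one water", {
  expect_equal(molecular_weight("G"), 75.0666, tolerance = 1e-4)
  # chain formation: mw(AB) = mw(A) + mw(B) - water
  expect_equal(molecular_weight("AC"),
               molecular_weight("A") + molecular_weight("C") - 18.0153,
               tolerance = 1e-6)
  expect_error(molecular_weight(""), class = "circpep_input_error")
  expect_error(molecular_weight("AXZ"), class = "circpep_alphabet_error")
})

test_that("pI orders acidic < neutral < basic and zeroes the net charge", {
  pi_d <- isoelectric_point("DDDD")
  pi_g <- isoelectric_point("GGGG")
  pi_k <- isoelectric_point("KKKK")
  expect_lt(pi_d, pi_g)
  expect_lt(pi_g, pi_k)
  for (s in c("DDDD", "GGGG", "KKKK", "ACDEFGHIKLMNPQRSTVWY")) {
    pi <- isoelectric_point(s, tolerance = 1e-4)
    expect_lt(abs(circpep:::protein_charge_at_ph(s, pi)), 1e-2)
  }
})

test_that("net charge decreases monotonically in pH", {
  set.seed(500)
  for (i in 1:5) {
    s <- paste(sample(circpep:::.AA20, 30, replace = TRUE), collapse = "")
    grid <- seq(0, 14, by = 0.25)
    ch <- vapply(grid, function(p) circpep:::protein_charge_at_ph(s, p),
                 numeric(1))
    expect_true(all(diff(ch) < 0))
  }
})

test_that("instability index handles the no-dipeptide edge case", {
  expect_warning(ii <- instability_index("W"), "dipeptide")
  expect_equal(ii, 0)
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravy("IV"), (4.5 + 4.2) / 2)
  # homopolymers give the scale value exactly; all values within scale bounds
  for (aa in c("A", "R", "I", "W")) {
    expect_equal(gravy(strrep(aa, 10)), circpep:::.KYTE_DOOLITTLE[[aa]])
  }
  set.seed(501)
  g <- gravy(vapply(1:20, function(i) {
    paste(sample(circpep:::.AA20, 25, replace = TRUE), collapse = "")
  }, character(1)))
  expect_true(all(g >= -4.5 & g <= 4.5))
})

test_that("calculators are case-insensitive and reject ambiguous residues", {
  expect_equal(molecular_weight("peptide"), molecular_weight("PEPTIDE"))
  expect_equal(gravy("ivl"), gravy("IVL"))
  for (f in list(molecular_weight, isoelectric_point, instability_index,
                 gravy)) {
    expect_error(f("PEPTIDEB"), class = "circpep_alphabet_error")
    expect_error(f("PEPTIDEU"), class = "circpep_alphabet_error")
  }
})

test_that("all four indices agree with the reference implementation", {
  ref <- utils::read.csv(test_path("physchem-reference.csv"),
                         stringsAsFactors = FALSE)
  expect_equal(nrow(ref), 50L)
  expect_equal(molecular_weight(ref$seq), ref$mw, tolerance = 1e-6)
  expect_lt(max(abs(isoelectric_point(ref$seq, tolerance = 1e-4) - ref$pi)),
            0.01)
  expect_lt(max(abs(instability_index(ref$seq) - ref$instability)), 0.01)
  expect_equal(gravy(ref$seq), ref$gravy, tolerance = 1e-6)
})

test_that("profile table carries the stability classification", {
  set.seed(502)
  prof <- physchem_profile(tibble::tibble(
    seq_id = paste0("p", 1:10),
    seq = vapply(1:10, function(i) {
      paste(sample(circpep:::.AA20, 40, replace = TRUE), collapse = "")
    }, character(1))
  ))
  expect_equal(prof$stable, prof$instability < 40)
  expect_equal(prof$length_aa, rep(40L, 10))
})

sim_profiles <- function(n, len_mean, stable_frac, seed) {
  set.seed(seed)
  lens <- pmax(10L, as.integer(rnorm(n, len_mean, len_mean / 5)))
  tibble::tibble(
    seq_id = paste0("s", seq_len(n)),
    length_aa = lens,
    mw = lens * 110 + rnorm(n, 0, 200),
    pi = runif(n, 4, 10),
    instability = ifelse(seq_len(n) <= round(stable_frac * n),
                         runif(n, 10, 39.9), runif(n, 40.1, 70)),
    gravy = rnorm(n, 0, 0.5),
    n_tryptic = pmax(0L, as.integer(lens / 12 + rnorm(n, 0, 1)))
  ) |>
    dplyr::mutate(stable = instability < 40)
}

test_that("identical groups give null comparisons", {
  g <- sim_profiles(50, 200, 0.5, seed = 600)
  cmp <- compare_physchem(g, g)
  tt <- tidy(cmp)
  expect_equal(tt$statistic[tt$metric == "length_aa"], 0)
  expect_true(all(tt$p_value > 0.99))
  expect_equal(tt$direction, rep(0, 5))
})

test_that("chi-square on a 2x2 table matches the hand computation", {
  ceps <- sim_profiles(40, 150, 30 / 40, seed = 601)
  leps <- sim_profiles(40, 150, 10 / 40, seed = 602)
  cmp <- compare_physchem(ceps, leps)
  chi <- tidy(cmp)
  expect_equal(chi$statistic[chi$metric == "stability"], 20, tolerance = 1e-9)
})

test_that("shorter, lighter CEPs are detected with the right direction", {
  ceps <- sim_profiles(200, 100, 0.7, seed = 603)
  leps <- sim_profiles(200, 450, 0.4, seed = 604)
  tt <- tidy(compare_physchem(ceps, leps))
  expect_lt(tt$p_value[tt$metric == "length_aa"], 0.001)
  expect_lt(tt$direction[tt$metric == "mw"], 0)
  expect_lt(tt$p_value[tt$metric == "stability"], 0.001)
  g <- glance(compare_physchem(ceps, leps))
  expect_equal(g$n_cep, 200L)
})

test_that("comparison is symmetric up to direction sign", {
  ceps <- sim_profiles(60, 120, 0.6, seed = 605)
  leps <- sim_profiles(60, 300, 0.3, seed = 606)
  ab <- tidy(compare_physchem(ceps, leps))
  ba <- tidy(compare_physchem(leps, ceps))
  expect_equal(ab$p_value[ab$metric == "length_aa"],
               ba$p_value[ba$metric == "length_aa"])
  expect_equal(ab$direction[ab$metric == "gravy"],
               -ba$direction[ba$metric == "gravy"])
})
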