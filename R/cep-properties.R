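# Physicochemical profiling of candidate circRNA-encoded proteins (CEPs)
# and their comparison against canonical linear-isoform proteins (LEPs):
# length, average molecular weight, theoretical pI (Bjellqvist pKa set,
# with residue-specific terminal corrections), instability index
# (Guruprasad DIWV dipeptide weights; < 40 classified stable), GRAVY
# (mean Kyte-Doolittle hydropathy), and theoretical tryptic peptide
# counts. All calculators are case-insensitive and reject ambiguous
# residues (B, J, O, U, X, Z).

#' Average protein molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param seq Amino-acid string(s).
#' @return Mass in Da.
#' @export
#' @examples
#' molecular_weight("G")  # 75.0666
molecular_weight <- function(seq) {
  vapply(toupper(seq), function(s) {
    if (nchar(s) == 0) {
      abort_circpep("Cannot compute the mass of an empty sequence.",
                    "circpep_input_error")
    }
    check_aa_alphabet(s)
    res <- strsplit(s, "")[[1]]
    sum(.AA_FREE_AVG_MASS[res]) - (length(res) - 1) * .WATER_AVG_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

# Net charge of a protein at a given pH under the Bjellqvist model.
# Positively ionisable groups (N-terminus, K, R, H) contribute
# 1/(1 + 10^(pH - pKa)); negatively ionisable groups (C-terminus, D, E,
# C, Y) contribute -1/(1 + 10^(pKa - pH)). Terminal pKas are corrected
# for the identity of the terminal residue where Bjellqvist provides a
# specific value.
protein_charge_at_ph <- function(seq, ph) {
  seq <- toupper(seq)
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  counts <- table(factor(res, levels = .AA20))
  pk_n <- unname(.PKA_NTERM_BY_RESIDUE[res[1]])
  if (is.na(pk_n)) pk_n <- .PKA_POSITIVE[["Nterm"]]
  pk_c <- unname(.PKA_CTERM_BY_RESIDUE[res[n]])
  if (is.na(pk_c)) pk_c <- .PKA_NEGATIVE[["Cterm"]]

  pos_pks <- c(pk_n, .PKA_POSITIVE[c("K", "R", "H")])
  pos_n <- c(1, counts[c("K", "R", "H")])
  neg_pks <- c(pk_c, .PKA_NEGATIVE[c("D", "E", "C", "Y")])
  neg_n <- c(1, counts[c("D", "E", "C", "Y")])

  sum(pos_n / (1 + 10^(ph - pos_pks))) - sum(neg_n / (1 + 10^(neg_pks - ph)))
}

#' Theoretical isoelectric point
#'
#' The pH at which the net charge of the protein is zero under the
#' Bjellqvist charge model (the standard ExPASy-style calculation),
#' found by bisection on pH 0-14. The net charge is strictly decreasing
#' in pH, so the root is unique.
#'
#' @param seq Amino-acid string(s).
#' @param tolerance Bisection interval width at convergence (default
#'   0.001 pH units).
#' @return pH value(s).
#' @export
isoelectric_point <- function(seq, tolerance = 0.001) {
  vapply(toupper(seq), function(s) {
    if (nchar(s) == 0) {
      abort_circpep("Cannot compute the pI of an empty sequence.",
                    "circpep_input_error")
    }
    check_aa_alphabet(s)
    lo <- 0; hi <- 14
    while (hi - lo > tolerance) {
      mid <- (lo + hi) / 2
      if (protein_charge_at_ph(s, mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Instability index
#'
#' Guruprasad's dipeptide-weight statistic:
#' `II = (10 / L) * sum of DIWV over the L - 1 dipeptides`. Proteins with
#' `II < 40` are classified stable. Sequences of length 1 have no
#' dipeptides; their index is 0, with a warning.
#'
#' @param seq Amino-acid string(s).
#' @return Numeric instability index value(s); use `instability < 40`
#'   for the stable/unstable classification.
#' @export
instability_index <- function(seq) {
  vapply(toupper(seq), function(s) {
    if (nchar(s) == 0) {
      abort_circpep("Cannot compute the instability index of an empty sequence.",
                    "circpep_input_error")
    }
    check_aa_alphabet(s)
    L <- nchar(s)
    if (L < 2) {
      warning("Sequence of length 1 has no dipeptides; instability index 0.",
              call. = FALSE)
      return(0)
    }
    res <- strsplit(s, "")[[1]]
    (10 / L) * sum(.DIWV[cbind(res[-L], res[-1])])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues. Positive values
#' indicate hydrophobic proteins, negative values hydrophilic; the value
#' is bounded by the scale extremes \[-4.5, 4.5\].
#'
#' @param seq Amino-acid string(s).
#' @return GRAVY value(s).
#' @export
#' @examples
#' gravy("IV")  # (4.5 + 4.2) / 2
gravy <- function(seq) {
  vapply(toupper(seq), function(s) {
    if (nchar(s) == 0) {
      abort_circpep("Cannot compute GRAVY of an empty sequence.",
                    "circpep_input_error")
    }
    check_aa_alphabet(s)
    mean(.KYTE_DOOLITTLE[strsplit(s, "")[[1]]])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Physicochemical profile table
#'
#' @param proteins Tibble with `seq_id` and `seq` (amino-acid strings).
#' @param tryptic_len_range Length range for theoretical tryptic
#'   peptides (default `c(7, 35)`).
#' @return Tibble: `seq_id`, `length_aa`, `mw`, `pi`, `instability`,
#'   `stable` (instability < 40), `gravy`, `n_tryptic`.
#' @export
physchem_profile <- function(proteins, tryptic_len_range = c(7L, 35L)) {
  required_cols(proteins, c("seq_id", "seq"), "physchem_profile")
  seqs <- toupper(proteins$seq)
  ii <- instability_index(seqs)
  tibble::tibble(
    seq_id = proteins$seq_id,
    length_aa = nchar(seqs),
    mw = molecular_weight(seqs),
    pi = isoelectric_point(seqs),
    instability = ii,
    stable = ii < 40,
    gravy = gravy(seqs),
    n_tryptic = count_theoretical_peptides(seqs, tryptic_len_range)
  )
}

#' Compare CEP and LEP physicochemical profiles
#'
#' Length and theoretical tryptic-peptide counts are compared by
#' two-sample Kolmogorov-Smirnov tests; molecular weight and GRAVY by
#' Mann-Whitney U tests; stable/unstable proportions by a chi-square
#' test on the 2x2 table (no Yates correction by default). Direction
#' summaries are CEP minus LEP.
#'
#' @param ceps,leps Profile tibbles from [physchem_profile()] (each
#'   group needs at least 5 rows).
#' @param yates Apply the continuity correction to the chi-square test
#'   (default FALSE).
#' @return An object of class `cep_lep_comparison`; `tidy()` gives the
#'   per-metric test table, `glance()` a one-row summary, `autoplot()` a
#'   comparison figure.
#' @export
compare_physchem <- function(ceps, leps, yates = FALSE) {
  for (g in list(ceps, leps)) {
    required_cols(g, c("length_aa", "mw", "gravy", "stable", "n_tryptic"),
                  "compare_physchem")
  }
  if (nrow(ceps) < 5 || nrow(leps) < 5) {
    abort_circpep("Each group needs at least 5 profiles.",
                  "circpep_input_error")
  }
  if (dplyr::n_distinct(ceps$length_aa) < 2 &&
      dplyr::n_distinct(leps$length_aa) < 2 &&
      dplyr::n_distinct(c(ceps$length_aa, leps$length_aa)) < 2) {
    abort_circpep("Degenerate groups: all lengths identical.",
                  "circpep_input_error")
  }

  ks_row <- function(metric, a, b) {
    ks <- suppressWarnings(stats::ks.test(a, b))
    tibble::tibble(metric = metric, test = "Kolmogorov-Smirnov",
                   statistic = unname(ks$statistic), p_value = ks$p.value,
                   direction = stats::median(a) - stats::median(b))
  }
  mwu_row <- function(metric, a, b) {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    tibble::tibble(metric = metric, test = "Mann-Whitney U",
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   direction = stats::median(a) - stats::median(b))
  }
  stab_tab <- rbind(cep = table(factor(ceps$stable, levels = c(TRUE, FALSE))),
                    lep = table(factor(leps$stable, levels = c(TRUE, FALSE))))
  chi <- suppressWarnings(stats::chisq.test(stab_tab, correct = yates))
  chi_row <- tibble::tibble(
    metric = "stability", test = "chi-square",
    statistic = unname(chi$statistic), p_value = chi$p.value,
    direction = mean(ceps$stable) - mean(leps$stable)
  )

  tests <- dplyr::bind_rows(
    ks_row("length_aa", ceps$length_aa, leps$length_aa),
    mwu_row("mw", ceps$mw, leps$mw),
    ks_row("n_tryptic", ceps$n_tryptic, leps$n_tryptic),
    chi_row,
    mwu_row("gravy", ceps$gravy, leps$gravy)
  )
  structure(
    list(tests = tests, n_cep = nrow(ceps), n_lep = nrow(leps),
         stability_table = stab_tab, ceps = ceps, leps = leps),
    class = "cep_lep_comparison"
  )
}

#' @export
print.cep_lep_comparison <- function(x, ...) {
  cat(sprintf("CEP vs LEP physicochemical comparison (%d CEPs, %d LEPs)\n",
              x$n_cep, x$n_lep))
  print(x$tests)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cep_lep_comparison <- function(x, ...) x$tests

#' @export
glance.cep_lep_comparison <- function(x, ...) {
  wide <- stats::setNames(x$tests$p_value, paste0("p_", x$tests$metric))
  dplyr::bind_cols(
    tibble::tibble(n_cep = x$n_cep, n_lep = x$n_lep),
    tibble::as_tibble(as.list(wide))
  )
}
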