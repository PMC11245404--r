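# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_circpep <- function(msg, class) {
  rlang::abort(msg, class = c(class, "circpep_error"))
}

#' @noRd
assert_flag_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort_circpep(
      sprintf("`%s` must be a single integer >= %d.", name, min),
      "circpep_parameter_error"
    )
  }
  as.integer(x)
}

# Normalise a nucleotide sequence: uppercase, RNA U -> DNA T.
normalize_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

check_nt_alphabet <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- stringr::str_detect(x, pat)
  if (any(bad)) {
    abort_circpep(
      sprintf(
        "%s contains characters outside the %s alphabet (first offender: '%s').",
        what, if (allow_n) "A/C/G/T/N" else "A/C/G/T",
        x[which(bad)[1]]
      ),
      "circpep_alphabet_error"
    )
  }
  invisible(x)
}

check_aa_alphabet <- function(x, what = "protein sequence") {
  bad <- stringr::str_detect(toupper(x), "[^ACDEFGHIKLMNPQRSTVWY]")
  if (any(bad)) {
    abort_circpep(
      sprintf(
        "%s contains residues outside the 20-letter amino-acid alphabet (first offender: '%s'). Ambiguous residues (B, J, O, U, X, Z) are rejected.",
        what, x[which(bad)[1]]
      ),
      "circpep_alphabet_error"
    )
  }
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Rotate a circular sequence left by k: rotate("ABCDE", 1) == "BCDEA".
rotate_seq <- function(x, k) {
  n <- nchar(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  paste0(substr(x, k + 1L, n), substr(x, 1L, k))
}

random_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

required_cols <- function(df, cols, fn) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort_circpep(
      sprintf("`%s()` requires column(s) %s in its input data frame.",
              fn, paste0("`", miss, "`", collapse = ", ")),
      "circpep_input_error"
    )
  }
  invisible(df)
}
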