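# Junction-spanning ORF prediction on pseudo-circularised sequences.
#
# The circle is linearised by replicating the mature sequence `copies`
# times (default 4), ORFs are called from start codons whose first
# occurrence lies in the first copy, and only ORFs that cross the
# back-splice junction at least once are retained. Because the reading
# frame relative to the circle shifts at every wrap when L %% 3 != 0, an
# ORF that survives three full wraps without a stop can never terminate;
# four copies therefore suffice to distinguish terminating from
# rolling-circle (stop-less) ORFs.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Default start codon set: ATG plus the common near-cognate NTG starts.
#' @export
default_start_codons <- function() c("ATG", "CTG", "GTG", "TTG")

#' Pseudo-circularise a mature circRNA sequence
#'
#' @param mature_seq Character vector of mature circular sequences.
#' @param copies Number of tandem copies (default 4; must be >= 2).
#' @return The replicated sequence(s), length `copies * L`.
#' @export
#' @examples
#' pseudo_circularize("ACG")  # "ACGACGACGACG"
pseudo_circularize <- function(mature_seq, copies = 4L) {
  copies <- assert_flag_count(copies, "copies", min = 2L)
  if (any(nchar(mature_seq) == 0)) {
    abort_circpep("Cannot pseudo-circularise an empty sequence.",
                  "circpep_input_error")
  }
  strrep(normalize_nt(mature_seq), copies)
}

#' Find junction-spanning ORFs on circRNAs
#'
#' Scans the pseudo-circularised (`copies`-fold replicated) mature
#' sequence of each circRNA for ORFs that begin at a start codon in the
#' first copy and extend to the first in-frame stop. Only ORFs crossing
#' the back-splice junction at least once are retained. Within a frame,
#' calling begins at the 5'-most start codon before each stop, so of any
#' set of ORFs related by sequence inclusion only the longest is kept;
#' equal-length ORFs in different frames are all kept. ORFs with no stop
#' anywhere in the replicated sequence are truncated at its last complete
#' codon and flagged `stopless` (rolling-circle ORFs).
#'
#' @param circs A circRNA tibble with `mature_seq`.
#' @param start_codons Initiation codons (default [default_start_codons()]).
#' @param copies Pseudo-circularisation copies (default 4).
#'
#' @return A tibble with one row per retained ORF: `circ_id`, `start`
#'   (0-based circular position), `length_nt` (stop codon included when
#'   present), `start_codon`, `stopless`, `peptide` (stop excluded;
#'   initiator translated as M), `junction_residues` (list: peptide
#'   indices whose codon touches the junction boundary), `junction_spans`
#'   (list: residue intervals `(lo, hi)` such that a peptide substring
#'   covering `[lo, hi]` crosses the junction), and `wraps` (number of
#'   junction crossings).
#' @export
find_circ_orfs <- function(circs, start_codons = default_start_codons(),
                           copies = 4L) {
  validate_circs(circs, need_seq = TRUE)
  start_codons <- normalize_nt(start_codons)
  if (length(start_codons) == 0) {
    abort_circpep("`start_codons` must be non-empty.", "circpep_parameter_error")
  }
  check_nt_alphabet(start_codons, allow_n = FALSE, what = "start codon")
  if (any(nchar(start_codons) != 3)) {
    abort_circpep("Start codons must be 3-mers.", "circpep_parameter_error")
  }
  if (any(start_codons %in% STOP_CODONS)) {
    abort_circpep("Start codons cannot be stop codons.", "circpep_parameter_error")
  }
  copies <- assert_flag_count(copies, "copies", min = 2L)
  out <- purrr::map2(circs$circ_id, circs$mature_seq, find_orfs_one,
                     start_codons = start_codons, copies = copies)
  dplyr::bind_rows(out)
}

orf_columns <- function() {
  tibble::tibble(
    circ_id = character(), start = integer(), length_nt = integer(),
    start_codon = character(), stopless = logical(), peptide = character(),
    junction_residues = list(), junction_spans = list(), wraps = integer()
  )
}

find_orfs_one <- function(id, S, start_codons, copies) {
  L <- nchar(S)
  if (L < 3L) {
    warning(sprintf("circRNA '%s' is shorter than one codon (L=%d); no ORFs.",
                    id, L), call. = FALSE)
    return(orf_columns())
  }
  P <- strrep(S, copies)
  N <- copies * L

  first_copy_codons <- substring(P, 1:L, 3:(L + 2L))
  starts <- which(first_copy_codons %in% start_codons)
  if (length(starts) == 0) return(orf_columns())

  # in-frame stop codon start positions, per linear frame of P
  frame_stops <- lapply(0:2, function(f) {
    q <- seq(f + 1L, N - 2L, by = 3L)
    q[substring(P, q, q + 2L) %in% STOP_CODONS]
  })

  frame_of <- (starts - 1L) %% 3L
  nxt <- vapply(seq_along(starts), function(i) {
    fs <- frame_stops[[frame_of[i] + 1L]]
    fs[findInterval(starts[i] - 0.5, fs) + 1L]
  }, integer(1))
  stopless <- is.na(nxt)
  length_nt <- ifelse(stopless, 3L * ((N - starts + 1L) %/% 3L),
                      nxt + 3L - starts)
  end0 <- (starts - 1L) + length_nt - 1L
  wraps <- end0 %/% L
  keep <- wraps >= 1L
  if (!any(keep)) return(orf_columns())
  df <- tibble::tibble(
    start0 = starts[keep] - 1L, length_nt = as.integer(length_nt[keep]),
    stopless = stopless[keep], end0 = as.integer(end0[keep]),
    wraps = as.integer(wraps[keep])
  )
  # Longest-on-inclusion, evaluated on the circle: two terminating ORFs
  # are inclusion-related iff they end at the same circular stop codon
  # (ends congruent mod L), in which case the shorter is a suffix of the
  # longer; keep the longest per circular stop. Stop-less rolling-circle
  # ORFs have no intrinsic longest form (truncation is an artefact of the
  # linearisation), so every stop-less start is reported and flagged.
  df <- df |>
    dplyr::mutate(grp = ifelse(.data$stopless,
                               paste0("sl", dplyr::row_number()),
                               paste0("stop@", .data$end0 %% L))) |>
    dplyr::group_by(.data$grp) |>
    dplyr::slice_max(.data$length_nt, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$start0, .data$length_nt)

  orf_nt <- substring(P, df$start0 + 1L, df$start0 + df$length_nt)
  peptide <- vapply(orf_nt, translate_orf, character(1),
                    start_codons = start_codons, USE.NAMES = FALSE)
  geom <- purrr::pmap(
    list(df$start0, df$length_nt, df$stopless, df$wraps, nchar(peptide)),
    junction_geometry, L = L
  )
  tibble::tibble(
    circ_id = id,
    start = df$start0,
    length_nt = df$length_nt,
    start_codon = substring(P, df$start0 + 1L, df$start0 + 3L),
    stopless = df$stopless,
    peptide = peptide,
    junction_residues = purrr::map(geom, "residues"),
    junction_spans = purrr::map(geom, "spans"),
    wraps = df$wraps
  )
}

# Residue-level geometry of the junction crossings of one ORF.
# Base x (0-based on the replicated string) belongs to peptide residue
# (x - start0) %/% 3 + 1 when that index is within the peptide. For each
# crossing k, the junction lies between bases kL-1 and kL; the residues
# containing those bases are junction residues, and a peptide substring
# crosses the junction iff it covers the corresponding residue span.
junction_geometry <- function(start0, length_nt, stopless, wraps, npep, L) {
  residues <- integer()
  spans <- list()
  res_of <- function(x) {
    r <- (x - start0) %/% 3L + 1L
    if (r >= 1L && r <= npep) r else NA_integer_
  }
  for (k in seq_len(wraps)) {
    b <- k * L
    i1 <- res_of(b - 1L)
    i2 <- res_of(b)
    residues <- c(residues, i1[!is.na(i1)], i2[!is.na(i2)])
    if (!is.na(i1) && !is.na(i2)) {
      spans[[length(spans) + 1L]] <- c(i1, i2)
    }
  }
  list(residues = sort(unique(residues)), spans = spans)
}

#' Translate an ORF nucleotide sequence
#'
#' Standard genetic code; the initiator codon is translated as M when it
#' is one of `start_codons` (near-cognate initiation); a trailing stop is
#' excluded from the peptide.
#'
#' @param orf_nt Nucleotide sequence, length a multiple of 3.
#' @param start_codons Codons translated as M at position 1.
#' @return The amino-acid string.
#' @export
#' @examples
#' translate_orf("ATGGCTTAA")  # "MA"
#' translate_orf("CTGGCTTAA")  # "MA"
translate_orf <- function(orf_nt, start_codons = default_start_codons()) {
  orf_nt <- normalize_nt(orf_nt)
  n <- nchar(orf_nt)
  if (n == 0 || n %% 3L != 0L) {
    abort_circpep("ORF length must be a positive multiple of 3.",
                  "circpep_input_error")
  }
  idx <- seq(1L, n, by = 3L)
  codons <- substring(orf_nt, idx, idx + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    abort_circpep("ORF contains non-A/C/G/T characters.",
                  "circpep_alphabet_error")
  }
  if (codons[1] %in% start_codons) aa[1] <- "M"
  ncod <- length(aa)
  if (aa[ncod] == "*") aa <- aa[-ncod]
  if (any(aa == "*")) {
    abort_circpep("Internal stop codon before the final codon.",
                  "circpep_consistency_error")
  }
  paste(aa, collapse = "")
}

#' Build the circRNA-encoded protein (CEP) database
#'
#' One entry per distinct (circRNA, peptide) pair with peptide length
#' strictly greater than `min_peptide_len - 1` amino acids (the default
#' keeps peptides longer than 10 aa) and at least one junction residue.
#' Identical peptides predicted from different circRNAs are kept as
#' separate entries but cross-referenced through a shared
#' `ambiguity_group`.
#'
#' @param orfs Output of [find_circ_orfs()].
#' @param min_peptide_len Minimum peptide length kept (default 11).
#' @return A tibble with `entry_id`, `circ_id`, `peptide`,
#'   `junction_residues`, `junction_spans`, `provenance` ("predicted"),
#'   `ambiguity_group`, `shared`.
#' @export
build_cep_db <- function(orfs, min_peptide_len = 11L) {
  min_peptide_len <- assert_flag_count(min_peptide_len, "min_peptide_len")
  required_cols(orfs, c("circ_id", "start", "length_nt", "stopless",
                        "peptide", "junction_residues", "junction_spans"),
                "build_cep_db")
  db <- orfs |>
    dplyr::filter(nchar(.data$peptide) >= min_peptide_len,
                  lengths(.data$junction_residues) >= 1L) |>
    dplyr::distinct(.data$circ_id, .data$peptide, .keep_all = TRUE) |>
    dplyr::mutate(
      entry_id = paste(.data$circ_id, .data$start, .data$length_nt,
                       as.integer(.data$stopless), sep = "|"),
      provenance = "predicted"
    )
  db |>
    dplyr::group_by(.data$peptide) |>
    dplyr::mutate(ambiguity_group = dplyr::cur_group_id(),
                  shared = dplyr::n_distinct(.data$circ_id) > 1L) |>
    dplyr::ungroup() |>
    dplyr::select("entry_id", "circ_id", "peptide", "junction_residues",
                  "junction_spans", "provenance", "ambiguity_group", "shared")
}

#' Generate a length-matched random decoy pool
#'
#' One decoy per target entry, with identical length. Residues are drawn
#' with replacement from the pooled amino-acid frequencies of the target
#' database (or uniformly with `mode = "uniform"`). Decoys colliding with
#' any target peptide or canonical peptide are resampled up to 100 times.
#'
#' @param db Output of [build_cep_db()].
#' @param seed Integer seed; generation is fully reproducible.
#' @param canonical_peptides Optional character vector of canonical
#'   peptides the decoys must avoid.
#' @param mode `"frequency"` (default) or `"uniform"` residue sampling.
#' @return A tibble shaped like `db` with `provenance = "decoy"`.
#' @export
build_decoy_pool <- function(db, seed, canonical_peptides = character(),
                             mode = c("frequency", "uniform")) {
  mode <- match.arg(mode)
  required_cols(db, c("entry_id", "peptide"), "build_decoy_pool")
  if (nrow(db) == 0) {
    abort_circpep("Cannot build decoys from an empty target database.",
                  "circpep_input_error")
  }
  aa <- .AA20
  probs <- if (mode == "frequency") {
    counts <- table(factor(strsplit(paste(db$peptide, collapse = ""), "")[[1]],
                           levels = aa))
    as.numeric(counts) / sum(counts)
  } else {
    rep(1 / 20, 20)
  }
  forbidden <- unique(c(db$peptide, canonical_peptides))
  withr::with_seed(seed, {
    decoys <- vapply(nchar(db$peptide), function(len) {
      for (attempt in seq_len(100L)) {
        cand <- paste(sample(aa, len, replace = TRUE, prob = probs),
                      collapse = "")
        if (!cand %in% forbidden) return(cand)
      }
      abort_circpep(
        "Decoy resampling exhausted (degenerate target alphabet).",
        "circpep_degenerate_alphabet_error"
      )
    }, character(1))
  })
  tibble::tibble(
    entry_id = paste0("decoy|", seq_along(decoys)),
    circ_id = NA_character_,
    peptide = decoys,
    junction_residues = list(integer()),
    junction_spans = list(list()),
    provenance = "decoy",
    ambiguity_group = NA_integer_,
    shared = FALSE
  )
}
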