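# Peptide-level evidence for circRNA translation: in-silico tryptic
# digestion, the two-criterion junction-peptide definition (absent from
# the canonical proteome AND spanning the back-splice junction), and
# target-decoy FDR control at the peptide level only.

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P (the
#' Keil rule). With `missed_cleavages = m`, concatenations of up to
#' `m + 1` adjacent fully-cleaved fragments are also emitted, in order.
#'
#' @param protein Amino-acid string (20-letter alphabet).
#' @param missed_cleavages Number of allowed missed cleavages (default 0).
#' @return Character vector of peptides.
#' @export
#' @examples
#' digest_trypsin("AKRP")                 # "AK", "RP"
#' digest_trypsin("AKCK", missed_cleavages = 1)  # "AK", "AKCK", "CK"
digest_trypsin <- function(protein, missed_cleavages = 0L) {
  digest_trypsin_pos(protein, missed_cleavages)$peptide
}

# Digestion with residue coordinates (1-based, inclusive).
digest_trypsin_pos <- function(protein, missed_cleavages = 0L) {
  missed_cleavages <- assert_flag_count(missed_cleavages,
                                        "missed_cleavages", min = 0L)
  protein <- toupper(protein)
  check_aa_alphabet(protein)
  n <- nchar(protein)
  res <- strsplit(protein, "")[[1]]
  # cleavage after position i: residue i is K/R and residue i+1 is not P
  cut_after <- which(res[-n] %in% c("K", "R") & res[-1] != "P")
  bounds <- c(0L, cut_after, n)
  starts <- utils::head(bounds, -1) + 1L
  ends <- utils::tail(bounds, -1)
  frags <- tibble::tibble(start = starts, end = ends, n_missed = 0L)
  if (missed_cleavages > 0L && length(starts) > 1L) {
    extra <- purrr::map(seq_len(min(missed_cleavages, length(starts) - 1L)),
                        function(m) {
                          i <- seq_len(length(starts) - m)
                          tibble::tibble(start = starts[i], end = ends[i + m],
                                         n_missed = m)
                        })
    frags <- dplyr::bind_rows(frags, extra)
  }
  frags <- dplyr::arrange(frags, .data$start, .data$end)
  dplyr::mutate(frags,
                peptide = substring(protein, .data$start, .data$end),
                .before = 1L)
}

#' Count theoretical tryptic peptides of a protein
#'
#' Number of fully-cleaved tryptic peptides whose length falls in the
#' inclusive `len_range` (default 7-35 aa, the typical detectable range).
#'
#' @param protein Amino-acid string, or a character vector of proteins.
#' @param len_range Inclusive length range, `c(min, max)`.
#' @return Integer count(s).
#' @export
count_theoretical_peptides <- function(protein, len_range = c(7L, 35L)) {
  vapply(protein, function(p) {
    len <- nchar(digest_trypsin(p))
    sum(len >= len_range[1] & len <= len_range[2])
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify observed peptides against the canonical, CEP and decoy databases
#'
#' Classes, checked in order:
#' \describe{
#'   \item{canonical}{the peptide is a tryptic peptide of the canonical
#'     proteome (criterion (i) dominates: a canonical peptide is never
#'     circRNA evidence, even if it also matches the CEP database);}
#'   \item{decoy}{a substring of a random decoy entry;}
#'   \item{cep_junction}{a tryptic peptide of a CEP database entry whose
#'     span covers the back-splice junction;}
#'   \item{cep_nonjunction}{matches a CEP entry without covering the
#'     junction — recorded, but never counted as circRNA evidence;}
#'   \item{unmatched}{none of the above.}
#' }
#'
#' @param peptides Tibble with `pep_seq`, `score`, optional `sample`
#'   (see [peptide_ids()]).
#' @param cep_db Output of [build_cep_db()].
#' @param decoys Output of [build_decoy_pool()].
#' @param canonical Canonical proteome as a tibble with `seq_id`, `seq`
#'   (digested with the same settings), or a precomputed character vector
#'   of canonical tryptic peptides.
#' @param missed_cleavages Digestion setting shared by all databases
#'   (default 0).
#' @param canonical_mode `"tryptic"` (default; shotgun granularity) or
#'   `"substring"` (criterion (i) as plain substring containment).
#' @param il_equivalent Treat I and L as indistinguishable (default
#'   FALSE).
#' @return The peptide tibble with `class` and `matched_entries`
#'   (list-column of CEP entry ids the peptide is attributed to) added.
#' @export
classify_peptides <- function(peptides, cep_db, decoys, canonical,
                              missed_cleavages = 0L,
                              canonical_mode = c("tryptic", "substring"),
                              il_equivalent = FALSE) {
  canonical_mode <- match.arg(canonical_mode)
  required_cols(peptides, c("pep_seq", "score"), "classify_peptides")
  required_cols(cep_db, c("entry_id", "peptide", "junction_spans"),
                "classify_peptides")
  if (!"sample" %in% names(peptides)) peptides$sample <- "S1"

  norm <- if (il_equivalent) function(x) chartr("I", "L", x) else identity

  canon_seqs <- if (is.data.frame(canonical)) canonical$seq else canonical
  canon_peps <- if (is.data.frame(canonical) || canonical_mode == "tryptic") {
    unique(norm(unlist(lapply(
      canon_seqs, digest_trypsin, missed_cleavages = missed_cleavages
    ))))
  } else {
    norm(canon_seqs)
  }

  # fragment index over CEP entries: fragment string -> entry + coverage
  frag_index <- purrr::map2(cep_db$peptide, seq_len(nrow(cep_db)),
                            function(pep, i) {
    frags <- digest_trypsin_pos(pep, missed_cleavages)
    spans <- cep_db$junction_spans[[i]]
    covers <- vapply(seq_len(nrow(frags)), function(j) {
      any(vapply(spans, function(sp) {
        frags$start[j] <= sp[1] && frags$end[j] >= sp[2]
      }, logical(1)))
    }, logical(1))
    tibble::tibble(frag = norm(frags$peptide),
                   entry_id = cep_db$entry_id[i],
                   covers_junction = covers)
  }) |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$frag, .data$entry_id) |>
    dplyr::summarise(covers_junction = any(.data$covers_junction),
                     .groups = "drop")

  decoy_peps <- norm(decoys$peptide)

  q <- norm(toupper(peptides$pep_seq))
  is_canon <- if (canonical_mode == "substring" && !is.data.frame(canonical)) {
    vapply(q, function(p) any(stringr::str_detect(canon_peps,
                                                  stringr::fixed(p))),
           logical(1), USE.NAMES = FALSE)
  } else {
    q %in% canon_peps
  }
  is_decoy <- vapply(q, function(p) {
    any(stringr::str_detect(decoy_peps, stringr::fixed(p)))
  }, logical(1), USE.NAMES = FALSE)

  matches <- lapply(q, function(p) {
    frag_index[frag_index$frag == p, , drop = FALSE]
  })

  class <- character(length(q))
  matched_entries <- vector("list", length(q))
  for (i in seq_along(q)) {
    m <- matches[[i]]
    if (is_canon[i]) {
      class[i] <- "canonical"
      matched_entries[[i]] <- character()
    } else if (is_decoy[i]) {
      class[i] <- "decoy"
      matched_entries[[i]] <- character()
    } else if (nrow(m) > 0 && any(m$covers_junction)) {
      class[i] <- "cep_junction"
      matched_entries[[i]] <- m$entry_id[m$covers_junction]
    } else if (nrow(m) > 0) {
      class[i] <- "cep_nonjunction"
      matched_entries[[i]] <- m$entry_id
    } else {
      class[i] <- "unmatched"
      matched_entries[[i]] <- character()
    }
  }
  dplyr::mutate(peptides, class = class,
                matched_entries = matched_entries)
}

#' Target-decoy FDR control at the peptide level
#'
#' For a score threshold s, `FDR(s) = (1 + #(decoy matches >= s)) /
#' max(1, #(junction targets >= s))` by default; q-values are the running
#' minimum of FDR over all thresholds admitting the peptide, so they are
#' non-increasing in score. Targets with `q <= alpha` are accepted. No
#' protein-level FDR is applied: short CEPs yield few theoretical
#' peptides, which makes a protein FDR overconservative, so the procedure
#' stops at the peptide level by design.
#'
#' The `+1` in the numerator (`correction = "plus1"`) makes the estimate
#' conservative: without it, a single top-scoring target is assigned
#' FDR 0 and the procedure accepts a false peptide in about half of all
#' null datasets. The uncorrected decoy/target ratio is available with
#' `correction = "none"`.
#'
#' @param evidence Output of [classify_peptides()] (must contain
#'   `cep_junction` targets and `decoy` matches).
#' @param alpha Peptide FDR threshold (default 0.05).
#' @param pool `"sample"` (default: FDR controlled within each sample) or
#'   `"all"` (samples pooled).
#' @param correction `"plus1"` (default, conservative) or `"none"`.
#' @return `evidence` with `q_value` (targets and decoys; NA for other
#'   classes) and logical `accepted` columns.
#' @export
target_decoy_fdr <- function(evidence, alpha = 0.05,
                             pool = c("sample", "all"),
                             correction = c("plus1", "none")) {
  pool <- match.arg(pool)
  correction <- match.arg(correction)
  pseudo <- if (correction == "plus1") 1L else 0L
  required_cols(evidence, c("pep_seq", "score", "class"), "target_decoy_fdr")
  if (!any(evidence$class == "decoy")) {
    abort_circpep("No decoy matches present: FDR is undefined.",
                  "circpep_input_error")
  }
  if (!"sample" %in% names(evidence)) evidence$sample <- "S1"
  grp <- if (pool == "sample") evidence$sample else rep("all", nrow(evidence))

  evidence$q_value <- NA_real_
  for (g in unique(grp)) {
    idx <- which(grp == g)
    cls <- evidence$class[idx]
    sc <- evidence$score[idx]
    t_scores <- sc[cls == "cep_junction"]
    d_scores <- sc[cls == "decoy"]
    if (length(t_scores) == 0) next
    thresholds <- sort(unique(c(t_scores, d_scores)), decreasing = TRUE)
    fdr <- vapply(thresholds, function(s) {
      (pseudo + sum(d_scores >= s)) / max(1L, sum(t_scores >= s))
    }, numeric(1))
    qv <- rev(cummin(rev(fdr)))
    lookup <- function(scores) qv[match(scores, thresholds)]
    evidence$q_value[idx[cls == "cep_junction"]] <- lookup(t_scores)
    evidence$q_value[idx[cls == "decoy"]] <- lookup(d_scores)
  }
  dplyr::mutate(evidence,
                accepted = .data$class == "cep_junction" &
                  !is.na(.data$q_value) & .data$q_value <= alpha)
}

#' Summarise accepted peptides into MS-supported circRNAs
#'
#' A circRNA is MS-supported when at least one accepted junction peptide
#' attributes to one of its CEP database entries. Peptides in ambiguity
#' groups attribute to every member circRNA and are flagged shared;
#' unique- and shared-peptide counts are reported separately.
#'
#' @param evidence Output of [target_decoy_fdr()] (uses `accepted` rows;
#'   a tibble of already-accepted `cep_junction` evidence also works).
#' @param cep_db Output of [build_cep_db()].
#' @return Tibble: `circ_id`, `n_peptides_unique`, `n_peptides_shared`,
#'   `ms_supported`.
#' @export
summarize_coding_circs <- function(evidence, cep_db) {
  required_cols(evidence, c("pep_seq", "class", "matched_entries"),
                "summarize_coding_circs")
  required_cols(cep_db, c("entry_id", "circ_id"), "summarize_coding_circs")
  acc <- if ("accepted" %in% names(evidence)) {
    evidence[evidence$accepted, , drop = FALSE]
  } else {
    evidence[evidence$class == "cep_junction", , drop = FALSE]
  }
  empty <- tibble::tibble(circ_id = character(),
                          n_peptides_unique = integer(),
                          n_peptides_shared = integer(),
                          ms_supported = logical())
  if (nrow(acc) == 0) return(empty)
  long <- acc |>
    dplyr::transmute(.data$pep_seq, entry_id = .data$matched_entries) |>
    tidyr::unnest("entry_id") |>
    dplyr::inner_join(cep_db[, c("entry_id", "circ_id")], by = "entry_id") |>
    dplyr::distinct(.data$pep_seq, .data$circ_id)
  if (nrow(long) == 0) return(empty)
  long <- long |>
    dplyr::group_by(.data$pep_seq) |>
    dplyr::mutate(shared = dplyr::n_distinct(.data$circ_id) > 1L) |>
    dplyr::ungroup()
  long |>
    dplyr::group_by(.data$circ_id) |>
    dplyr::summarise(
      n_peptides_unique = dplyr::n_distinct(.data$pep_seq[!.data$shared]),
      n_peptides_shared = dplyr::n_distinct(.data$pep_seq[.data$shared]),
      .groups = "drop"
    ) |>
    dplyr::mutate(ms_supported = TRUE)
}
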