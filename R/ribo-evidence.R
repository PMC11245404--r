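# Ribosome-footprint evidence at back-splice junctions.
#
# Reads are matched into the 2*flank junction windows by substitution-only
# (Hamming) alignment at every offset that crosses the junction boundary;
# gapped alignment is unnecessary at window scale. `N` positions never
# match, in either the read or the window.

#' Match footprint reads to junction windows
#'
#' A hit is reported wherever a read aligns within a window with at most
#' `max_mismatch` substitutions (no indels) and strictly crosses the
#' junction boundary (at least one aligned base on each side). A read may
#' hit several windows; all hits are reported. Reads longer than a window
#' are skipped for that window and counted in the `n_skipped_long`
#' attribute.
#'
#' Callers are expected to supply reads that failed to map to the linear
#' genome/transcriptome; record whether that upstream filter was applied
#' with `linear_unmapped`.
#'
#' @param reads Tibble with `read_id`, `seq` (see [ribo_reads()]).
#' @param windows Output of [junction_windows()].
#' @param max_mismatch Maximum substitutions allowed (default 0).
#' @param linear_unmapped Logical provenance flag recorded on the result:
#'   were these reads pre-filtered against the linear reference?
#'
#' @return Tibble of junction hits: `read_id`, `circ_id`, `window_offset`
#'   (0-based start of the alignment within the window), `overhang5`,
#'   `overhang3` (bases on the 5'/3' side of the junction; both >= 1 by
#'   construction), `mismatches`. Attributes: `n_skipped_long`,
#'   `linear_unmapped`.
#' @export
match_reads_to_junctions <- function(reads, windows, max_mismatch = 0L,
                                     linear_unmapped = NA) {
  required_cols(reads, c("read_id", "seq"), "match_reads_to_junctions")
  required_cols(windows, c("circ_id", "window_seq", "junction_offset"),
                "match_reads_to_junctions")
  max_mismatch <- assert_flag_count(max_mismatch, "max_mismatch", min = 0L)

  read_len <- nchar(reads$seq)
  n_raw <- charToRaw("N")
  # group reads by length; one m x n byte matrix per length lets every
  # window offset be scored against all same-length reads in one
  # vectorised comparison
  groups <- split(seq_len(nrow(reads)), read_len)
  group_mat <- lapply(groups, function(idx) {
    m <- matrix(unlist(lapply(reads$seq[idx], charToRaw)),
                nrow = read_len[idx[1]])
    list(idx = idx, bytes = m, n_mask = m == n_raw)
  })
  n_skipped <- 0L
  hits <- vector("list", nrow(windows))

  for (w in seq_len(nrow(windows))) {
    wraw <- charToRaw(windows$window_seq[w])
    wlen <- length(wraw)
    jo <- windows$junction_offset[w]  # 1-based index of last base before junction
    wn <- wraw == n_raw
    wrows <- list()
    for (g in group_mat) {
      m <- nrow(g$bytes)
      if (m > wlen) {
        n_skipped <- n_skipped + length(g$idx)
        next
      }
      # 1-based offsets whose alignment covers bases jo and jo+1
      o_min <- max(1L, jo - m + 2L)
      o_max <- min(jo, wlen - m + 1L)
      if (o_min > o_max) next
      for (o in o_min:o_max) {
        span <- o:(o + m - 1L)
        mm <- colSums(g$bytes != wraw[span] | g$n_mask | wn[span])
        ok <- which(mm <= max_mismatch)
        if (length(ok)) {
          wrows[[length(wrows) + 1L]] <-
            cbind(r = g$idx[ok], o = o, mm = mm[ok])
        }
      }
    }
    if (length(wrows)) {
      mat <- do.call(rbind, wrows)
      hits[[w]] <- tibble::tibble(
        read_id = reads$read_id[mat[, "r"]],
        circ_id = windows$circ_id[w],
        window_offset = as.integer(mat[, "o"] - 1L),
        overhang5 = as.integer(jo - mat[, "o"] + 1L),
        overhang3 = as.integer(mat[, "o"] + read_len[mat[, "r"]] - 1L - jo),
        mismatches = as.integer(mat[, "mm"])
      )
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) > 0) {
    out <- dplyr::arrange(out, match(.data$circ_id, windows$circ_id),
                          match(.data$read_id, reads$read_id),
                          .data$window_offset)
  }
  if (nrow(out) == 0) {
    out <- tibble::tibble(read_id = character(), circ_id = character(),
                          window_offset = integer(), overhang5 = integer(),
                          overhang3 = integer(), mismatches = integer())
  }
  attr(out, "n_skipped_long") <- n_skipped
  attr(out, "linear_unmapped") <- linear_unmapped
  out
}

#' Collapse junction hits to unique reads
#'
#' Per junction, hits are collapsed by identical read sequence ("unique
#' reads"); one representative is kept and the collapse count recorded.
#' With `by = "offset"`, distinct alignment offsets define uniqueness
#' instead.
#'
#' @param hits Output of [match_reads_to_junctions()].
#' @param reads The read tibble the hits came from (for sequences).
#' @param by `"sequence"` (default) or `"offset"`.
#' @return The collapsed hit tibble with an `n_collapsed` column.
#' @export
dedupe_unique <- function(hits, reads, by = c("sequence", "offset")) {
  by <- match.arg(by)
  required_cols(hits, c("read_id", "circ_id", "window_offset",
                        "overhang5", "overhang3"), "dedupe_unique")
  if (nrow(hits) == 0) return(dplyr::mutate(hits, n_collapsed = integer()))
  if (by == "sequence") {
    required_cols(reads, c("read_id", "seq"), "dedupe_unique")
    hits <- dplyr::left_join(hits, reads[, c("read_id", "seq")], by = "read_id")
    key <- c("circ_id", "seq")
  } else {
    key <- c("circ_id", "window_offset", "overhang5")
  }
  out <- hits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::mutate(n_collapsed = dplyr::n()) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  out[, c(setdiff(names(hits), "seq"), "n_collapsed")]
}

#' Call ribosome-associated circRNAs
#'
#' A unique hit is eligible when it overhangs the junction by at least
#' `min_overhang` nucleotides on both sides; a circRNA is called
#' ribosome-associated when its junction carries at least `min_unique`
#' eligible unique reads (defaults: 2 unique reads, 4-nt overhang).
#'
#' @param hits Deduplicated hits (see [dedupe_unique()]).
#' @param min_unique Minimum eligible unique reads (default 2).
#' @param min_overhang Minimum overhang on each side, nt (default 4).
#' @param circ_ids Optional character vector: circRNAs to report even
#'   when they collected no hits.
#' @return Tibble: `circ_id`, `n_hits`, `n_unique_eligible`,
#'   `ribosome_associated`.
#' @export
call_ribosome_associated <- function(hits, min_unique = 2L, min_overhang = 4L,
                                     circ_ids = NULL) {
  min_unique <- assert_flag_count(min_unique, "min_unique")
  min_overhang <- assert_flag_count(min_overhang, "min_overhang")
  required_cols(hits, c("circ_id", "overhang5", "overhang3"),
                "call_ribosome_associated")
  summ <- hits |>
    dplyr::group_by(.data$circ_id) |>
    dplyr::summarise(
      n_hits = dplyr::n(),
      n_unique_eligible = sum(pmin(.data$overhang5, .data$overhang3) >=
                                min_overhang),
      .groups = "drop"
    )
  if (!is.null(circ_ids)) {
    summ <- dplyr::left_join(tibble::tibble(circ_id = circ_ids), summ,
                             by = "circ_id") |>
      tidyr::replace_na(list(n_hits = 0L, n_unique_eligible = 0L))
  }
  dplyr::mutate(summ,
                ribosome_associated = .data$n_unique_eligible >= min_unique)
}

#' Flag candidate circRNAs by RNA-seq back-splice support
#'
#' A circRNA is a candidate when its back-splice junction is supported by
#' at least `min_reads` independent (deduplicated) reads. Input is either
#' a junction-hit tibble from [match_reads_to_junctions()] (hits are
#' collapsed by read sequence first) or a precomputed count table with
#' columns `circ_id`, `n_bsj_reads`.
#'
#' @param rna Hits tibble (with `read_id`) or counts tibble.
#' @param min_reads Support threshold (default 2).
#' @param reads Read tibble, required when `rna` is a hit tibble.
#' @param circ_ids Optional circRNAs to report even with zero support.
#' @return Tibble: `circ_id`, `n_bsj_reads`, `candidate`.
#' @export
rna_junction_support <- function(rna, min_reads = 2L, reads = NULL,
                                 circ_ids = NULL) {
  min_reads <- assert_flag_count(min_reads, "min_reads")
  if ("n_bsj_reads" %in% names(rna)) {
    counts <- rna[, c("circ_id", "n_bsj_reads")]
  } else {
    required_cols(rna, c("read_id", "circ_id"), "rna_junction_support")
    deduped <- dedupe_unique(rna, reads)
    counts <- deduped |>
      dplyr::count(.data$circ_id, name = "n_bsj_reads")
  }
  if (!is.null(circ_ids)) {
    counts <- dplyr::left_join(tibble::tibble(circ_id = circ_ids), counts,
                               by = "circ_id") |>
      tidyr::replace_na(list(n_bsj_reads = 0L))
  }
  dplyr::mutate(counts, candidate = .data$n_bsj_reads >= min_reads)
}

#' Footprint read-length histogram
#'
#' Exact counts per read length, plus the fraction of reads inside the
#' expected footprint range (default 25-35 nt).
#'
#' @param reads Tibble with `seq`.
#' @param range Inclusive footprint length range (default `c(25, 35)`).
#' @return Tibble `length`, `n`, `fraction`; attributes
#'   `fraction_in_range` (NA for empty input) and `modal_length`.
#' @export
read_length_histogram <- function(reads, range = c(25L, 35L)) {
  required_cols(reads, "seq", "read_length_histogram")
  len <- nchar(reads$seq)
  out <- tibble::tibble(length = len) |>
    dplyr::count(.data$length, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  attr(out, "fraction_in_range") <-
    if (length(len) == 0) NA_real_
    else mean(len >= range[1] & len <= range[2])
  attr(out, "modal_length") <-
    if (nrow(out) == 0) NA_integer_ else out$length[which.max(out$n)]
  out
}

#' Three-nucleotide periodicity of footprint 5' ends
#'
#' Fractions of 5'-end offsets (relative to annotated ORF starts of
#' linear CDS controls) in each frame class mod 3.
#'
#' @param offsets Integer vector of 5'-end offsets.
#' @return Tibble `frame` (0/1/2), `n`, `fraction`; fractions sum to 1.
#' @export
frame_periodicity <- function(offsets) {
  if (length(offsets) == 0 || !is.numeric(offsets)) {
    abort_circpep("`offsets` must be a non-empty numeric vector.",
                  "circpep_input_error")
  }
  fr <- factor(((offsets %% 3) + 3) %% 3, levels = 0:2)
  tab <- table(fr)
  tibble::tibble(
    frame = 0:2,
    n = as.integer(tab),
    fraction = as.integer(tab) / sum(tab)
  )
}
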