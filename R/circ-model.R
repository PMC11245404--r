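#' Assemble a circRNA table
#'
#' Builds the tibble that every downstream stage consumes: one row per
#' circRNA, with exon blocks in 0-based half-open genomic coordinates and
#' (optionally) the strand-resolved mature circular sequence. The
#' back-splice junction always lies between the last and the first base of
#' `mature_seq`.
#'
#' @param circ_id Character vector of unique circRNA identifiers.
#' @param chrom Chromosome name per circRNA.
#' @param strand `"+"` or `"-"` per circRNA.
#' @param exon_starts,exon_ends Lists of integer vectors: per circRNA, the
#'   0-based starts and half-open ends of its exon blocks, sorted by start
#'   and non-overlapping.
#' @param mature_seq Optional mature circular sequence (A/C/G/T/N; U is
#'   converted to T). Use [build_mature_sequence()] to derive it from a
#'   genome.
#' @param host_gene Optional host gene symbol.
#'
#' @return A tibble of class data (one row per circRNA) with columns
#'   `circ_id`, `chrom`, `strand`, `exon_starts`, `exon_ends`,
#'   `mature_seq`, `host_gene`.
#' @export
#' @examples
#' circ_tbl("circ1", "chr1", "+", list(c(0L, 6L)), list(c(3L, 9L)))
circ_tbl <- function(circ_id, chrom = NA_character_, strand = "+",
                     exon_starts = list(integer()), exon_ends = list(integer()),
                     mature_seq = NA_character_, host_gene = NA_character_) {
  circs <- tibble::tibble(
    circ_id = as.character(circ_id),
    chrom = chrom,
    strand = strand,
    exon_starts = exon_starts,
    exon_ends = exon_ends,
    mature_seq = ifelse(is.na(mature_seq), NA_character_,
                        normalize_nt(mature_seq)),
    host_gene = host_gene
  )
  validate_circs(circs)
}

validate_circs <- function(circs, need_seq = FALSE) {
  required_cols(circs, c("circ_id", "strand"), "circ_tbl")
  if (anyDuplicated(circs$circ_id)) {
    abort_circpep("`circ_id` values must be unique.", "circpep_input_error")
  }
  if (!all(circs$strand %in% c("+", "-"))) {
    abort_circpep("`strand` must be '+' or '-'.", "circpep_input_error")
  }
  if (all(c("exon_starts", "exon_ends") %in% names(circs))) {
    ok <- purrr::map2_lgl(circs$exon_starts, circs$exon_ends, function(s, e) {
      if (length(s) != length(e)) return(FALSE)
      if (length(s) == 0) return(TRUE)
      all(e > s) && !is.unsorted(s, strictly = TRUE) &&
        all(utils::head(e, -1) <= utils::tail(s, -1))
    })
    if (!all(ok)) {
      abort_circpep(
        "Exon blocks must be sorted by start, non-overlapping, with end > start.",
        "circpep_coordinate_error"
      )
    }
  }
  if (need_seq) {
    if (!"mature_seq" %in% names(circs) || anyNA(circs$mature_seq)) {
      abort_circpep(
        "This operation needs `mature_seq`; run `build_mature_sequence()` first.",
        "circpep_input_error"
      )
    }
    check_nt_alphabet(circs$mature_seq, allow_n = TRUE, what = "mature_seq")
    if (any(nchar(circs$mature_seq) < 1)) {
      abort_circpep("`mature_seq` must have length >= 1.", "circpep_input_error")
    }
  }
  circs
}

#' Splice mature circular sequences from a genome
#'
#' Concatenates the exon blocks of each circRNA in genomic order and
#' reverse-complements the result for minus-strand circles, yielding the
#' mature circular sequence whose last base is joined back to its first
#' base at the back-splice junction. `N` bases are permitted and flagged;
#' they never match motifs or reads downstream.
#'
#' @param circs A circRNA tibble (see [circ_tbl()]).
#' @param genome Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#'
#' @return `circs` with `mature_seq` filled in and a logical `has_n`
#'   column flagging sequences containing ambiguous bases.
#' @export
build_mature_sequence <- function(circs, genome) {
  validate_circs(circs)
  genome <- as_genome_chr(genome)
  seqs <- purrr::pmap_chr(
    list(circs$circ_id, circs$chrom, circs$strand,
         circs$exon_starts, circs$exon_ends),
    function(id, chrom, strand, starts, ends) {
      if (is.na(chrom) || !chrom %in% names(genome)) {
        abort_circpep(
          sprintf("circRNA '%s': chromosome '%s' not present in the genome.",
                  id, chrom),
          "circpep_coordinate_error"
        )
      }
      chrom_seq <- genome[[chrom]]
      clen <- nchar(chrom_seq)
      if (length(starts) == 0) {
        abort_circpep(sprintf("circRNA '%s' has no exon blocks.", id),
                      "circpep_input_error")
      }
      if (any(starts < 0) || any(ends > clen)) {
        abort_circpep(
          sprintf("circRNA '%s': exon block outside chromosome '%s' (length %d).",
                  id, chrom, clen),
          "circpep_coordinate_error"
        )
      }
      spliced <- paste(substring(chrom_seq, starts + 1L, ends), collapse = "")
      if (strand == "-") spliced <- revcomp(spliced)
      spliced
    }
  )
  check_nt_alphabet(seqs, allow_n = TRUE, what = "spliced mature sequence")
  dplyr::mutate(circs,
                mature_seq = seqs,
                has_n = stringr::str_detect(seqs, "N"))
}

as_genome_chr <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome))) {
    abort_circpep(
      "`genome` must be a named character vector, DNAStringSet, or FASTA path.",
      "circpep_input_error"
    )
  }
  # headers like "chr1 description" -> "chr1"
  names(genome) <- sub("\\s.*$", "", names(genome))
  vapply(genome, normalize_nt, character(1))
}

#' Build back-splice junction windows
#'
#' For each circRNA, concatenates the last `flank` nucleotides of the
#' mature sequence with its first `flank` nucleotides, so that a read
#' crossing the window midpoint is a read crossing the back-splice
#' junction. For circles shorter than `flank`, both sides use the whole
#' sequence (window length `2 * L`) and `short_circle` is set.
#'
#' @param circs A circRNA tibble with `mature_seq`.
#' @param flank Nucleotides taken on each side of the junction (default
#'   25, i.e. the 25 bp upstream and downstream of the back-spliced site).
#'
#' @return A tibble with one row per circRNA: `circ_id`, `window_seq`,
#'   `junction_offset` (0-based index of the first base after the
#'   junction within `window_seq`), `flank`, `short_circle`.
#' @export
#' @examples
#' circs <- circ_tbl("c1", mature_seq = "AAAATTTT")
#' junction_windows(circs, flank = 4)
junction_windows <- function(circs, flank = 25L) {
  flank <- assert_flag_count(flank, "flank", min = 1L)
  validate_circs(circs, need_seq = TRUE)
  L <- nchar(circs$mature_seq)
  f <- pmin(flank, L)
  tibble::tibble(
    circ_id = circs$circ_id,
    window_seq = paste0(
      substring(circs$mature_seq, L - f + 1L, L),
      substring(circs$mature_seq, 1L, f)
    ),
    junction_offset = f,
    flank = flank,
    short_circle = L < flank
  )
}

#' Count RRACH motif occurrences on the circle
#'
#' Scans the mature circular sequence for the m6A consensus motif RRACH
#' (R = A/G, H = A/C/T), counting every circular start position once —
#' motifs wrapping across the back-splice junction are included. `N`
#' bases never match.
#'
#' @param circs A circRNA tibble with `mature_seq`.
#' @return `circs` with an integer `n_rrach` column appended.
#' @export
#' @examples
#' scan_rrach(circ_tbl("c1", mature_seq = "GGACC"))$n_rrach  # 1
scan_rrach <- function(circs) {
  validate_circs(circs, need_seq = TRUE)
  dplyr::mutate(circs, n_rrach = vapply(.data$mature_seq, count_rrach_circular,
                                        integer(1), USE.NAMES = FALSE))
}

count_rrach_circular <- function(seq) {
  L <- nchar(seq)
  if (L < 1) abort_circpep("Empty sequence.", "circpep_input_error")
  # extend so every circular 5-mer starting at p in [1, L] is linear
  reps <- ceiling((L + 4) / L)
  ext <- substr(strrep(seq, reps), 1L, L + 4L)
  hits <- gregexpr("(?=[AG][AG]AC[ACT])", ext, perl = TRUE)[[1]]
  if (hits[1] == -1) return(0L)
  sum(hits <= L)
}
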