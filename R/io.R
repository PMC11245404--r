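# Readers and writers for the standard formats the pipeline touches.
# All sequence I/O goes through Biostrings; tables go through readr.

#' Read a genome FASTA into a named character vector
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named character vector of uppercase DNA sequences (U converted
#'   to T); names are truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(x), normalize_nt, character(1))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read mature circular sequences from FASTA
#'
#' Headers carry the circRNA id (up to the first whitespace or `|`).
#'
#' @param path FASTA path.
#' @return A circRNA tibble with `circ_id` and `mature_seq`.
#' @export
read_circ_fasta <- function(path) {
  x <- read_genome_fasta(path)
  ids <- sub("\\|.*$", "", names(x))
  circ_tbl(circ_id = ids, mature_seq = unname(x))
}

#' Read circRNA exon models from a BED12 file
#'
#' Uses `blockCount`/`blockSizes`/`blockStarts` to reconstruct exon
#' blocks in 0-based half-open genomic coordinates.
#'
#' @param path BED12 path (tab-separated, no header).
#' @return A circRNA tibble (without `mature_seq`).
#' @export
read_circ_bed12 <- function(path) {
  bed <- readr::read_tsv(
    path, col_names = FALSE, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(bed) < 12) {
    abort_circpep("BED12 input needs 12 columns.", "circpep_input_error")
  }
  chrom_start <- as.integer(bed$X2)
  sizes <- purrr::map(strsplit(bed$X11, ","), as.integer)
  starts <- purrr::map(strsplit(bed$X12, ","), as.integer)
  n_blocks <- as.integer(bed$X10)
  ok <- purrr::pmap_lgl(list(sizes, starts, n_blocks),
                        function(s, st, n) length(s) == n && length(st) == n)
  if (!all(ok)) {
    abort_circpep("blockSizes/blockStarts disagree with blockCount.",
                  "circpep_input_error")
  }
  circ_tbl(
    circ_id = bed$X4,
    chrom = bed$X1,
    strand = bed$X6,
    exon_starts = purrr::map2(starts, chrom_start, `+`),
    exon_ends = purrr::pmap(list(starts, sizes, chrom_start),
                            function(st, s, cs) st + s + cs)
  )
}

#' Write circRNA exon models to BED12
#'
#' @param circs A circRNA tibble with exon blocks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circ_bed12 <- function(circs, path) {
  validate_circs(circs)
  lines <- purrr::pmap_chr(
    list(circs$circ_id, circs$chrom, circs$strand,
         circs$exon_starts, circs$exon_ends),
    function(id, chrom, strand, s, e) {
      paste(chrom, min(s), max(e), id, 0L, strand, min(s), max(e), "0",
            length(s),
            paste0(paste(e - s, collapse = ","), ","),
            paste0(paste(s - min(s), collapse = ","), ","),
            sep = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector (nucleotide or amino acid).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Export junction windows as FASTA
#'
#' Headers have the form `circ_id|junction_offset`.
#'
#' @param windows Output of [junction_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_fasta <- function(windows, path) {
  required_cols(windows, c("circ_id", "window_seq", "junction_offset"),
                "write_window_fasta")
  seqs <- stats::setNames(
    windows$window_seq,
    paste(windows$circ_id, windows$junction_offset, sep = "|")
  )
  write_fasta(seqs, path)
}

#' Export a CEP (or decoy) database as FASTA
#'
#' Headers have the form `entry_id circ_id|provenance`.
#'
#' @param db Output of [build_cep_db()] or [build_decoy_pool()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cep_fasta <- function(db, path) {
  required_cols(db, c("entry_id", "circ_id", "peptide", "provenance"),
                "write_cep_fasta")
  seqs <- stats::setNames(
    db$peptide,
    paste0(db$entry_id, " ", db$circ_id, "|", db$provenance)
  )
  write_fasta(seqs, path)
}

#' Read footprint reads from FASTA or FASTQ
#'
#' Reads shorter than `min_len` are rejected at ingest and counted in the
#' `n_rejected_short` attribute of the result.
#'
#' @param path FASTA or FASTQ path (format sniffed from the first byte).
#' @param min_len Minimum read length retained (default 15).
#' @return Tibble with `read_id`, `seq`; attribute `n_rejected_short`.
#' @export
read_reads <- function(path, min_len = 15L) {
  first <- readChar(path, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  reads <- tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = normalize_nt(as.character(x))
  )
  ribo_reads(reads, min_len = min_len)
}

#' Validate and ingest a read table
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param min_len Minimum read length retained (default 15).
#' @return The filtered tibble; attribute `n_rejected_short` records how
#'   many reads were dropped.
#' @export
ribo_reads <- function(reads, min_len = 15L) {
  required_cols(reads, c("read_id", "seq"), "ribo_reads")
  reads$seq <- normalize_nt(reads$seq)
  check_nt_alphabet(reads$seq, allow_n = TRUE, what = "read sequence")
  keep <- nchar(reads$seq) >= min_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_rejected_short") <- sum(!keep)
  out
}

#' Write reads as FASTQ (constant quality)
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  required_cols(reads, c("read_id", "seq"), "write_reads_fastq")
  lines <- rbind(paste0("@", reads$read_id), reads$seq, "+",
                 strrep("I", nchar(reads$seq)))
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Read peptide identifications from TSV
#'
#' Expects columns `pep_seq`, `score`, and optionally `sample`.
#' Identifications shorter than `min_len` amino acids are rejected at
#' ingest and counted in the `n_rejected_short` attribute.
#'
#' @param path TSV path with a header row.
#' @param min_len Minimum peptide length retained (default 6).
#' @return Tibble with `pep_seq`, `score`, `sample`.
#' @export
read_peptides_tsv <- function(path, min_len = 6L) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  peptide_ids(x, min_len = min_len)
}

#' Validate and ingest peptide identifications
#'
#' @param peptides Tibble with `pep_seq`, `score`, optional `sample`.
#' @param min_len Minimum peptide length retained (default 6).
#' @return The filtered tibble; attribute `n_rejected_short`.
#' @export
peptide_ids <- function(peptides, min_len = 6L) {
  required_cols(peptides, c("pep_seq", "score"), "peptide_ids")
  if (!"sample" %in% names(peptides)) peptides$sample <- "S1"
  peptides$pep_seq <- toupper(peptides$pep_seq)
  check_aa_alphabet(peptides$pep_seq, what = "peptide identification")
  if (any(!is.finite(peptides$score))) {
    abort_circpep("Peptide scores must be finite.", "circpep_input_error")
  }
  keep <- nchar(peptides$pep_seq) >= min_len
  out <- peptides[keep, , drop = FALSE]
  attr(out, "n_rejected_short") <- sum(!keep)
  out
}

#' Read a protein FASTA (e.g. the canonical proteome)
#'
#' @param path FASTA path.
#' @return Tibble with `seq_id`, `seq`.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    seq_id = sub("\\s.*$", "", names(x)),
    seq = toupper(as.character(x))
  )
}
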