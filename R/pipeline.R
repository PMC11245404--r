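# End-to-end orchestration: candidate flagging -> junction windows ->
# footprint matching -> ribosome-association calls -> ORF discovery ->
# CEP database and decoys -> peptide evidence -> physicochemical
# profiles -> translation ratios -> integrated per-circRNA report.

#' Pipeline parameters
#'
#' Defaults mirror the analysis thresholds: 25-nt junction flanks, >= 2
#' unique footprints with >= 4-nt overhang, >= 2 back-spliced RNA reads,
#' 4x pseudo-circularisation, > 10 aa CEP peptides, 5% peptide FDR.
#'
#' @param flank Junction window flank, nt.
#' @param max_mismatch Substitutions allowed when matching reads.
#' @param min_unique Unique eligible footprints required per junction.
#' @param min_overhang Minimum footprint overhang on each side, nt.
#' @param min_rna_reads Back-spliced RNA reads required for candidacy.
#' @param min_peptide_len CEP database peptide length floor, aa.
#' @param fdr Peptide-level FDR threshold.
#' @param fdr_correction FDR estimator variant (see [target_decoy_fdr()]).
#' @param copies Pseudo-circularisation copies.
#' @param start_codons Initiation codons for ORF discovery.
#' @param missed_cleavages Tryptic missed cleavages for all digests.
#' @param pseudocount Pseudocount for translation ratios.
#' @param search_all Search peptides against all circRNAs instead of
#'   only ribosome-associated ones (default FALSE, mirroring a search
#'   database restricted to ribosome-associated circles).
#' @param seed Seed for the decoy pool (the only random step).
#' @param ribo_libsize,rna_libsize Library sizes for TR; default to the
#'   totals of the supplied reads/counts.
#' @return A list of class `circpep_params`.
#' @export
pipeline_params <- function(flank = 25L, max_mismatch = 0L, min_unique = 2L,
                            min_overhang = 4L, min_rna_reads = 2L,
                            min_peptide_len = 11L, fdr = 0.05,
                            fdr_correction = c("plus1", "none"), copies = 4L,
                            start_codons = default_start_codons(),
                            missed_cleavages = 0L, pseudocount = 0,
                            search_all = FALSE, seed = 1L,
                            ribo_libsize = NULL, rna_libsize = NULL) {
  fdr_correction <- match.arg(fdr_correction)
  structure(as.list(environment()), class = "circpep_params")
}

#' Run the full coding-circRNA discovery pipeline
#'
#' @param circs circRNA tibble with `mature_seq` (see [circ_tbl()],
#'   [build_mature_sequence()]).
#' @param reads Footprint read tibble (`read_id`, `seq`), pre-filtered
#'   against the linear reference by the caller.
#' @param rna_counts Back-spliced RNA support: tibble `circ_id`,
#'   `n_bsj_reads` (or a hit tibble, see [rna_junction_support()]).
#' @param peptides Peptide identifications (`pep_seq`, `score`,
#'   optional `sample`).
#' @param canonical Canonical proteome tibble (`seq_id`, `seq`).
#' @param params A [pipeline_params()].
#'
#' @return An object of class `circ_pipeline`: `report` (one row per
#'   circRNA), `stages` (every intermediate table) and `params`.
#'   `tidy()` returns the report, `glance()` headline counts.
#' @export
run_pipeline <- function(circs, reads, rna_counts, peptides, canonical,
                         params = pipeline_params()) {
  validate_circs(circs, need_seq = TRUE)
  circ_ids <- circs$circ_id

  candidate <- rna_junction_support(rna_counts, params$min_rna_reads,
                                    circ_ids = circ_ids)
  windows <- junction_windows(circs, flank = params$flank)
  hits <- match_reads_to_junctions(reads, windows,
                                   max_mismatch = params$max_mismatch)
  hits_unique <- dedupe_unique(hits, reads)
  assoc <- call_ribosome_associated(hits_unique,
                                    min_unique = params$min_unique,
                                    min_overhang = params$min_overhang,
                                    circ_ids = circ_ids)
  orfs <- find_circ_orfs(circs, start_codons = params$start_codons,
                         copies = params$copies)
  cep_db <- build_cep_db(orfs, min_peptide_len = params$min_peptide_len)
  search_ids <- if (params$search_all) {
    circ_ids
  } else {
    assoc$circ_id[assoc$ribosome_associated]
  }
  search_db <- cep_db[cep_db$circ_id %in% search_ids, , drop = FALSE]

  canon_peps <- unique(unlist(lapply(
    canonical$seq, digest_trypsin,
    missed_cleavages = params$missed_cleavages
  )))

  if (nrow(search_db) > 0) {
    decoys <- build_decoy_pool(search_db, seed = params$seed + 1000003L,
                               canonical_peptides = canon_peps)
    evidence <- classify_peptides(peptides, search_db, decoys, canonical,
                                  missed_cleavages = params$missed_cleavages)
    evidence <- tryCatch(
      target_decoy_fdr(evidence, alpha = params$fdr,
                       correction = params$fdr_correction),
      circpep_input_error = function(e) {
        warning("No decoy matches observed; accepting no peptides.",
                call. = FALSE)
        dplyr::mutate(evidence, q_value = NA_real_, accepted = FALSE)
      }
    )
    ms_summary <- summarize_coding_circs(evidence, search_db)
  } else {
    decoys <- NULL
    evidence <- dplyr::mutate(peptides, class = "unmatched",
                              matched_entries = list(character()),
                              q_value = NA_real_, accepted = FALSE)
    ms_summary <- summarize_coding_circs(
      dplyr::filter(evidence, .data$accepted), cep_db
    )
  }

  ribo_libsize <- params$ribo_libsize %||% nrow(reads)
  rna_libsize <- params$rna_libsize %||% sum(candidate$n_bsj_reads)
  tr_records <- compute_tr(
    tibble::tibble(
      transcript_id = assoc$circ_id,
      ribo_count = assoc$n_hits,
      rna_count = candidate$n_bsj_reads[match(assoc$circ_id,
                                              candidate$circ_id)],
      ribo_libsize = ribo_libsize,
      rna_libsize = rna_libsize
    ),
    pseudocount = params$pseudocount
  )

  # best ORF per circle: the longest among those backing a DB entry
  best_orf <- orfs |>
    dplyr::semi_join(cep_db, by = c("circ_id", "peptide")) |>
    dplyr::group_by(.data$circ_id) |>
    dplyr::slice_max(.data$length_nt, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  profiles <- if (nrow(best_orf) > 0) {
    physchem_profile(tibble::tibble(seq_id = best_orf$circ_id,
                                    seq = best_orf$peptide))
  } else {
    physchem_profile(tibble::tibble(seq_id = character(),
                                    seq = character()))
  }

  rr <- scan_rrach(circs)
  n_orfs <- orfs |> dplyr::count(.data$circ_id, name = "n_orfs")
  n_entries <- cep_db |> dplyr::count(.data$circ_id, name = "n_cep_entries")

  report <- tibble::tibble(circ_id = circ_ids) |>
    dplyr::left_join(candidate, by = "circ_id") |>
    dplyr::left_join(assoc, by = "circ_id") |>
    dplyr::left_join(n_orfs, by = "circ_id") |>
    dplyr::left_join(n_entries, by = "circ_id") |>
    dplyr::left_join(
      dplyr::select(best_orf, "circ_id",
                    best_orf_length_nt = "length_nt",
                    best_orf_start_codon = "start_codon",
                    best_orf_stopless = "stopless",
                    best_orf_peptide = "peptide"),
      by = "circ_id"
    ) |>
    dplyr::left_join(ms_summary, by = "circ_id") |>
    dplyr::left_join(
      dplyr::select(tr_records, circ_id = "transcript_id", "tr"),
      by = "circ_id"
    ) |>
    dplyr::left_join(
      dplyr::select(profiles, circ_id = "seq_id", cep_length_aa = "length_aa",
                    cep_mw = "mw", cep_pi = "pi",
                    cep_instability = "instability", cep_stable = "stable",
                    cep_gravy = "gravy"),
      by = "circ_id"
    ) |>
    dplyr::left_join(dplyr::select(rr, "circ_id", "n_rrach"),
                     by = "circ_id") |>
    tidyr::replace_na(list(n_orfs = 0L, n_cep_entries = 0L,
                           n_peptides_unique = 0L, n_peptides_shared = 0L,
                           ms_supported = FALSE))

  stopifnot(all(!report$ms_supported | report$ribosome_associated |
                  params$search_all))

  structure(
    list(report = report,
         stages = list(windows = windows, hits = hits,
                       hits_unique = hits_unique, assoc = assoc,
                       orfs = orfs, cep_db = cep_db, search_db = search_db,
                       decoys = decoys, evidence = evidence,
                       ms_summary = ms_summary, tr = tr_records,
                       profiles = profiles),
         params = params),
    class = "circ_pipeline"
  )
}

#' @export
print.circ_pipeline <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "circpep pipeline: %d circRNAs\n",
    "  candidates (>= %d BSJ reads):        %d\n",
    "  ribosome-associated:                 %d\n",
    "  with CEP database entries (> %d aa): %d\n",
    "  MS-supported:                        %d\n",
    "  accepted junction peptides:          %d\n"),
    g$n_circ, x$params$min_rna_reads, g$n_candidate,
    g$n_ribosome_associated, x$params$min_peptide_len - 1L,
    g$n_with_cep_entries, g$n_ms_supported, g$n_accepted_peptides))
  invisible(x)
}

#' @export
tidy.circ_pipeline <- function(x, ...) x$report

#' @export
glance.circ_pipeline <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_circ = nrow(r),
    n_candidate = sum(r$candidate),
    n_ribosome_associated = sum(r$ribosome_associated),
    n_with_cep_entries = sum(r$n_cep_entries > 0),
    n_ms_supported = sum(r$ms_supported),
    n_accepted_peptides = sum(x$stages$evidence$accepted %||% FALSE),
    n_cep_entries = nrow(x$stages$cep_db)
  )
}

#' Confusion matrices of pipeline calls against ground truth
#'
#' Compares the report of [run_pipeline()] with the manifest of
#' [simulate_circ_dataset()], one row per stage: candidate flagging,
#' ribosome-association, ORF discovery (a circle counts positive when it
#' has >= 1 CEP database entry; circles flagged `coding_ambiguous` are
#' excluded from the negatives of this stage), and MS support.
#'
#' @param pipeline A `circ_pipeline` (or its report tibble).
#' @param truth The truth tibble of [simulate_circ_dataset()].
#' @return Tibble: `stage`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `precision`, `specificity`.
#' @export
evaluate_against_truth <- function(pipeline, truth) {
  report <- if (inherits(pipeline, "circ_pipeline")) {
    pipeline$report
  } else {
    pipeline
  }
  orphans <- c(setdiff(report$circ_id, truth$circ_id),
               setdiff(truth$circ_id, report$circ_id))
  if (length(orphans)) {
    abort_circpep(
      sprintf("circ_ids do not reconcile between report and truth: %s",
              paste(utils::head(orphans, 5), collapse = ", ")),
      "circpep_input_error"
    )
  }
  j <- dplyr::inner_join(report, truth, by = "circ_id",
                         suffix = c("", ".truth"))
  confusion <- function(stage, called, expected, exclude = FALSE) {
    called <- called[!exclude]
    expected <- expected[!exclude]
    tp <- sum(called & expected); fp <- sum(called & !expected)
    fn <- sum(!called & expected); tn <- sum(!called & !expected)
    tibble::tibble(
      stage = stage, tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  }
  dplyr::bind_rows(
    confusion("candidate", j$candidate, j$is_candidate),
    confusion("ribosome_association", j$ribosome_associated,
              j$expected_ribosome_associated),
    confusion("orf_discovery", j$n_cep_entries > 0, j$has_planted_orf,
              exclude = j$coding_ambiguous & !j$has_planted_orf),
    confusion("ms_support", j$ms_supported, j$expected_ms_supported)
  )
}

#' Write pipeline artifacts to a directory
#'
#' One TSV per stage plus the integrated report with a provenance
#' header (package version and parameter fingerprint) and a JSON
#' sidecar of headline counts. Floating-point fields are written with 6
#' significant digits.
#'
#' @param pipeline A `circ_pipeline`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- pipeline$params
  header <- sprintf(
    "# circpep %s | flank=%d min_unique=%d min_overhang=%d min_rna_reads=%d min_peptide_len=%d fdr=%g copies=%d seed=%d",
    as.character(utils::packageVersion("circpep")),
    params$flank, params$min_unique, params$min_overhang,
    params$min_rna_reads, params$min_peptide_len, params$fdr,
    params$copies, params$seed
  )
  fmt <- function(df) {
    dplyr::mutate(df, dplyr::across(
      dplyr::where(is.double), ~ signif(.x, 6)
    ), dplyr::across(dplyr::where(is.list), ~ vapply(
      .x, function(v) paste(unlist(v), collapse = ","), character(1)
    )))
  }
  report_path <- file.path(dir, "report.tsv")
  writeLines(header, report_path)
  readr::write_tsv(fmt(pipeline$report), report_path, append = TRUE,
                   col_names = TRUE)
  for (nm in c("assoc", "cep_db", "evidence", "tr", "profiles")) {
    st <- pipeline$stages[[nm]]
    if (!is.null(st) && nrow(st) > 0) {
      readr::write_tsv(fmt(st), file.path(dir, paste0(nm, ".tsv")))
    }
  }
  jsonlite::write_json(as.list(glance(pipeline)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
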