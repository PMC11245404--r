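# Translation ratio (TR): the abundance of translating RNA relative to
# total RNA for a transcript. For circRNAs both abundances are
# junction-crossing reads per million library reads; for linear mRNA
# controls the same formula is applied to CDS-mapped counts supplied by
# the caller.

#' Compute translation ratios
#'
#' `tr = ((ribo_count + pseudocount) / ribo_libsize) /
#'       ((rna_count + pseudocount) / rna_libsize)`.
#' Records with `rna_count = 0` and `pseudocount = 0` get `tr = NA` and
#' should be excluded from downstream comparisons (they are dropped by
#' [compare_tr()]).
#'
#' @param records Tibble with `transcript_id`, `ribo_count`, `rna_count`,
#'   `ribo_libsize`, `rna_libsize`.
#' @param pseudocount Added to both counts before normalisation
#'   (default 0; undefined TRs are excluded rather than imputed).
#' @return `records` with a `tr` column appended.
#' @export
#' @examples
#' compute_tr(tibble::tibble(transcript_id = "t1", ribo_count = 10,
#'                           rna_count = 20, ribo_libsize = 1e6,
#'                           rna_libsize = 2e6))$tr  # 1
compute_tr <- function(records, pseudocount = 0) {
  required_cols(records, c("transcript_id", "ribo_count", "rna_count",
                           "ribo_libsize", "rna_libsize"), "compute_tr")
  if (any(records$ribo_count < 0 | records$rna_count < 0)) {
    abort_circpep("Counts must be non-negative.", "circpep_input_error")
  }
  if (any(records$ribo_libsize <= 0 | records$rna_libsize <= 0)) {
    abort_circpep("Library sizes must be positive.", "circpep_input_error")
  }
  if (pseudocount < 0) {
    abort_circpep("`pseudocount` must be non-negative.",
                  "circpep_parameter_error")
  }
  # written as (count ratio) * (libsize ratio) so that jointly rescaling
  # both library sizes cancels exactly, not just to rounding
  dplyr::mutate(records, tr = dplyr::if_else(
    .data$rna_count + pseudocount > 0,
    ((.data$ribo_count + pseudocount) / (.data$rna_count + pseudocount)) *
      (.data$rna_libsize / .data$ribo_libsize),
    NA_real_
  ))
}

#' Compare two groups of translation ratios
#'
#' Two-sample Kolmogorov-Smirnov test on the TR distributions, with a
#' median-difference direction summary. Non-finite values are dropped
#' first.
#'
#' @param tr_a,tr_b Numeric TR vectors (each needs >= 2 finite values).
#' @return One-row tibble: `n_a`, `n_b`, `ks_statistic`, `p_value`,
#'   `median_a`, `median_b`, `median_diff` (a minus b).
#' @export
compare_tr <- function(tr_a, tr_b) {
  tr_a <- tr_a[is.finite(tr_a)]
  tr_b <- tr_b[is.finite(tr_b)]
  if (length(tr_a) < 2 || length(tr_b) < 2) {
    abort_circpep("Each group needs at least 2 finite TR values.",
                  "circpep_input_error")
  }
  ks <- suppressWarnings(stats::ks.test(tr_a, tr_b))
  tibble::tibble(
    n_a = length(tr_a),
    n_b = length(tr_b),
    ks_statistic = unname(ks$statistic),
    p_value = ks$p.value,
    median_a = stats::median(tr_a),
    median_b = stats::median(tr_b),
    median_diff = stats::median(tr_a) - stats::median(tr_b)
  )
}
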