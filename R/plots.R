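# ggplot2 figures for the main result types.

#' Footprint read-length distribution plot
#'
#' Bar chart of read lengths with the expected footprint range (default
#' 25-35 nt) shaded.
#'
#' @param reads Read tibble with `seq`.
#' @param range Footprint range to highlight.
#' @return A ggplot object.
#' @export
plot_read_lengths <- function(reads, range = c(25L, 35L)) {
  hist <- read_length_histogram(reads, range = range)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::annotate("rect", xmin = range[1] - 0.5, xmax = range[2] + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "Read length (nt)", y = "Reads",
                  title = "Ribosome footprint size distribution") +
    ggplot2::theme_minimal()
}

#' Frame periodicity plot
#'
#' @param periodicity Output of [frame_periodicity()].
#' @return A ggplot object.
#' @export
plot_frame_periodicity <- function(periodicity) {
  ggplot2::ggplot(periodicity,
                  ggplot2::aes(x = factor(.data$frame), y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "5' end frame (mod 3)", y = "Fraction of reads",
                  title = "3-nt codon periodicity") +
    ggplot2::theme_minimal()
}

#' Translation-ratio distribution plot
#'
#' Empirical cumulative distributions of two TR groups.
#'
#' @param tr_a,tr_b Numeric TR vectors.
#' @param labels Group labels.
#' @return A ggplot object.
#' @export
plot_tr_comparison <- function(tr_a, tr_b, labels = c("circRNA", "mRNA")) {
  df <- dplyr::bind_rows(
    tibble::tibble(tr = tr_a[is.finite(tr_a)], group = labels[1]),
    tibble::tibble(tr = tr_b[is.finite(tr_b)], group = labels[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tr, colour = .data$group)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Translation ratio", y = "Cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cep_lep_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$ceps, group = "CEP"),
    dplyr::mutate(object$leps, group = "LEP")
  ) |>
    dplyr::select("group", "length_aa", "mw", "gravy", "instability") |>
    tidyr::pivot_longer(-"group", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "CEP vs LEP physicochemical profiles") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.circ_pipeline <- function(object, ...) {
  g <- glance(object)
  df <- tibble::tibble(
    stage = factor(c("circRNAs", "candidate", "ribosome-associated",
                     "CEP predicted", "MS-supported"),
                   levels = c("circRNAs", "candidate", "ribosome-associated",
                              "CEP predicted", "MS-supported")),
    n = c(g$n_circ, g$n_candidate, g$n_ribosome_associated,
          g$n_with_cep_entries, g$n_ms_supported)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "circRNAs",
                  title = "Coding-circRNA discovery funnel") +
    ggplot2::theme_minimal()
}
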