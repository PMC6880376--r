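#' Tidy a sweep scan into one row per region
#'
#' @param x A `sweep_scan` object.
#' @param ... Unused.
#' @return A tibble with one row per merged sweep region: coordinates,
#'   member-window count, per-statistic maxima and the overlapping gene IDs
#'   collapsed into a comma-separated string (when annotation was run).
#' @export
tidy.sweep_scan <- function(x, ...) {
  reg <- tibble::as_tibble(x$regions)
  if ("genes" %in% names(reg)) {
    reg$genes <- vapply(reg$genes, paste, "", collapse = ",")
  }
  reg
}

#' One-row summary of a sweep scan
#'
#' @param x A `sweep_scan` object.
#' @param ... Unused.
#' @return A one-row tibble: window counts, the three empirical thresholds,
#'   signal/region/gene counts and the genome-wide weighted F_ST.
#' @export
glance.sweep_scan <- function(x, ...) {
  thr <- stats::setNames(x$thresholds$threshold,
                         paste0(x$thresholds$statistic, "_threshold"))
  tibble::tibble(
    n_windows = nrow(x$windows),
    n_ranked = sum(x$windows$ranked),
    n_signal = sum(x$windows$signal),
    n_regions = nrow(x$regions),
    n_genes = if ("genes" %in% names(x$regions)) {
      length(unique(unlist(x$regions$genes)))
    } else {
      NA_integer_
    },
    fst_threshold = thr[["fst_threshold"]],
    pi_ratio_threshold = thr[["pi_ratio_threshold"]],
    ihh12_threshold = thr[["ihh12_threshold"]],
    genome_weighted_fst = x$genome_fst$weighted_fst
  )
}

#' Plot the windowed statistics of a sweep scan
#'
#' A faceted genome plot of windowed F_ST, log2 diversity ratio and mean
#' normalised iHH12, with the empirical thresholds as dashed lines and the
#' signal windows highlighted.
#'
#' @param object A `sweep_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_scan <- function(object, ...) {
  w <- object$windows
  long <- tidyr::pivot_longer(
    dplyr::mutate(w, mid = (.data$start + .data$end) / 2),
    cols = c("fst", "log2_pi_ratio", "ihh12"),
    names_to = "statistic", values_to = "value")
  thr <- object$thresholds
  thr$statistic[thr$statistic == "pi_ratio"] <- "log2_pi_ratio"
  thr$threshold[thr$statistic == "log2_pi_ratio"] <-
    log2(thr$threshold[thr$statistic == "log2_pi_ratio"])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid / 1e6, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$signal), size = 0.8) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_grid(statistic ~ chrom, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "signal") +
    ggplot2::theme_minimal()
}

#' Plot an LD decay curve
#'
#' @param decay A tibble from [decay_curve()] (several may be row-bound
#'   with a `population` column for comparison).
#' @return A ggplot object of mean r2 against distance.
#' @export
plot_ld_decay <- function(decay) {
  aes <- if ("population" %in% names(decay)) {
    ggplot2::aes(x = .data$dist_lo / 1000, y = .data$mean_r2,
                 colour = .data$population)
  } else {
    ggplot2::aes(x = .data$dist_lo / 1000, y = .data$mean_r2)
  }
  ggplot2::ggplot(decay[!is.na(decay$mean_r2), ], aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Plot windowed diversity or differentiation along the genome
#'
#' @param table A window table (e.g. from [windowed_pi()] or
#'   [windowed_fst()]).
#' @param stat Name of the column to plot.
#' @return A ggplot object.
#' @export
plot_windows <- function(table, stat = "pi") {
  stopifnot(stat %in% names(table))
  df <- dplyr::mutate(table, mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6,
                                   y = .data[[stat]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = stat) +
    ggplot2::theme_minimal()
}
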