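# ---- diagnostic plots ----

#' Density versus G+C content
#'
#' Scatter of per-genome OSC densities (total and per frame) against coding
#' G+C content, the analogue of the survey's density-composition plot.
#'
#' @param metrics a tibble from [genome_metrics()].
#' @return A ggplot object.
#' @export
plot_gc_density <- function(metrics) {
  long <- metrics |>
    select("organism", "gc", "density2", "density3", "density_total") |>
    tidyr::pivot_longer(cols = c("density2", "density3", "density_total"),
                        names_to = "frame", values_to = "density") |>
    mutate(frame = dplyr::recode(.data$frame, density2 = "+2", density3 = "+3",
                                 density_total = "total"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gc, y = .data$density,
                                     colour = .data$frame)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "G+C content of coding sequences",
                  y = "OSCs per 100 codons", colour = "frame")
}

#' Frame bias versus GC ratio
#'
#' log10(N2/N3) against the GC:AT ratio of coding sequences; genomes with an
#' undefined bias are dropped.
#'
#' @param metrics a tibble from [genome_metrics()].
#' @return A ggplot object.
#' @export
plot_frame_bias <- function(metrics) {
  d <- metrics |> filter(!is.na(.data$frame_bias))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gc_ratio, y = .data$frame_bias)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "[G+C]:[A+T] ratio", y = "log10(N+2 / N+3)")
}

#' Stop-usage frequencies versus G+C content
#'
#' Relative usage of each stop trinucleotide within each alternate frame,
#' plotted against coding G+C.
#'
#' @param metrics a tibble from [genome_metrics()].
#' @return A ggplot object.
#' @export
plot_usage <- function(metrics) {
  usage_cols <- grep("_f[23]$", names(metrics), value = TRUE)
  long <- metrics |>
    select("organism", "gc", dplyr::all_of(usage_cols)) |>
    tidyr::pivot_longer(cols = dplyr::all_of(usage_cols),
                        names_to = c("stop", "frame"), names_sep = "_",
                        values_to = "freq")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gc, y = .data$freq,
                                     colour = .data$stop)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~frame) +
    ggplot2::labs(x = "G+C content", y = "relative usage within frame")
}

#' @export
autoplot.expectation_result <- function(object, frame = "combined", ...) {
  row <- object[object$frame == frame, ]
  if (!nrow(row)) abort("no such frame in result", class = "oscan_input_error")
  sims <- tibble(density = row$sim_densities[[1]])
  ggplot2::ggplot(sims, ggplot2::aes(x = .data$density)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = row$observed, colour = "red") +
    ggplot2::labs(title = sprintf("%s | %s | frame %s", row$organism, row$model, frame),
                  subtitle = sprintf("observed %.3f vs expected %.3f +/- %.3f (pct dev %+.2f%%)",
                                     row$observed, row$mean_expected,
                                     row$sd_expected, row$pct_deviation),
                  x = "simulated OSC density (per 100 codons)", y = "trials")
}

#' @export
autoplot.pca_result <- function(object, ...) {
  d <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "component", y = "fraction of variance")
}

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
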