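#' Plot a spectral kernel set
#'
#' Four traces (one per LED channel, coloured by wavelength) on the lag
#' axis, in baseline z-score units.
#'
#' @param object A `kernel_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kernel_set <- function(object, ...) {
  df <- tidy(object)
  pal <- c(R = "#d73027", G = "#1a9850", B = "#4575b4", UV = "#984ea3")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70", linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::labs(x = "time lag (s)", y = "kernel (baseline z-score)") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster mean kernels
#'
#' @param profiles Output of [cluster_profiles()].
#' @param scaled Plot max-scaled means (default) or raw means.
#' @return A ggplot faceted by cluster.
#' @export
plot_cluster_kernels <- function(profiles, scaled = TRUE) {
  col <- if (scaled) "mean_scaled" else "mean"
  df <- profiles |>
    dplyr::mutate(wave = .data[[col]]) |>
    dplyr::select("cluster", "channel", "wave") |>
    tidyr::unnest_longer("wave", values_to = "value") |>
    dplyr::group_by(.data$cluster, .data$channel) |>
    dplyr::mutate(lag_s = lag_grid()) |>
    dplyr::ungroup()
  pal <- c(R = "#d73027", G = "#1a9850", B = "#4575b4", UV = "#984ea3")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::labs(x = "time lag (s)",
                  y = if (scaled) "max-scaled mean kernel" else "mean kernel") +
    ggplot2::theme_minimal()
}
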