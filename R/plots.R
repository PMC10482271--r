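#' Heatmap of a positional HGT score matrix
#'
#' @param object A `nterm_hgt_matrix` from [positional_hgt_matrix()].
#' @param hgt_cap Scores are clipped to `[-hgt_cap, hgt_cap]` for display so
#'   a single extreme cell does not flatten the colour scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nterm_hgt_matrix
#' @export
autoplot.nterm_hgt_matrix <- function(object, hgt_cap = 20, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      hgt_clipped = pmax(pmin(.data$hgt, hgt_cap), -hgt_cap))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = factor(.data$residue, levels = rev(AA20)),
                                   fill = .data$hgt_clipped)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  name = "HGT") +
    ggplot2::labs(x = "position", y = "residue") +
    ggplot2::theme_minimal()
}

#' Barplot of observed versus background residue frequencies at a position
#'
#' @param object A `nterm_bias` from [position_bias_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nterm_bias
#' @export
autoplot.nterm_bias <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::arrange(dplyr::desc(.data$f_obs)) |>
    dplyr::mutate(residue = factor(.data$residue, levels = .data$residue)) |>
    tidyr::pivot_longer(c("f_obs", "f_ref"), names_to = "which",
                        values_to = "freq")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$freq,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(f_obs = "#4DAF4A", f_ref = "#377EB8"),
                               labels = c(f_obs = "observed", f_ref = "background"),
                               name = NULL) +
    ggplot2::labs(x = "residue", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Proportion and HGT curves of a threshold sweep
#'
#' @param object A `nterm_sweep` from [threshold_sweep()].
#' @param classes Optional subset of classes to draw.
#' @param ... Unused.
#' @return A ggplot object with one panel for class proportions and one for
#'   HGT scores, both against the enrichment threshold.
#' @method autoplot nterm_sweep
#' @export
autoplot.nterm_sweep <- function(object, classes = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(classes)) df <- dplyr::filter(df, .data$class %in% classes)
  df <- tidyr::pivot_longer(df, c("proportion", "hgt"),
                            names_to = "panel", values_to = "value") |>
    dplyr::mutate(panel = factor(.data$panel, levels = c("proportion", "hgt")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "enrichment threshold", y = NULL) +
    ggplot2::theme_minimal()
}
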