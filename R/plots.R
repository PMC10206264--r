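#' Plot an RMSD time series
#'
#' @param series Tibble from [rmsd_series()].
#' @return A ggplot object.
#' @export
plot_rmsd <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time, y = .data$rmsd)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (ps)", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Plot per-residue RMSF
#'
#' @param rmsf Tibble from [rmsf_per_residue()].
#' @return A ggplot object.
#' @export
plot_rmsf <- function(rmsf) {
  ggplot2::ggplot(rmsf, ggplot2::aes(x = .data$residue_index, y = .data$rmsf)) +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Plot hydrogen-bond occupancies
#'
#' @param hbonds Tibble from [detect_hbonds()].
#' @return A ggplot object (horizontal bars, occupancy percent).
#' @export
plot_hbond_occupancy <- function(hbonds) {
  hbonds <- hbonds |>
    mutate(pair = paste(.data$donor, "...", .data$acceptor))
  ggplot2::ggplot(hbonds,
                  ggplot2::aes(x = .data$occupancy,
                               y = stats::reorder(.data$pair, .data$occupancy))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "occupancy (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-residue binding-enthalpy contributions
#'
#' @param contribs Tibble from [decompose_per_residue()].
#' @param key_only Show only residues flagged as key contributors.
#' @return A ggplot object.
#' @export
plot_residue_contributions <- function(contribs, key_only = FALSE) {
  if (key_only) contribs <- filter(contribs, .data$is_key)
  contribs <- contribs |>
    mutate(residue = paste0(.data$residue_name, .data$residue_index))
  ggplot2::ggplot(contribs,
                  ggplot2::aes(x = stats::reorder(.data$residue, .data$residue_index),
                               y = .data$d_subtotal,
                               fill = .data$d_subtotal < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "contribution (kcal/mol)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname binding_free_energy
#' @param object A `bs_binding_energy`.
#' @export
autoplot.bs_binding_energy <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "kcal/mol") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
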