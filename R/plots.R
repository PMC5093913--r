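# ggplot2 displays for the main result types.

#' Ramachandran plot of classified conformers
#'
#' @param classified Output of [classify_conformers()] (capped systems are
#'   the informative ones).
#' @param highlight_minima Circle the per-system global minima?
#' @return A ggplot object.
#' @export
plot_ramachandran <- function(classified, highlight_minima = TRUE) {
  d <- classified[!is.na(classified$phi) & !is.na(classified$psi), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$phi, y = .data$psi)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), alpha = 0.8) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::scale_y_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(
      x = expression(phi ~ "(deg)"), y = expression(psi ~ "(deg)"),
      colour = "class"
    ) +
    ggplot2::theme_minimal()
  if (highlight_minima) {
    gm <- global_minima(d)
    p <- p + ggplot2::geom_point(
      data = gm, shape = 21, size = 4, stroke = 0.8, colour = "red", fill = NA
    )
  }
  p
}

#' Conformational energy hierarchies, bare vs complexed
#'
#' Vertical level diagrams of relative energies per system, the standard
#' display for conformational hierarchies.
#'
#' @param hierarchies A list of `pepc_hierarchy` objects (or one).
#' @param max_rel_ev Clip levels above this relative energy (eV).
#' @return A ggplot object.
#' @export
plot_hierarchy <- function(hierarchies, max_rel_ev = Inf) {
  if (inherits(hierarchies, "pepc_hierarchy")) hierarchies <- list(hierarchies)
  d <- dplyr::bind_rows(lapply(hierarchies, function(h) {
    tibble(system = h$system, rel_ev = h$entries$rel_ev)
  }))
  d <- d[d$rel_ev <= max_rel_ev, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$system, y = .data$rel_ev)) +
    ggplot2::geom_point(shape = 95, size = 6) +
    ggplot2::labs(x = NULL, y = "relative energy (eV)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Binding-energy trends across ligands and ions
#'
#' Ligands on the x-axis sorted by affinity to a reference ion (strongest
#' first), one line per ion.
#'
#' @param trend A `pepc_trend`.
#' @param sort_by Reference ion for the x-axis ordering.
#' @return A ggplot object.
#' @export
plot_binding_trend <- function(trend, sort_by = "Ca") {
  ord <- affinity_ranking(trend, sort_by)$ligand
  d <- trend$records
  d$ligand <- factor(d$ligand, levels = ord)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$ligand, y = .data$e_bind,
    colour = .data$ion, group = .data$ion
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(E[bind] ~ "(eV)"), colour = "ion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Cation-oxygen distance histogram
#'
#' @param x A `pepc_disthist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pepc_disthist <- function(x, ...) {
  d <- tibble(
    mid = (head(x$breaks, -1) + tail(x$breaks, -1)) / 2,
    count = x$counts
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = x$bin_width, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = x$median, linetype = 2) +
    ggplot2::labs(x = "cation-O distance (A)", y = "count") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pepc_disthist
#' @param hist A `pepc_disthist`.
#' @export
plot_distance_histogram <- function(hist) autoplot.pepc_disthist(hist)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
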