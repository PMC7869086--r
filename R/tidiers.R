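#' Tidy a Ripley K/L result
#'
#' @param x A `ripley_result` from [ripley_k_l()].
#' @param ... Unused.
#' @return A plain tibble with `r`, `k`, `l` and the centred `l_minus_r`.
#' @export
tidy.ripley_result <- function(x, ...) {
  tibble(r = x$r, k = x$k, l = x$l, l_minus_r = x$l - x$r)
}

#' @rdname tidy.ripley_result
#' @export
glance.ripley_result <- function(x, ...) {
  tibble(n_points = attr(x, "n_points"),
         area = attr(x, "area"),
         r_max = attr(x, "r_max"),
         correction = attr(x, "correction"),
         max_weight = attr(x, "max_weight"))
}

#' Plot the centred L function
#'
#' Plots `L(r) - r` against `r`; the dashed zero line is the CSR (Poisson)
#' reference. An envelope tibble from [csr_envelope()] is drawn as a ribbon.
#'
#' @param object A `ripley_result`.
#' @param envelope Optional envelope tibble (`r`, `lo`, `hi`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ripley_result <- function(object, envelope = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$l_minus_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "r (nm)", y = "L(r) - r") +
    ggplot2::theme_minimal()
  if (!is.null(envelope) && nrow(envelope) > 0 && !all(is.na(envelope$lo))) {
    p <- p + ggplot2::geom_ribbon(
      data = envelope,
      ggplot2::aes(x = .data$r, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.2)
  }
  p + ggplot2::geom_line(linewidth = 0.7)
}

#' @export
tidy.nq_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         exact = x$exact)
}

#' @export
glance.nq_test <- function(x, ...) tidy(x)

#' Plot per-cell enrichment values by region and CB1 class
#'
#' Jittered per-cell gene enrichment values, faceted by gene, coloured by
#' CB1 class, with the gene positivity cutoffs as dashed lines -- the
#' standard way to display the bimodal strong/weak split of an ISH
#' quantification.
#'
#' @param classified Output of [classify_cells()].
#' @param cutoffs The [cutoff_table()] used (for the cutoff guides).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(classified, cutoffs = default_cutoffs()) {
  guides <- tibble(gene = names(cutoffs$genes), cutoff = unname(cutoffs$genes))
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data$cb1_class, y = .data$enrichment,
                               colour = .data$cb1_class)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(data = guides,
                        ggplot2::aes(yintercept = .data$cutoff),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(region ~ gene) +
    ggplot2::labs(x = "CB1 class", y = "enrichment (ROI / background)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a bouton map coloured by layer
#'
#' @param boutons A bouton tibble (`x_um`, `y_um`, `layer`).
#' @return A ggplot object.
#' @export
plot_bouton_map <- function(boutons) {
  ggplot2::ggplot(boutons, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                        colour = .data$layer)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "depth (um)", colour = "layer") +
    ggplot2::theme_minimal()
}
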