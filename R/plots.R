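# ggplot2 visualizations: fold-change heat map, isotherm/kinetic/anisotropy
# fits, observed-vs-predicted additivity.

#' @describeIn fold_change_map Tile plot of the fold-change matrix
#'   (positions on the y axis, substitutions on the x axis, log colour
#'   scale).
#' @param object A `heat_map`.
#' @param ... Unused.
#' @export
#' @method autoplot heat_map
autoplot.heat_map <- function(object, ...) {
  cells <- dplyr::mutate(object$cells,
                         pos_label = paste0(.data$wild, .data$position))
  cells$pos_label <- factor(cells$pos_label,
                            levels = unique(cells$pos_label[order(cells$position)]))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$sub, y = .data$pos_label,
                                      fill = .data$fold)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_viridis_c(trans = "log10", name = "Fold-change") +
    ggplot2::labs(
      x = "Substitution", y = "Position (wild residue)",
      title = sprintf("Point-variant screen fold-change vs %s", object$lead_name)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_equilibrium Isotherm data with the fitted Langmuir curve
#'   on a log concentration axis.
#' @param object An `equilibrium_fit`.
#' @param ... Unused.
#' @export
#' @method autoplot equilibrium_fit
autoplot.equilibrium_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    conc = 10^seq(log10(min(d$conc[d$conc > 0])), log10(max(d$conc)), length.out = 120)
  )
  grid$response <- equilibrium_response(grid$conc, object$kd, object$rmax)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Concentration (M)", y = "Response (RU)",
      title = sprintf("Equilibrium isotherm fit: Kd = %s", format_kd(object$kd))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_kinetics Sensorgrams with the fitted association and
#'   dissociation curves, one colour per concentration.
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @export
#' @method autoplot kinetic_fit
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  d$t_plot <- ifelse(d$phase == "assoc", d$time,
                     object$t_end[as.character(d$conc)] + d$time)
  fitted <- d
  fitted$response <- purrr::pmap_dbl(
    list(d$time, d$conc, d$phase),
    function(t, cc, ph) {
      rmax <- object$rmax[[as.character(cc)]]
      if (ph == "assoc") {
        association_response(t, cc, object$kon, object$koff, rmax)
      } else {
        r0 <- association_response(object$t_end[[as.character(cc)]], cc,
                                   object$kon, object$koff, rmax)
        dissociation_response(t, r0, object$koff)
      }
    }
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_plot, y = .data$response,
                                  color = factor(.data$conc))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = fitted) +
    ggplot2::labs(
      x = "Time (s)", y = "Response (RU)", color = "Conc (M)",
      title = sprintf("1:1 kinetic fit: kon = %.2g, koff = %.2g, Kd = %s",
                      object$kon, object$koff, format_kd(object$kd))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_anisotropy Titration data with the fitted depletion
#'   binding curve.
#' @param object An `anisotropy_fit`.
#' @param ... Unused.
#' @export
#' @method autoplot anisotropy_fit
autoplot.anisotropy_fit <- function(object, ...) {
  d <- object$data
  pc <- d$protein_conc[d$protein_conc > 0]
  grid <- tibble::tibble(
    protein_conc = 10^seq(log10(min(pc)), log10(max(pc)), length.out = 120)
  )
  grid$signal <- object$s_free + (object$s_bound - object$s_free) *
    fraction_bound(grid$protein_conc, object$labeled_conc, object$kd)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$protein_conc, y = .data$signal)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Titrant concentration (M)", y = "Signal",
      title = sprintf("Anisotropy titration fit: Kd = %s", format_kd(object$kd))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn assess_additivity Observed vs predicted free energies with
#'   the identity line and error bars; flagged (sub-additive) sets are
#'   highlighted.
#' @param object An `additivity_report`.
#' @param ... Unused.
#' @export
#' @method autoplot additivity_report
autoplot.additivity_report <- function(object, ...) {
  p <- object$pairs
  ggplot2::ggplot(p, ggplot2::aes(x = .data$dg_pred, y = .data$dg_obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$dg_obs - .data$se_obs,
                                        ymax = .data$dg_obs + .data$se_obs),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$dg_pred - .data$se_pred,
                                         xmax = .data$dg_pred + .data$se_pred),
                            height = 0) +
    ggplot2::geom_point(ggplot2::aes(color = .data$flagged), size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "firebrick"),
                                name = "Sub-additive") +
    ggplot2::labs(
      x = expression(paste("Predicted ", Delta, "G", degree, " (kcal/mol)")),
      y = expression(paste("Observed ", Delta, "G", degree, " (kcal/mol)")),
      title = "Thermodynamic additivity: observed vs predicted"
    ) +
    ggplot2::theme_minimal()
}
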