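#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot out-of-fold predictions against experiment
#'
#' Scatter of experimental versus predicted delta-Tm pooled over the
#' cross-validation folds, with the first/third-quadrant bisector; points
#' are coloured by burial class when accessibilities are available.
#'
#' @param object An `ms_dtm_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ms_dtm_cv <- function(object, ...) {
  df <- object$predictions
  df$burial <- cut(df$acc, breaks = c(-Inf, 15, 50, Inf),
                   labels = c("core (A < 15%)", "partial (15-50%)",
                              "surface (A > 50%)"), right = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$obs,
                                   colour = .data$burial)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "predicted dTm (C)", y = "experimental dTm (C)",
                  colour = NULL,
                  title = sprintf("%s model, pooled out-of-fold predictions",
                                  object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a two-state stability curve
#'
#' @param object An `ms_stability_curve`.
#' @param from,to Temperature range (Kelvin).
#' @param ... Unused.
#' @return A ggplot of `dG(T)` with the melting temperature marked.
#' @exportS3Method ggplot2::autoplot
autoplot.ms_stability_curve <- function(object, from = 250, to = 420, ...) {
  t <- seq(from, to, length.out = 300)
  df <- tibble::tibble(temp = t, dg = gibbs_energy(object, t))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temp, y = .data$dg)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tm, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "T (K)", y = "folding dG (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Distance profile of a derived potential
#'
#' Shows the energy of a distance-type potential as a function of the
#' distance bin for a chosen amino acid (marginalising nothing: the other
#' axes are fixed or faceted over their labels).
#'
#' @param set An `ms_potentials`.
#' @param id Potential id with a distance axis (e.g. `"sd"`).
#' @param aa One-letter amino acid code to profile.
#' @param config The [ms_config()] used at derivation (for bin midpoints).
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(set, id = "sd", aa = "L",
                                  config = ms_config()) {
  p <- set$potentials[[id]]
  if (is.null(p) || !is.null(p$components) || !"d" %in% p$elements) {
    stop("'", id, "' is not an ungrouped distance-type potential in this set")
  }
  d_axis <- which(p$elements == "d")
  s_axis <- which(p$elements == "s")[1]
  idx <- rep(list(rlang::missing_arg()), length(dim(p$energy)))
  idx[[s_axis]] <- aa
  e <- do.call(`[`, c(list(p$energy), idx, list(drop = FALSE)))
  prof <- apply(e, d_axis, mean)
  mids <- config$d_min + (seq_along(prof) - 0.5) * config$d_bin
  df <- tibble::tibble(distance = mids, energy = prof)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$energy)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "side-chain centroid distance (A)",
                  y = "energy (kT)",
                  title = sprintf("%s potential, %s", id, aa)) +
    ggplot2::theme_minimal()
}
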