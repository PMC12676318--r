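#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_abline geom_line
#'   geom_point geom_polygon geom_text labs coord_cartesian theme_minimal
#'   annotate
NULL

#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' Step plot of the ROC with the chance diagonal; the title carries the
#' trapezoidal AUC.
#'
#' @param object A [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  area <- sum(diff(object$fpr) * (utils::head(object$tpr, -1) +
                                  utils::tail(object$tpr, -1)) / 2)
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step() +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.4f)", area)) +
    theme_minimal()
}

#' Plot ranked hits in (affinity, LD50) space
#'
#' Scatter of the ranked compounds against the ideal point (shown as a
#' cross), with rank labels; distance to the ideal point is what orders
#' the hits.
#'
#' @param object A [euclidean_rank()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ranked_hits <- function(object, ...) {
  ideal <- attr(object, "ideal")
  p <- ggplot(object, aes(x = .data$affinity_kcal_mol, y = .data$ld50_mol_kg)) +
    geom_point() +
    geom_text(aes(label = .data$ranking), vjust = -0.8, size = 3) +
    labs(x = "Affinity (kcal/mol)", y = "Predicted LD50 (mol/kg)",
         title = "Ideal-point Euclidean ranking") +
    theme_minimal()
  if (!is.null(ideal)) {
    p <- p + annotate("point", x = ideal$affinity_min, y = ideal$ld50_max,
                      shape = 4, size = 4, colour = "red")
  }
  p
}

#' Plot a trajectory RMSD time series
#'
#' @param object A [traj_rmsd()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.traj_rmsd <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ns, y = .data$rmsd)) +
    geom_line() +
    labs(x = "Time (ns)", y = "RMSD (Å)", title = "Backbone RMSD") +
    theme_minimal()
}

#' Plot a per-residue RMSF profile
#'
#' @param object A [traj_rmsf()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.traj_rmsf <- function(object, ...) {
  ggplot(object, aes(x = .data$resid, y = .data$rmsf)) +
    geom_line() +
    labs(x = "Residue", y = "RMSF (Å)", title = "Per-residue RMSF") +
    theme_minimal()
}

#' Plot per-frame hydrogen-bond counts
#'
#' @param object An [hbond_counts()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hbond_counts <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ns, y = .data$n_hbonds)) +
    geom_step() +
    labs(x = "Time (ns)", y = "Hydrogen bonds", title = "Hydrogen-bond count") +
    theme_minimal()
}

ellipse_points <- function(e, n = 200) {
  th <- seq(0, 2 * pi, length.out = n)
  rot <- e$angle_deg * pi / 180
  u <- (e$width_tpsa / 2) * cos(th)
  v <- (e$height_wlogp / 2) * sin(th)
  tibble(
    tpsa = e$center_tpsa + u * cos(rot) - v * sin(rot),
    wlogp = e$center_wlogp + u * sin(rot) + v * cos(rot)
  )
}

#' BOILED-Egg plot
#'
#' Draws the white (HIA) and yolk (BBB) ellipses in (TPSA, WLOGP) space
#' and overlays the compounds, coloured by their classified region.
#'
#' @param records Compound tibble with `wlogp` and `tpsa` columns (`id`
#'   used for labels when present).
#' @param model An [load_egg_model()] result.
#' @return A ggplot.
#' @export
plot_boiled_egg <- function(records, model = load_egg_model()) {
  records <- classify_egg(records, model)
  p <- ggplot(records, aes(x = .data$tpsa, y = .data$wlogp)) +
    geom_polygon(data = ellipse_points(model$white), fill = "ivory",
                 colour = "grey50", alpha = 0.8) +
    geom_polygon(data = ellipse_points(model$yolk), fill = "gold",
                 colour = "grey50", alpha = 0.8) +
    geom_point(aes(colour = .data$region)) +
    labs(x = "TPSA (Å²)", y = "WLOGP", colour = "Region",
         title = "BOILED-Egg classification") +
    theme_minimal()
  if ("id" %in% names(records)) {
    p <- p + geom_text(aes(label = .data$id), vjust = -0.8, size = 2.5)
  }
  p
}
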