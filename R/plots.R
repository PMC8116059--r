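#' @export
autoplot.scalar_map <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    coord_equal() +
    scale_fill_viridis_c(
      na.value = "white",
      name = paste0(attr(object, "descriptor"),
                    if (nzchar(attr(object, "units")))
                      paste0(" (", attr(object, "units"), ")") else "")
    ) +
    labs(
      x = "x (Å)", y = "y (Å)",
      title = sprintf("%s, %s leaflet(s)", attr(object, "descriptor"),
                      attr(object, "leaflet"))
    ) +
    theme_minimal()
}

#' Plot a distance-resolved enrichment profile
#'
#' @param profile Tibble from [enrichment_profile()].
#' @return A ggplot.
#' @export
plot_enrichment_profile <- function(profile) {
  ggplot(profile, aes(x = .data$distance, y = .data$enrichment,
                      colour = .data$sector)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line() +
    geom_point() +
    labs(x = "distance from protein surface (Å)",
         y = "DL enrichment (%)", colour = "interface") +
    theme_minimal()
}

#' @export
autoplot.isotherm_fit <- function(object, ...) {
  pts <- object$data
  grid <- tibble(chi_star = 10^seq(log10(min(pts$chi_star)) - 0.5,
                                   log10(max(pts$chi_star)) + 0.5,
                                   length.out = 200))
  grid$f_dimer <- isotherm_fraction(object$keq, grid$chi_star)
  ggplot(pts, aes(x = .data$chi_star, y = .data$f_dimer)) +
    geom_line(data = grid, colour = "steelblue") +
    geom_point() +
    scale_x_log10() +
    labs(
      x = expression(chi * "* (subunits/lipid)"), y = expression(F[Dimer]),
      title = sprintf("Keq = %.3g, ΔG° = %.2f kcal/mole%s",
                      object$keq, object$dg,
                      if (object$lower_limit_only) " (lower limit only)" else "")
    ) +
    theme_minimal()
}

#' @export
autoplot.titration_fit <- function(object, ...) {
  pts <- object$data
  xr <- range(pts$pct_dl)
  grid <- tibble(pct_dl = seq(xr[1], xr[2], length.out = 300))
  co <- as.list(object$coef)
  f0 <- object$f0_fixed %||% co$f0
  grid$f_dimer <- if (object$model == "single") {
    f0 * exp(-co$lambda * grid$pct_dl)
  } else {
    f0 * (co$f1 * exp(-co$lambda1 * grid$pct_dl) +
            (1 - co$f1) * exp(-co$lambda2 * grid$pct_dl))
  }
  ggplot(pts, aes(x = .data$pct_dl, y = .data$f_dimer)) +
    geom_line(data = grid, colour = "darkorange") +
    geom_point() +
    labs(x = "DL (%)", y = expression(F[Dimer]),
         title = paste0(object$model, " exponential decay")) +
    theme_minimal()
}

#' @export
autoplot.efflux_fit <- function(object, ...) {
  pts <- object$data
  grid <- tibble(time = seq(min(pts$time), max(pts$time), length.out = 300))
  grid$value <- efflux_model(grid$time, object$f0_vol, object$k_leak,
                             object$k_p)
  ggplot(pts, aes(x = .data$time, y = .data$value)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_line(data = grid, colour = "steelblue") +
    labs(x = "time (s)", y = "normalized Cl⁻ release",
         title = sprintf("k_P = %.3g /s, k_leak = %.3g /s, F0,vol = %.2f",
                         object$k_p, object$k_leak, object$f0_vol)) +
    theme_minimal()
}

#' Plot photobleaching step distributions
#'
#' @param data Tibble with columns `p1`, `p2`, `p3plus` and a grouping
#'   column named by `by` (e.g. `pct_dl` or `label`).
#' @param by Name of the grouping column.
#' @return A ggplot.
#' @export
plot_step_distribution <- function(data, by = "pct_dl") {
  long <- data |>
    tidyr::pivot_longer(c("p1", "p2", "p3plus"), names_to = "steps",
                        values_to = "probability") |>
    mutate(steps = factor(.data$steps, c("p1", "p2", "p3plus"),
                          c("1", "2", "3+")))
  ggplot(long, aes(x = factor(.data[[by]]), y = .data$probability,
                   fill = .data$steps)) +
    geom_col(position = "dodge") +
    labs(x = by, y = "probability", fill = "bleaching steps") +
    theme_minimal()
}
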