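#' Plot a radial pair-correlation profile
#'
#' One line per species, `g(r)` against the shell radius.
#'
#' @param object A `radial_profile` from [pair_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$g,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "r from cluster COM (nm)", y = "g(r)",
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot contour-resolved bilayer profiles
#'
#' Thickness, linear bead density and mean chain extension against the
#' contour coordinate `s`, in stacked facets.
#'
#' @param object A `contour_profile` from [contour_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contour_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("s", "thickness", "bead_density", "Qbar_s")],
    -"s", names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(long$quantity,
                          levels = c("thickness", "bead_density", "Qbar_s"),
                          labels = c("thickness (nm)", "bead density (1/nm)",
                                     "mean Q (nm)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "contour distance s (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a scalar time series
#'
#' @param object A [scalar_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalar_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ns)", y = attr(object, "label") %||% "value") +
    ggplot2::theme_minimal()
}

#' Plot a fitted critical-strain law
#'
#' Observed rupture points with the fitted exponential decay toward
#' `gamma_inf`; the anchored threshold point is highlighted.
#'
#' @param object A `rupture_fit` from [fit_critical_strain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rupture_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble::tibble(Wi = seq(min(pts$Wi), max(pts$Wi), length.out = 200))
  grid$gamma_c <- predict(object, grid)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$Wi, y = .data$gamma_c)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = pts[1, ], shape = 21, size = 3,
                        fill = "gold") +
    ggplot2::geom_hline(yintercept = object$gamma_inf, linetype = "dotted") +
    ggplot2::labs(x = "Wi", y = expression(gamma[c])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL
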