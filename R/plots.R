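#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   labs coord_polar facet_wrap
NULL

#' Plot an amplitude profile
#'
#' Relative radius against angle, with the unit circle as reference; peaks
#' in this curve are what the bumpiness metric counts.
#'
#' @param object An `amplitude_profile`.
#' @param polar Draw in polar coordinates?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amplitude_profile <- function(object, polar = FALSE, ...) {
  p <- ggplot(object, aes(x = .data$angle, y = .data$value)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    geom_line() +
    labs(x = "angle (deg, clockwise from +x)", y = "relative radius",
         title = if (!is.null(attr(object, "altitude")) &&
                     !is.na(attr(object, "altitude")))
           paste("amplitude profile,", attr(object, "altitude")) else
             "amplitude profile")
  if (polar) p <- p + coord_polar()
  p
}

#' Plot per-focal-adhesion reaction forces against radial position
#'
#' @param object An `fa_force_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fa_force_report <- function(object, ...) {
  ggplot(object, aes(x = .data$radial_position, y = .data$fmag,
                     colour = .data$class)) +
    geom_point() +
    labs(x = "radial position (um)", y = "reaction force magnitude (pN)",
         colour = NULL, title = "focal-adhesion reaction forces")
}

#' Plot a cap comparison
#'
#' Reaction-force radial profiles of the cap-present and cap-absent solves
#' side by side.
#'
#' @param object A `cap_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cap_comparison <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$fa_with), cap = "with cap"),
    dplyr::mutate(tibble::as_tibble(object$fa_without), cap = "without cap"))
  ggplot(d, aes(x = .data$radial_position, y = .data$fmag,
                colour = .data$class)) +
    geom_point() +
    facet_wrap(~cap) +
    labs(x = "radial position (um)", y = "reaction force magnitude (pN)",
         colour = NULL)
}
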