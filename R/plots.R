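# ggplot2 views of the result types. These return ggplot objects; nothing
# is printed or written to disk.

#' Plot a fitted Hill curve over its data
#'
#' @param object A [fit_hill()] result.
#' @param n Curve resolution (default 200 points).
#' @param ... Unused.
#' @return A ggplot: observed points and the fitted curve on a log dose
#'   axis.
#' @export
autoplot.hill_fit <- function(object, n = 200, ...) {
  dat <- object$data
  pos <- dat$dose[dat$dose > 0]
  dd <- 10^seq(log10(min(pos)) - 0.3, log10(max(pos)) + 0.3, length.out = n)
  line <- tibble::tibble(dose = dd, effect = hill_effect(dd, object$curve))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose, y = .data$effect)) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (log scale)", y = "effect fraction",
                  title = sprintf("%s: emax = %.3g, d50 = %.3g, slope = %.3g",
                                  object$curve$label, object$curve$emax,
                                  object$curve$d50, object$curve$slope))
}

#' Plot an isobole in scaled-dose coordinates
#'
#' @param object An [isobole()] result.
#' @param ... Unused.
#' @return A ggplot of `m_b` against `m_a` at the stored effect level.
#' @export
autoplot.isobole <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$m_a, y = .data$m_b)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "scaled dose of agent A (m_a)", y = "scaled dose of agent B (m_b)",
      title = sprintf("%s isobole at effect %.3g",
                      attr(object, "method"), attr(object, "level"))
    )
}

#' Plot a difference grid between two reference surfaces
#'
#' @param object A [difference_grid()] result.
#' @param ... Unused.
#' @return A ggplot raster + contours of `u_A - u_B` over the two dose
#'   axes (log scale).
#' @export
autoplot.difference_grid <- function(object, ...) {
  dc <- grep("^dose_", names(object), value = TRUE)[1:2]
  mth <- attr(object, "methods")
  df <- object[object[[dc[1]]] > 0 & object[[dc[2]]] > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[dc[1]]], y = .data[[dc[2]]],
                                   fill = .data$diff)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$diff),
                          colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred", midpoint = 0) +
    ggplot2::labs(fill = sprintf("%s - %s", mth[1], mth[2]),
                  title = "Difference between reference surfaces")
}
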