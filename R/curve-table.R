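#' Construct a curve table
#'
#' The generic observable container used across the package: one row per
#' measured point, with the independent variable `x` (units depend on
#' `kind`), the observable `y`, a per-point standard deviation `sigma`
#' (0 for noise-free model curves) and the condition metadata. Synthetic
#' datasets additionally carry their generator seed and configuration as
#' attributes.
#'
#' @param x,y,sigma Equal-length numeric vectors.
#' @param kind Curve kind, e.g. `"chem_denaturation"`, `"chevron"`,
#'   `"melt"`, `"dsc"`, `"titration"`, `"velocity"`.
#' @param C_tot,T,P_tot Condition metadata (recycled).
#' @param series Series label (recycled), default `"1"`.
#' @param seed,config Generator provenance (stored as attributes).
#' @return A tibble of class `curve_table`.
#' @export
curve_table <- function(x, y, sigma = 0, kind = "curve",
                        C_tot = NA_real_, T = NA_real_, P_tot = NA_real_,
                        series = "1", seed = NULL, config = NULL) {
  stopifnot(length(x) == length(y))
  out <- tibble(x = x, y = y, sigma = sigma, kind = kind,
                C_tot = C_tot, T = T, P_tot = P_tot,
                series = as.character(series))
  class(out) <- c("curve_table", class(out))
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  out
}

#' @export
print.curve_table <- function(x, ...) {
  kinds <- unique(x$kind)
  cat(sprintf("<curve_table: %d points, kind %s, %d series>\n",
              nrow(x), paste(kinds, collapse = "/"),
              length(unique(x$series))))
  if (!is.null(attr(x, "seed")))
    cat(sprintf("  generator seed: %s\n", attr(x, "seed")))
  NextMethod()
}

#' Plot a curve table
#'
#' Points (with error bars where `sigma > 0`) coloured by series,
#' faceted by curve kind when mixed.
#'
#' @param object A [curve_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.curve_table <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = .data$series)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "x", y = "signal")
  if (any(object$sigma > 0, na.rm = TRUE))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$sigma,
                   ymax = .data$y + .data$sigma),
      width = 0, alpha = 0.5)
  if (length(unique(object$kind)) > 1L)
    p <- p + ggplot2::facet_wrap(~kind, scales = "free")
  p + ggplot2::theme_minimal()
}
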