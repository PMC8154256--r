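# broom-style tidiers, ggplot2 autoplot methods and print methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a KDE into an (x, density) tibble
#'
#' @param x A `kde_pdf`.
#' @param ... Unused.
#' @return A tibble with columns `x` and `density`.
#' @method tidy kde_pdf
#' @export
tidy.kde_pdf <- function(x, ...) {
  centers <- x$grid$centers
  dens <- x$pdf
  tibble(x = centers, density = dens)
}

#' One-row summary of a KDE fit
#'
#' @param x A `kde_pdf`.
#' @param ... Unused.
#' @return A one-row tibble: grid bounds, resolution, bandwidth (`h`, data
#'   units), squared bandwidths, convergence flag, sample counts.
#' @method glance kde_pdf
#' @export
glance.kde_pdf <- function(x, ...) {
  tibble(lower = x$grid$lower, upper = x$grid$upper,
         resolution = x$grid$resolution, spacing = x$grid$spacing,
         bandwidth = x$bandwidth$h, t_data = x$bandwidth$t_data,
         t_unit = x$bandwidth$t_unit, bw_converged = x$bandwidth$converged,
         normalization_applied = x$normalization_applied,
         n_samples = x$n_samples, n_effective = x$n_effective)
}

#' Tidy an entropy estimate
#'
#' @param x An `entropy_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with `label`, `entropy` (J/(mol K)) and `units`.
#' @method tidy entropy_estimate
#' @export
tidy.entropy_estimate <- function(x, ...) {
  tibble(label = x$label, entropy = x$value, units = "J/(mol K)")
}

#' One-row diagnostic summary of an entropy estimate
#'
#' @param x An `entropy_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the entropy, quadrature rule, resolution,
#'   bandwidth and convergence flag.
#' @method glance entropy_estimate
#' @export
glance.entropy_estimate <- function(x, ...) {
  tibble(entropy = x$value,
         integration_rule = x$integration_rule,
         resolution = x$density$grid$resolution,
         bandwidth = x$density$bandwidth$h,
         bw_converged = x$density$bandwidth$converged,
         n_samples = x$n_samples %||% NA_integer_)
}

#' @method tidy kde_bandwidth
#' @export
tidy.kde_bandwidth <- function(x, ...) {
  tibble(t_unit = x$t_unit, t_data = x$t_data, h = x$h,
         converged = x$converged, residual = x$residual, n_used = x$n_used)
}

#' Plot a KDE
#'
#' @param object A `kde_pdf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kde_pdf
#' @export
autoplot.kde_pdf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x", y = "density",
                  subtitle = sprintf("r = %d, h = %.4g%s",
                                     object$grid$resolution, object$bandwidth$h,
                                     if (isFALSE(object$bandwidth$converged))
                                       " (bandwidth fallback)" else ""))
}

#' Plot the density underlying an entropy estimate
#'
#' @param object An `entropy_estimate`.
#' @param ... Unused.
#' @return A ggplot object annotated with the entropy value.
#' @method autoplot entropy_estimate
#' @export
autoplot.entropy_estimate <- function(object, ...) {
  autoplot(object$density) +
    ggplot2::labs(title = sprintf("S = %.3f J/(mol K)%s", object$value,
                                  if (nzchar(object$label))
                                    paste0("  [", object$label, "]") else ""))
}

#' Plot residuewise entropies along the sequence
#'
#' @param object A [residuewise_entropy()] tibble.
#' @param ... Unused.
#' @return A ggplot object (combined entropy per residue).
#' @method autoplot residuewise_entropy
#' @export
autoplot.residuewise_entropy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue_index,
                                       y = .data$combined)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue", y = "combined dihedral entropy [J/(mol K)]")
}

#' @export
print.kde_grid <- function(x, ...) {
  cat(sprintf("<kde_grid> [%g, %g), %d bins (spacing %.6g), kind '%s'\n",
              x$lower, x$upper, x$resolution, x$spacing, x$kind))
  invisible(x)
}

#' @export
print.binned_1d <- function(x, ...) {
  cat(sprintf("<binned_1d> %d samples (total weight %.6g, n_eff %.6g) on %d bins\n",
              x$n_samples, x$total_weight, x$n_effective, x$grid$resolution))
  invisible(x)
}

#' @export
print.kde_bandwidth <- function(x, ...) {
  cat(sprintf("<kde_bandwidth> h = %.6g (t = %.6g data units; t_unit = %.4g), %s\n",
              x$h, x$t_data, x$t_unit,
              if (isTRUE(x$converged)) "converged"
              else if (isFALSE(x$converged)) "NOT converged (scan fallback)"
              else "manual"))
  invisible(x)
}

#' @export
print.kde_pdf <- function(x, ...) {
  cat(sprintf("<kde_pdf> %d points on [%g, %g), h = %.6g\n",
              x$grid$resolution, x$grid$lower, x$grid$upper, x$bandwidth$h))
  invisible(x)
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate>%s S = %.4f J/(mol K) (%s rule, r = %d, h = %.4g)\n",
              if (nzchar(x$label)) paste0(" ", x$label, ":") else "",
              x$value, x$integration_rule, x$density$grid$resolution,
              x$density$bandwidth$h))
  invisible(x)
}

#' @export
print.fixture_1d <- function(x, ...) {
  cat(sprintf("<fixture_1d> %s, n = %d, true entropy %.4f J/(mol K)\n",
              x$kind, length(x$values), x$true_entropy))
  invisible(x)
}
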