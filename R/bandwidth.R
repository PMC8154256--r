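# Plug-in ("improved Sheather-Jones" style) bandwidth selection on binned
# data, via the diffusion fixed-point equation of Botev, Grotowski and
# Kroese solved in the cosine-transform domain of the unit interval.

BW_STAGES <- 7L          # depth of the derivative-functional recursion
BW_T_MIN <- 1e-12        # root bracket, squared bandwidth on the unit interval
BW_T_MAX <- 0.1
BW_SCAN_POINTS <- 400L   # log-spaced bracketing scan

fp_residual_scalar <- function(t, n_used, a) {
  r <- length(a)
  I <- (seq_len(r - 1L))^2
  a2 <- (a[-1L] / 2)^2
  l <- BW_STAGES
  f <- 2 * pi^(2 * l) * sum(I^l * a2 * exp(-I * pi^2 * t))
  for (s in (l - 1L):2L) {
    k0 <- prod(seq(1, 2 * s - 1, 2)) / sqrt(2 * pi)
    cst <- (1 + (1 / 2)^(s + 1 / 2)) / 3
    t_s <- (2 * cst * k0 / (n_used * f))^(2 / (3 + 2 * s))
    f <- 2 * pi^(2 * s) * sum(I^s * a2 * exp(-I * pi^2 * t_s))
  }
  t - (2 * n_used * sqrt(pi) * f)^(-2 / 5)
}

#' Fixed-point residual of the plug-in bandwidth equation
#'
#' The dimensionless residual whose root is the optimal squared bandwidth
#' `t` on the unit interval. Starting from the highest-order density
#' derivative functional estimated from the cosine coefficients, each stage
#' plugs the previous functional into the asymptotically optimal pilot
#' bandwidth for the next-lower derivative; the residual is
#' `t - (2 N sqrt(pi) f_2(t))^(-2/5)`. Exposed so the root can be checked
#' by brute-force scanning, independently of the solver.
#'
#' @param t Positive squared bandwidth(s) on the unit interval.
#' @param n_used Effective number of observations.
#' @param dct_coeffs Full DCT-II coefficient vector of the normalized bin
#'   frequencies (including the k = 0 term).
#' @return Residual value(s), same length as `t`.
#' @export
fixed_point_residual <- function(t, n_used, dct_coeffs) {
  if (length(dct_coeffs) < 2L) abort("`dct_coeffs` must have length >= 2.")
  if (any(!is.finite(t)) || any(t <= 0)) abort("`t` must be positive.")
  if (length(n_used) != 1L || !is.finite(n_used) || n_used <= 0)
    abort("`n_used` must be a single positive number.")
  vapply(t, fp_residual_scalar, numeric(1), n_used = n_used, a = dct_coeffs)
}

#' Select the KDE bandwidth by the plug-in fixed-point method
#'
#' Normalizes the bin masses to frequencies, takes their type-II discrete
#' cosine transform, and root-finds the plug-in fixed-point residual for
#' the squared bandwidth `t` on the unit interval. The root is bracketed on
#' a log-spaced scan of (1e-12, 0.1] and refined with [stats::uniroot()];
#' if no sign change is found, the scan minimizer of |residual| is used and
#' `converged` is set to `FALSE` (with a warning).
#'
#' @param binned A `binned_1d` object with at least two occupied bins.
#' @param n_used Override for the effective sample count (used by the
#'   periodic dihedral pipeline, where samples are replicated but the
#'   bandwidth must see the original count). Defaults to the Kish effective
#'   sample size of `binned`.
#' @return A `kde_bandwidth` object: `t_unit` (squared bandwidth on the
#'   unit interval), `t_data` (= `t_unit * (upper - lower)^2`), `h`
#'   (= `sqrt(t_data)`, the kernel standard deviation in data units),
#'   `converged`, `residual`, `n_used`, and the grid signature.
#' @export
select_bandwidth <- function(binned, n_used = NULL) {
  if (!inherits(binned, "binned_1d")) abort("`binned` must be a `binned_1d`.")
  if (sum(binned$bin_mass > 0) < 2L)
    abort("all mass falls in a single bin: zero-variance data have no bandwidth.")
  n_used <- n_used %||% binned$n_effective
  if (length(n_used) != 1L || !is.finite(n_used) || n_used < 2)
    abort("`n_used` must be >= 2: too few observations for bandwidth selection.")

  p <- binned$bin_mass / binned$total_weight
  a <- dct2(p)
  g <- function(t) fp_residual_scalar(t, n_used, a)

  tgrid <- 10^seq(log10(BW_T_MIN), log10(BW_T_MAX), length.out = BW_SCAN_POINTS)
  gv <- vapply(tgrid, g, numeric(1))
  ok <- is.finite(gv)
  cross <- which(ok[-length(gv)] & ok[-1] &
                   gv[-length(gv)] * gv[-1] <= 0)
  if (length(cross) > 0L) {
    i <- cross[1L]
    t_star <- uniroot(g, lower = tgrid[i], upper = tgrid[i + 1L],
                      tol = .Machine$double.eps^0.75)$root
    converged <- TRUE
  } else {
    t_star <- tgrid[ok][which.min(abs(gv[ok]))]
    converged <- FALSE
    warn("plug-in fixed point did not bracket a sign change; using the scan minimizer of |residual|.")
  }

  rng <- binned$grid$upper - binned$grid$lower
  structure(
    list(t_unit = t_star,
         t_data = t_star * rng^2,
         h = sqrt(t_star) * rng,
         converged = converged,
         residual = g(t_star),
         n_used = n_used,
         grid_lower = binned$grid$lower,
         grid_upper = binned$grid$upper,
         grid_resolution = binned$grid$resolution),
    class = "kde_bandwidth")
}

#' Construct a bandwidth object with a given kernel width
#'
#' Mainly for reference evaluations and tests where the bandwidth is known
#' a priori rather than selected from data.
#'
#' @param grid The `kde_grid` the bandwidth refers to.
#' @param t_data Squared bandwidth in data units (give this or `h`).
#' @param h Kernel standard deviation in data units.
#' @return A `kde_bandwidth` object (with `converged = NA`).
#' @export
manual_bandwidth <- function(grid, t_data = NULL, h = NULL) {
  if (!inherits(grid, "kde_grid")) abort("`grid` must be a `kde_grid`.")
  if (is.null(t_data) && is.null(h)) abort("give `t_data` or `h`.")
  if (!is.null(h)) t_data <- h^2
  if (length(t_data) != 1L || !is.finite(t_data) || t_data <= 0)
    abort("`t_data` must be a single positive number.")
  rng <- grid$upper - grid$lower
  structure(
    list(t_unit = t_data / rng^2, t_data = t_data, h = sqrt(t_data),
         converged = NA, residual = NA_real_, n_used = NA_real_,
         grid_lower = grid$lower, grid_upper = grid$upper,
         grid_resolution = grid$resolution),
    class = "kde_bandwidth")
}
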