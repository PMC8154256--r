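# Dihedral (periodic) entropy pipeline. Dihedrals live on [-180, 180)
# degrees and are periodic; periodicity is honored by replicating every
# sample at x - 360 and x + 360, smoothing on the triple window
# [-540, 540), and renormalizing the central period. The bandwidth
# selection sees the original (un-replicated) effective sample count, so
# replication does not shrink the kernel artificially.

#' Periodic KDE of a dihedral-angle sample
#'
#' Wraps the angles, replicates them once per neighboring period, smooths
#' on \[-540, 540) with 3x the chosen resolution, and returns the density
#' restricted to the central \[-180, 180) window, renormalized to unit
#' probability there. The density is per degree.
#'
#' @param angles Angles in degrees (wrapped into \[-180, 180) internally).
#' @param weights Optional positive per-frame weights.
#' @param resolution `"auto"` (4096 bins for >= 1e4 frames, halving to a
#'   floor of 512 for smaller samples) or a power-of-two bin count for the
#'   central window.
#' @param label Free-text identifier.
#' @return A `kde_pdf` on \[-180, 180) degrees.
#' @export
dihedral_density <- function(angles, weights = NULL, resolution = "auto",
                             label = "") {
  check_values(angles)
  check_weights(weights, length(angles))
  a <- wrap_degrees(angles)
  n <- length(a)

  r <- if (identical(resolution, "auto"))
    choose_resolution(n, "dihedral", "auto")
  else check_resolution(resolution)

  n_eff <- if (is.null(weights)) as.numeric(n)
  else sum(weights)^2 / sum(weights^2)
  if (n_eff < 2) abort("need an effective sample size of at least 2.")

  xr <- c(a - 360, a, a + 360)
  wr <- if (!is.null(weights)) rep(weights, 3L)

  grid3 <- new_grid(-540, 540, 3L * r, kind = "dihedral_extended")
  binned <- bin_samples(xr, grid3, wr, label = label)
  bw <- select_bandwidth(binned, n_used = n_eff)
  dens <- estimate_density(binned, bw)

  central <- (r + 1L):(2L * r)
  grid_c <- new_grid(-180, 180, r, kind = "dihedral")
  pdf <- dens$pdf[central]
  pdf <- pdf / (sum(pdf) * grid_c$spacing)

  new_kde_pdf(grid_c, pdf, bw, normalization_applied = TRUE,
              n_samples = n, n_effective = n_eff)
}

#' Entropy of one dihedral-angle time series
#'
#' Periodic KDE (see [dihedral_density()]) followed by entropy integration
#' over one period, with the integration variable expressed in radians, so
#' that a uniform circular distribution gives `R * log(2 pi)` (about
#' 15.28 J/(mol K)). The radian convention fixes only an additive constant;
#' entropy differences are unaffected by it.
#'
#' @inheritParams dihedral_density
#' @param integration Quadrature rule for the entropy integral.
#' @return An `entropy_estimate` whose stored density is on radians.
#' @examples
#' set.seed(1)
#' th <- runif(2e4, -180, 180)
#' dihedral_entropy(th)$value  # close to R * log(2 * pi)
#' @export
dihedral_entropy <- function(angles, weights = NULL, resolution = "auto",
                             integration = c("simpson", "trapezoid"),
                             label = "") {
  integration <- match.arg(integration)
  dens <- dihedral_density(angles, weights, resolution, label = label)
  drad <- rescale_pdf(dens, pi / 180)
  out <- integrate_entropy(drad, integration, label = label)
  out$angular_unit <- "radian"
  out$n_samples <- dens$n_samples
  out
}

#' Residuewise backbone-dihedral entropies
#'
#' Groups dihedral series by residue, computes each series' periodic
#' entropy independently, and sums the per-dihedral entropies within each
#' residue (e.g. phi + psi). The per-residue sum is the residuewise
#' flexibility measure typically projected onto a structure.
#'
#' @param data A long table of dihedral observations, as returned by
#'   [read_dihedral_table()]: columns `frame`, `dihedral` (series name
#'   within the residue, e.g. `"phi"`), `residue_index`, optionally
#'   `residue_name`, and `angle` (degrees).
#' @param weights Optional per-frame weights, shared by all series.
#' @param resolution Passed to [dihedral_entropy()].
#' @return A tibble with one row per residue, ordered by `residue_index`:
#'   `residue_index`, `residue_name`, one column per dihedral name, and
#'   `combined` (their sum).
#' @export
residuewise_entropy <- function(data, weights = NULL, resolution = "auto") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  needed <- c("frame", "dihedral", "residue_index", "angle")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L)
    abort(sprintf("`data` lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  if (any(is.na(data$residue_index)))
    abort("all series need residue metadata (`residue_index` has NAs).")
  if (!"residue_name" %in% names(data)) data$residue_name <- NA_character_

  dup <- data |>
    dplyr::count(.data$residue_index, .data$dihedral, .data$frame) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L)
    abort(sprintf("duplicate dihedral name '%s' within residue %d.",
                  dup$dihedral[1L], dup$residue_index[1L]))

  per_series <- data |>
    dplyr::group_by(.data$residue_index, .data$residue_name, .data$dihedral) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      entropy = dihedral_entropy(.data$angle, weights = weights,
                                 resolution = resolution)$value,
      .groups = "drop")

  dihedral_names <- unique(per_series$dihedral)
  wide <- per_series |>
    tidyr::pivot_wider(names_from = "dihedral", values_from = "entropy") |>
    dplyr::mutate(combined = rowSums(dplyr::across(dplyr::all_of(dihedral_names)),
                                     na.rm = TRUE)) |>
    dplyr::arrange(.data$residue_index)

  class(wide) <- c("residuewise_entropy", class(wide))
  attr(wide, "dihedral_names") <- dihedral_names
  wide
}
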