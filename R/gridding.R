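# Resolution selection, grid construction and binning: the discretization
# stage that precedes the spectral KDE.

is_pow2 <- function(x) {
  x <- as.numeric(x)
  length(x) == 1L && is.finite(x) && x >= 1 && x == 2^round(log2(x))
}

next_pow2 <- function(x) as.integer(2^ceiling(log2(as.numeric(x))))

RESOLUTION_MIN <- 32L     # 2^5
RESOLUTION_MAX <- 8192L   # 2^13
DIHEDRAL_RES_MAX <- 4096L # default for large dihedral datasets
DIHEDRAL_RES_MIN <- 512L

# Validate a user-requested resolution; non-powers of two are rounded up
# (with a notice) because the spectral smoother wants clean transform sizes.
check_resolution <- function(resolution) {
  if (length(resolution) != 1L || !is.finite(resolution) || resolution < 2)
    abort("`resolution` must be a single number >= 2 or \"auto\".")
  if (!is_pow2(resolution)) {
    r2 <- next_pow2(resolution)
    warn(sprintf("resolution %s is not a power of two; rounding up to %d.",
                 format(resolution), r2))
    return(r2)
  }
  as.integer(resolution)
}

#' Choose the histogram resolution for a binned KDE
#'
#' Picks the number of bins ("resolution") used to discretize the sample
#' before spectral smoothing. Generic data use classical histogram rules of
#' thumb rounded up to the next power of two and clamped to \[2^5, 2^13\];
#' dihedral data use a dedicated schedule: 4096 bins for datasets of at
#' least 10^4 frames, halving for smaller datasets down to a floor of 512.
#'
#' @param n_samples Number of observations (>= 1).
#' @param data_kind `"generic"` or `"dihedral"`.
#' @param rule Resolution rule: `"auto"` (Rice rule for generic data, the
#'   dihedral schedule for dihedral data), `"sturges"`, `"rice"`, `"sqrt"`,
#'   or `"fixed"` (use `fixed_value`).
#' @param fixed_value Required when `rule = "fixed"`: a power-of-two bin
#'   count.
#' @return An integer power of two.
#' @examples
#' choose_resolution(2e5, "dihedral")        # 4096
#' choose_resolution(1e6, rule = "rice")     # 256
#' @export
choose_resolution <- function(n_samples,
                              data_kind = c("generic", "dihedral"),
                              rule = c("auto", "sturges", "rice", "sqrt", "fixed"),
                              fixed_value = NULL) {
  data_kind <- match.arg(data_kind)
  rule <- match.arg(rule)
  if (length(n_samples) != 1L || !is.finite(n_samples) || n_samples < 1)
    abort("`n_samples` must be a single finite number >= 1.")
  n <- floor(n_samples)

  if (rule == "fixed") {
    if (is.null(fixed_value))
      abort("`fixed_value` is required when rule = \"fixed\".")
    if (!is_pow2(fixed_value))
      abort(sprintf(
        "`fixed_value` (%s) must be a power of two; use e.g. %d.",
        format(fixed_value), next_pow2(fixed_value)))
    r <- as.integer(fixed_value)
    if (r < RESOLUTION_MIN || r > RESOLUTION_MAX) {
      r <- min(RESOLUTION_MAX, max(RESOLUTION_MIN, r))
      warn(sprintf("fixed resolution clamped to %d.", r))
    }
    return(r)
  }
  if (!is.null(fixed_value))
    abort("`fixed_value` is only meaningful with rule = \"fixed\".")

  if (data_kind == "dihedral" && rule == "auto") {
    r <- DIHEDRAL_RES_MAX
    if (n < 1e4) r <- DIHEDRAL_RES_MAX / 2^ceiling(log2(1e4 / n))
    return(as.integer(min(DIHEDRAL_RES_MAX, max(DIHEDRAL_RES_MIN, r))))
  }

  k <- switch(rule,
    auto = ,
    rice = ceiling(2 * n^(1 / 3)),
    sturges = ceiling(log2(n)) + 1,
    sqrt = ceiling(sqrt(n)))
  as.integer(min(RESOLUTION_MAX, max(RESOLUTION_MIN, next_pow2(k))))
}

#' Wrap angles into \[-180, 180) degrees
#'
#' Dihedral angles are periodic; values outside the principal range (for
#' instance the occasional 180.0 emitted by trajectory tools) are wrapped by
#' modular arithmetic rather than rejected.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into \[-180, 180).
#' @export
wrap_degrees <- function(x) {
  ((x + 180) %% 360) - 180
}

# internal grid constructor (no power-of-two restriction: the periodic
# pipeline uses 3 * r bins on the triple window)
new_grid <- function(lower, upper, resolution, kind = "generic") {
  resolution <- as.integer(resolution)
  spacing <- (upper - lower) / resolution
  structure(
    list(lower = lower, upper = upper, resolution = resolution,
         spacing = spacing,
         centers = lower + (seq_len(resolution) - 0.5) * spacing,
         kind = kind),
    class = "kde_grid")
}

#' Build a uniform evaluation grid for a sample
#'
#' Generic data get a grid spanning the sample range padded by
#' `pad_fraction` on each side (default 10%), which keeps the data away
#' from the reflective boundaries of the cosine-transform smoother.
#' Dihedral data always use exactly \[-180, 180) degrees.
#'
#' @param values Numeric sample (finite, non-empty).
#' @param resolution Number of bins; a power of two (other values are
#'   rounded up with a notice).
#' @param data_kind `"generic"` or `"dihedral"`.
#' @param pad_fraction Non-negative padding fraction per side (generic data).
#' @return A `kde_grid` object with fields `lower`, `upper`, `resolution`,
#'   `spacing` and bin `centers`.
#' @export
make_grid <- function(values, resolution,
                      data_kind = c("generic", "dihedral"),
                      pad_fraction = 0.1) {
  data_kind <- match.arg(data_kind)
  resolution <- check_resolution(resolution)
  if (data_kind == "dihedral")
    return(new_grid(-180, 180, resolution, kind = "dihedral"))

  check_values(values)
  if (length(pad_fraction) != 1L || !is.finite(pad_fraction) || pad_fraction < 0)
    abort("`pad_fraction` must be a single non-negative number.")
  lo <- min(values)
  hi <- max(values)
  rng <- hi - lo
  if (rng <= 0)
    abort("all values are identical: the data have no scale, so no density grid can be built.")
  new_grid(lo - pad_fraction * rng, hi + pad_fraction * rng, resolution,
           kind = "generic")
}

check_values <- function(values) {
  if (length(values) == 0L) abort("`values` must be non-empty.")
  if (!is.numeric(values)) abort("`values` must be numeric.")
  if (any(!is.finite(values)))
    abort(sprintf("`values` contains non-finite entries (first at index %d).",
                  which(!is.finite(values))[1L]))
  invisible(values)
}

check_weights <- function(weights, n) {
  if (is.null(weights)) return(invisible(NULL))
  if (!is.numeric(weights) || length(weights) != n)
    abort(sprintf("`weights` must be numeric of length %d (got %d).",
                  n, length(weights)))
  if (any(!is.finite(weights)) || any(weights <= 0))
    abort("`weights` must all be finite and > 0.")
  invisible(weights)
}

#' Bin a (possibly weighted) sample onto a grid
#'
#' Each observation contributes its weight (1 when unweighted) to the bin
#' containing it. Bins are half-open `[edge_k, edge_{k+1})` with the final
#' bin closed; a value exactly on an interior edge goes to the right-hand
#' bin. On dihedral grids the values are wrapped into \[-180, 180) first.
#'
#' For weighted data the Kish effective sample size
#' `(sum w)^2 / sum(w^2)` is recorded; it replaces the raw count during
#' bandwidth selection.
#'
#' @param values Numeric sample.
#' @param grid A `kde_grid` from [make_grid()].
#' @param weights Optional positive per-observation weights.
#' @param label Free-text identifier carried through to results.
#' @return A `binned_1d` object: `grid`, `bin_mass`, `n_samples`,
#'   `total_weight`, `n_effective`, `label`.
#' @export
bin_samples <- function(values, grid, weights = NULL, label = "") {
  if (!inherits(grid, "kde_grid")) abort("`grid` must be a `kde_grid`.")
  check_values(values)
  check_weights(weights, length(values))

  x <- values
  if (identical(grid$kind, "dihedral")) x <- wrap_degrees(x)

  below <- x < grid$lower
  above <- x > grid$upper
  if (any(below) || any(above)) {
    idx <- which(below | above)[1L]
    abort(sprintf("value %g (index %d) lies outside the grid [%g, %g].",
                  x[idx], idx, grid$lower, grid$upper))
  }

  r <- grid$resolution
  bin <- floor((x - grid$lower) / grid$spacing) + 1
  bin[bin > r] <- r  # upper boundary: final bin is closed
  bin <- as.integer(bin)

  if (is.null(weights)) {
    bin_mass <- as.numeric(tabulate(bin, nbins = r))
    total_weight <- length(x)
    n_effective <- as.numeric(length(x))
  } else {
    bin_mass <- numeric(r)
    agg <- rowsum(weights, group = bin)
    bin_mass[as.integer(rownames(agg))] <- agg[, 1L]
    total_weight <- sum(weights)
    n_effective <- total_weight^2 / sum(weights^2)
  }

  structure(
    list(grid = grid, bin_mass = bin_mass,
         n_samples = length(x), total_weight = total_weight,
         n_effective = n_effective, label = label),
    class = "binned_1d")
}
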