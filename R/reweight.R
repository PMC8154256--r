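# Accelerated-MD reweighting: per-frame boost potentials are converted
# into KDE weights via a truncated Maclaurin expansion of exp(beta * dV),
# the standard noise-robust alternative to exponential reweighting.

#' Maclaurin-series frame weights for accelerated-MD data
#'
#' Computes `w_i = sum_{k=0}^{order} (beta * dV_i)^k / k!`, the Maclaurin
#' expansion of `exp(beta * dV_i)` truncated at `order` (default 10). The
#' weights are returned unnormalized; binning normalizes them. `order = 0`
#' gives unit weights, i.e. the unweighted estimate.
#'
#' @param delta_v Non-negative per-frame boost potentials in kcal/mol.
#' @param temperature Simulation temperature in K (default 300).
#' @param beta Inverse temperature in (kcal/mol)^-1. Defaults to
#'   `1 / (k_B * temperature)` with `k_B = 0.0019872041` kcal/(mol K); if
#'   both `beta` and `temperature` are supplied they must agree.
#' @param order Truncation order (non-negative integer, default 10).
#' @return Numeric vector of positive weights, monotone in `delta_v`.
#' @examples
#' maclaurin_weights(0)                      # 1
#' maclaurin_weights(1, beta = 1)            # sum_{k<=10} 1/k! = 2.7182818...
#' @export
maclaurin_weights <- function(delta_v, temperature = 300, beta = NULL,
                              order = 10) {
  if (length(delta_v) == 0L || !is.numeric(delta_v))
    abort("`delta_v` must be a non-empty numeric vector.")
  if (any(!is.finite(delta_v)))
    abort("`delta_v` contains non-finite entries.")
  if (any(delta_v < 0))
    abort(sprintf("boost potentials must be non-negative (first negative at index %d).",
                  which(delta_v < 0)[1L]))
  if (length(order) != 1L || !is.finite(order) || order < 0 ||
      order != round(order))
    abort("`order` must be a non-negative integer.")

  if (is.null(beta)) {
    if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0)
      abort("`temperature` must be a single positive number (K).")
    beta <- 1 / (KB_KCAL * temperature)
  } else {
    if (length(beta) != 1L || !is.finite(beta) || beta <= 0)
      abort("`beta` must be a single positive number.")
    if (!missing(temperature) &&
        abs(beta - 1 / (KB_KCAL * temperature)) > 1e-9 * beta)
      abort("`beta` and `temperature` disagree; supply one or the other.")
  }

  bdv <- beta * delta_v
  w <- rep(1, length(bdv))
  term <- rep(1, length(bdv))
  for (k in seq_len(order)) {
    term <- term * bdv / k
    w <- w + term
  }
  w
}

#' Read per-frame boost potentials from a plain-text file
#'
#' Accepts a one-column file of boost potentials, or a two-column
#' (frame, dV) file; columns may be whitespace- or comma-separated, with
#' an optional '#'-prefixed header.
#'
#' @param path File path.
#' @return A tibble with columns `frame` and `delta_v` (kcal/mol).
#' @export
read_boost_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("boost file '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) abort(sprintf("boost file '%s' is empty.", path))
  sep_split <- function(l) strsplit(trimws(l), "[,[:space:]]+")[[1L]]
  parts <- lapply(lines, sep_split)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1L)
    abort(sprintf("ragged boost file '%s': rows have %s fields.",
                  path, paste(sort(ncol), collapse = " and ")))
  vals <- suppressWarnings(matrix(as.numeric(unlist(parts)),
                                  ncol = ncol, byrow = TRUE))
  if (any(is.na(vals))) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    abort(sprintf("non-numeric value in boost file '%s' at data line %d.",
                  path, bad))
  }
  if (ncol == 1L) {
    tibble(frame = seq_len(nrow(vals)), delta_v = vals[, 1L])
  } else if (ncol == 2L) {
    tibble(frame = as.integer(vals[, 1L]), delta_v = vals[, 2L])
  } else {
    abort(sprintf("boost file '%s' must have 1 or 2 columns (got %d).",
                  path, ncol))
  }
}
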