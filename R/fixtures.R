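# Synthetic-data generators. These define the simulated study conditions
# used throughout the test-suite: Gaussian and mixture samples with known
# entropies, von Mises angles for the periodic pipeline, and a biased
# dihedral ensemble with per-frame boost potentials for end-to-end
# reweighting checks. True entropies are always computed from the analytic
# density (closed form or adaptive quadrature), never through the KDE.

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

vm_log_density <- function(theta, mu, kappa) {
  kappa * cos(theta - mu) - log(2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) - kappa
}

vm_mixture_density <- function(theta, weights, mu, kappa) {
  d <- 0
  for (j in seq_along(weights))
    d <- d + weights[j] * exp(vm_log_density(theta, mu[j], kappa[j]))
  d
}

# rejection sampler against a uniform envelope on the circle
r_von_mises <- function(n, mu, kappa) {
  out <- numeric(0L)
  rate <- besselI(kappa, 0, expon.scaled = TRUE)  # = I0(k) e^-k, accept rate
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / rate * 1.3) + 50L
    th <- runif(m, -pi, pi)
    u <- runif(m)
    out <- c(out, th[u < exp(kappa * (cos(th - mu) - 1))])
  }
  out[seq_len(n)]
}

entropy_by_quadrature <- function(density_fn, lower, upper) {
  f <- function(x) {
    p <- density_fn(x)
    ifelse(p > 0, -p * log(p), 0)
  }
  GAS_CONSTANT * integrate(f, lower, upper, rel.tol = 1e-12,
                           subdivisions = 500L)$value
}

#' Generate a synthetic 1D sample with known entropy
#'
#' Deterministic given `seed`. Gaussian and uniform fixtures carry their
#' closed-form differential entropy; Gaussian-mixture and von Mises
#' fixtures carry a true entropy obtained by adaptive quadrature of
#' `-R p log p` on the analytic density, so the reference is independent of
#' the KDE path. Von Mises angles are returned in degrees in \[-180, 180)
#' with the true entropy in the radian convention used by
#' [dihedral_entropy()].
#'
#' @param kind `"gaussian"`, `"mixture"` (of Gaussians), `"uniform"`, or
#'   `"von_mises"`.
#' @param n Number of observations.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param mean,sd Gaussian parameters.
#' @param means,sds,mixture_weights Mixture parameters; weights must sum
#'   to 1.
#' @param min,max Uniform support.
#' @param mu,kappa Von Mises location (degrees) and concentration.
#' @param label Free-text identifier.
#' @return A `fixture_1d` object: `values`, `true_entropy` (J/(mol K)),
#'   `kind`, `params`, `seed`, `label`.
#' @export
generate_fixture <- function(kind = c("gaussian", "mixture", "uniform", "von_mises"),
                             n, seed = NULL,
                             mean = 0, sd = 1,
                             means = c(-2, 2), sds = c(1, 1),
                             mixture_weights = c(0.5, 0.5),
                             min = 0, max = 1,
                             mu = 0, kappa = 1,
                             label = NULL) {
  kind <- match.arg(kind)
  if (length(n) != 1L || !is.finite(n) || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)

  out <- switch(kind,
    gaussian = {
      if (sd <= 0) abort("`sd` must be > 0.")
      list(values = with_seed_maybe(seed, rnorm(n, mean, sd)),
           true_entropy = analytic_gaussian_entropy(sd),
           params = list(mean = mean, sd = sd))
    },
    uniform = {
      if (max <= min) abort("`max` must exceed `min`.")
      list(values = with_seed_maybe(seed, runif(n, min, max)),
           true_entropy = analytic_uniform_entropy(max - min),
           params = list(min = min, max = max))
    },
    mixture = {
      k <- length(means)
      if (length(sds) != k || length(mixture_weights) != k)
        abort("`means`, `sds` and `mixture_weights` must have equal length.")
      if (any(sds <= 0)) abort("`sds` must be > 0.")
      if (abs(sum(mixture_weights) - 1) > 1e-9)
        abort("`mixture_weights` must sum to 1.")
      dens <- function(x) {
        d <- 0
        for (j in seq_len(k))
          d <- d + mixture_weights[j] * stats::dnorm(x, means[j], sds[j])
        d
      }
      lo <- min(means - 10 * sds)
      hi <- max(means + 10 * sds)
      vals <- with_seed_maybe(seed, {
        comp <- sample.int(k, n, replace = TRUE, prob = mixture_weights)
        rnorm(n, means[comp], sds[comp])
      })
      list(values = vals,
           true_entropy = entropy_by_quadrature(dens, lo, hi),
           params = list(means = means, sds = sds,
                         mixture_weights = mixture_weights))
    },
    von_mises = {
      if (kappa <= 0) abort("`kappa` must be > 0.")
      mu_rad <- mu * pi / 180
      dens <- function(th) exp(vm_log_density(th, mu_rad, kappa))
      vals <- with_seed_maybe(seed, r_von_mises(n, mu_rad, kappa))
      list(values = wrap_degrees(vals * 180 / pi),
           true_entropy = entropy_by_quadrature(dens, -pi, pi),
           params = list(mu = mu, kappa = kappa))
    })

  structure(
    list(values = out$values, true_entropy = out$true_entropy,
         kind = kind, params = out$params, seed = seed,
         label = label %||% kind),
    class = "fixture_1d")
}

#' Generate a biased dihedral ensemble with known boost potentials
#'
#' Emulates an accelerated-MD workflow end to end: frames are drawn from
#' the biased density `p_b(x) \propto p_true(x) * exp(-beta * dV(x))`,
#' where `p_true` is a von Mises mixture and
#' `dV(x) = boost_height * (1 + cos(x - boost_center)) / 2` (kcal/mol) is a
#' smooth non-negative boost. Sampling draws from `p_true` and thins each
#' frame with probability `exp(-beta * dV)`, which is exact. The returned
#' per-frame `delta_v` values feed [maclaurin_weights()], and the true
#' (unbiased) entropy and density allow recovery to be checked against an
#' oracle that never touches the KDE.
#'
#' @param n Number of frames to return.
#' @param seed Optional integer seed.
#' @param mixture_weights,mu,kappa Parameters of the unbiased von Mises
#'   mixture (`mu` in degrees).
#' @param boost_height Maximum boost in kcal/mol. `beta * boost_height`
#'   above 30 is rejected: order-10 Maclaurin weights become numerically
#'   useless there, so rescale the boost instead.
#' @param boost_center Angle (degrees) where the boost peaks.
#' @param temperature Temperature in K defining `beta`.
#' @return A list of class `boosted_dihedral_fixture`: `angles` (degrees),
#'   `delta_v` (kcal/mol per frame), `temperature`, `beta`,
#'   `true_entropy` (radian convention, J/(mol K)), and `true_density`, a
#'   function of angle in degrees returning the unbiased density per
#'   degree.
#' @export
generate_boosted_dihedral <- function(n, seed = NULL,
                                      mixture_weights = c(0.65, 0.35),
                                      mu = c(-120, 60),
                                      kappa = c(8, 8),
                                      boost_height = 1.2,
                                      boost_center = 60,
                                      temperature = 300) {
  if (length(n) != 1L || !is.finite(n) || n < 1) abort("`n` must be >= 1.")
  k <- length(mixture_weights)
  if (length(mu) != k || length(kappa) != k)
    abort("`mixture_weights`, `mu` and `kappa` must have equal length.")
  if (abs(sum(mixture_weights) - 1) > 1e-9)
    abort("`mixture_weights` must sum to 1.")
  if (any(kappa <= 0)) abort("`kappa` must be > 0.")
  if (boost_height < 0) abort("`boost_height` must be >= 0.")
  beta <- 1 / (KB_KCAL * temperature)
  if (beta * boost_height > 30)
    abort(paste0("beta * boost_height exceeds 30: order-10 Maclaurin weights ",
                 "overflow their useful range; lower `boost_height`."))

  mu_rad <- mu * pi / 180
  bc_rad <- boost_center * pi / 180
  dv_rad <- function(th) boost_height * (1 + cos(th - bc_rad)) / 2

  n <- as.integer(n)
  draw <- function() {
    ang <- numeric(0L)
    while (length(ang) < n) {
      m <- ceiling((n - length(ang)) * 1.6) + 50L
      comp <- sample.int(k, m, replace = TRUE, prob = mixture_weights)
      th <- numeric(m)
      for (j in seq_len(k)) {
        pick <- comp == j
        if (any(pick)) th[pick] <- r_von_mises(sum(pick), mu_rad[j], kappa[j])
      }
      keep <- runif(m) < exp(-beta * dv_rad(th))
      ang <- c(ang, th[keep])
    }
    ang[seq_len(n)]
  }
  th <- with_seed_maybe(seed, draw())

  p_true_rad <- function(t) vm_mixture_density(t, mixture_weights, mu_rad, kappa)
  angles <- wrap_degrees(th * 180 / pi)

  structure(
    list(angles = angles,
         delta_v = dv_rad(th),
         temperature = temperature,
         beta = beta,
         true_entropy = entropy_by_quadrature(p_true_rad, -pi, pi),
         true_density = function(theta_deg)
           p_true_rad(theta_deg * pi / 180) * pi / 180,
         params = list(mixture_weights = mixture_weights, mu = mu,
                       kappa = kappa, boost_height = boost_height,
                       boost_center = boost_center),
         seed = seed),
    class = "boosted_dihedral_fixture")
}
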