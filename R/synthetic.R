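#' Specification for the synthetic-data generators
#'
#' Bundles the seed and noise settings shared by all generators. Every
#' generator is a pure function of (parameters, spec): a fixed seed gives
#' bit-identical output. Sub-seeds for individual curves are derived
#' deterministically from the top-level seed as
#' `(seed * 7919 + index) mod (2^31 - 1)` (index = position of the curve
#' within the call), so multi-curve generators are reproducible
#' curve-by-curve.
#'
#' @param seed Integer seed.
#' @param noise_sd_frac Noise scale: for recovery curves, the SD of the
#'   additive Gaussian intensity noise as a fraction of m0 (detector-like
#'   noise); for rheology sweeps, the log-SD of the multiplicative
#'   log-normal modulus noise. Default 0.02 (2%), a realistic well-shimmed
#'   acquisition.
#' @param n_points Number of points per curve (default 12 delays for
#'   recovery, 121 frequencies for sweeps when `NULL`).
#' @param delay_range Optional length-2 recovery-delay range in seconds;
#'   default `c(0.01, 6) * T1` guess, log-spaced.
#' @param freq_range Optional length-2 angular-frequency range in rad/s for
#'   sweeps; default `c(0.01, 100) / lambda`, log-spaced.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, noise_sd_frac = 0.02,
                           n_points = NULL, delay_range = NULL,
                           freq_range = NULL) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (!is.numeric(noise_sd_frac) || noise_sd_frac < 0) {
    stop("`noise_sd_frac` must be >= 0", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), noise_sd_frac = noise_sd_frac,
         n_points = n_points, delay_range = delay_range,
         freq_range = freq_range),
    class = "generator_spec"
  )
}

## deterministic sub-seed for curve `index` under a top-level seed
.sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + index) %% 2147483647)
}

.log_space <- function(from, to, n) 10^seq(log10(from), log10(to),
                                           length.out = n)

.ideal_recovery <- function(t, t1, m0, scheme) {
  switch(scheme,
    saturation = m0 * (1 - exp(-t / t1)),
    inversion = m0 * (1 - 2 * exp(-t / t1))
  )
}

#' Generate a synthetic mono-exponential recovery curve
#'
#' Ideal recovery (saturation: \eqn{M(t) = m_0(1 - e^{-t/T_1})}; inversion:
#' \eqn{M(t) = m_0(1 - 2e^{-t/T_1})}) plus i.i.d. additive Gaussian noise
#' of SD `noise_sd_frac * m0`, at delays log-spaced over
#' `spec$delay_range` (default 0.01--6 x T1).
#'
#' @param t1 True T1 in seconds (> 0).
#' @param m0 Equilibrium intensity (arbitrary units).
#' @param scheme `"saturation"` or `"inversion"`.
#' @param spec A [generator_spec()].
#' @param resonance,sample Labels forwarded to the curve.
#' @return A [recovery_curve()].
#' @export
gen_recovery <- function(t1, m0 = 100, scheme = c("saturation", "inversion"),
                         spec = generator_spec(),
                         resonance = "resonance", sample = "sample") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.numeric(t1) || t1 <= 0) stop("`t1` must be positive", call. = FALSE)
  n <- if (is.null(spec$n_points)) 12L else spec$n_points
  rng <- if (is.null(spec$delay_range)) c(0.01, 6) * t1 else spec$delay_range
  delays <- .log_space(rng[1], rng[2], n)
  ideal <- .ideal_recovery(delays, t1, m0, scheme)
  noise <- withr::with_seed(.sub_seed(spec$seed, 1L),
                            stats::rnorm(n, sd = spec$noise_sd_frac * m0))
  recovery_curve(delays, ideal + noise, scheme = scheme,
                 resonance = resonance, sample = sample)
}

#' Generate a ring/methyl pair of recovery curves
#'
#' Emulates the two experimental regimes of an HA gel: call with
#' `t1_ring == t1_methyl` for the stiff, spin-diffusion-equilibrated case
#' (dense gels) and with distinct values for the mobile case (dilute gels).
#' Both curves share the acquisition scheme and delay list (log-spaced over
#' 0.01 x min(T1) to 6 x max(T1) by default) but carry independent noise
#' (sub-seeds 1 and 2).
#'
#' @param t1_ring,t1_methyl True T1 values in seconds.
#' @param spec A [generator_spec()].
#' @param m0 Equilibrium intensity for both curves.
#' @param scheme Acquisition scheme shared by the pair.
#' @param sample Sample label shared by the pair.
#' @return List of two [recovery_curve()]s named `ring` and `methyl`.
#' @export
gen_t1_pair <- function(t1_ring, t1_methyl, spec = generator_spec(),
                        m0 = 100, scheme = c("saturation", "inversion"),
                        sample = "sample") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "generator_spec"))
  if (t1_ring <= 0 || t1_methyl <= 0) {
    stop("T1 values must be positive", call. = FALSE)
  }
  n <- if (is.null(spec$n_points)) 12L else spec$n_points
  rng <- if (is.null(spec$delay_range)) {
    c(0.01 * min(t1_ring, t1_methyl), 6 * max(t1_ring, t1_methyl))
  } else spec$delay_range
  delays <- .log_space(rng[1], rng[2], n)
  one <- function(t1, label, index) {
    ideal <- .ideal_recovery(delays, t1, m0, scheme)
    noise <- withr::with_seed(.sub_seed(spec$seed, index),
                              stats::rnorm(n, sd = spec$noise_sd_frac * m0))
    recovery_curve(delays, ideal + noise, scheme = scheme,
                   resonance = label, sample = sample)
  }
  list(ring = one(t1_ring, "ring", 1L), methyl = one(t1_methyl, "methyl", 2L))
}

## exp(-A t) %*% v for a 2x2 matrix via eigendecomposition
.expm2_apply <- function(A, t, v) {
  eg <- eigen(A)
  V <- eg$vectors
  coef <- solve(V, v)
  Re(V %*% (exp(-eg$values %o% t) * drop(coef)))
}

#' Generate a two-pool exchange recovery curve
#'
#' Robustness fixture for the proton-exchange relaxation pathway: pool A
#' (polymer 1H, the observable) and pool B (e.g. water 1H) relax with their
#' own T1 while exchanging magnetisation at rate `k_ex`. Longitudinal
#' magnetisation follows the coupled two-pool rate equations
#' \deqn{\frac{d\Delta M}{dt} = -\begin{pmatrix} 1/T_{1a} + k_{ab} & -k_{ba}\\
#'   -k_{ab} & 1/T_{1b} + k_{ba} \end{pmatrix} \Delta M}
#' (\eqn{\Delta M = M - M_\infty}; \eqn{k_{ab} = k_{ex} p_b},
#' \eqn{k_{ba} = k_{ex} p_a}, detailed balance), solved exactly by 2x2
#' eigendecomposition. The returned intensities are pool-A magnetisation
#' with the same additive noise model (and sub-seed) as [gen_recovery()],
#' so `k_ex = 0` reproduces `gen_recovery(t1_a, ...)` bit for bit.
#'
#' @param t1_a,t1_b Pool T1 values in seconds.
#' @param k_ex Total exchange rate in s^-1 (>= 0).
#' @param spec A [generator_spec()].
#' @param pa Equilibrium population fraction of pool A (default 0.5).
#' @param m0 Pool-A equilibrium intensity.
#' @param scheme Recovery scheme (both pools prepared identically).
#' @param resonance,sample Labels.
#' @return A [recovery_curve()] of the observable pool-A signal.
#' @export
gen_two_pool <- function(t1_a, t1_b, k_ex, spec = generator_spec(),
                         pa = 0.5, m0 = 100,
                         scheme = c("saturation", "inversion"),
                         resonance = "resonance", sample = "sample") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "generator_spec"))
  if (t1_a <= 0 || t1_b <= 0) stop("T1 values must be positive",
                                   call. = FALSE)
  if (k_ex < 0) stop("`k_ex` must be >= 0", call. = FALSE)
  if (pa <= 0 || pa >= 1) stop("`pa` must be in (0, 1)", call. = FALSE)
  pb <- 1 - pa
  n <- if (is.null(spec$n_points)) 12L else spec$n_points
  rng <- if (is.null(spec$delay_range)) c(0.01, 6) * t1_a else
    spec$delay_range
  delays <- .log_space(rng[1], rng[2], n)
  A <- matrix(c(1 / t1_a + k_ex * pb, -k_ex * pb,
                -k_ex * pa,           1 / t1_b + k_ex * pa),
              nrow = 2, byrow = FALSE)
  ## equilibrium scaled so pool A has m0; preparation factor per scheme
  minf <- c(m0, m0 * pb / pa)
  prep <- if (scheme == "saturation") -1 else -2
  dM0 <- prep * minf                     # M(0) - Minf
  dM <- .expm2_apply(A, delays, dM0)
  signal_a <- minf[1L] + dM[1L, ]
  noise <- withr::with_seed(.sub_seed(spec$seed, 1L),
                            stats::rnorm(n, sd = spec$noise_sd_frac * m0))
  recovery_curve(delays, signal_a + noise, scheme = scheme,
                 resonance = resonance, sample = sample)
}

#' Generate a single-mode Maxwell oscillatory sweep
#'
#' Maxwell-fluid moduli
#' \deqn{G'(\omega) = G\frac{\omega^2\lambda^2}{1+\omega^2\lambda^2},\quad
#'       G''(\omega) = G\frac{\omega\lambda}{1+\omega^2\lambda^2}}
#' with the analytic crossover at \eqn{\omega_c = 1/\lambda},
#' \eqn{G_c = G/2}, sampled log-spaced over `spec$freq_range` (default
#' 0.01--100 / lambda, 121 points) with multiplicative log-normal noise of
#' log-SD `noise_sd_frac` on both moduli (instrument-typical relative
#' error).
#'
#' @param G Plateau modulus in Pa (> 0).
#' @param lambda Relaxation time in seconds (> 0).
#' @param spec A [generator_spec()].
#' @param sample Sample label.
#' @return An [oscillatory_sweep()].
#' @export
gen_maxwell_sweep <- function(G, lambda, spec = generator_spec(),
                              sample = "sample") {
  stopifnot(inherits(spec, "generator_spec"))
  if (G <= 0 || lambda <= 0) stop("`G` and `lambda` must be positive",
                                  call. = FALSE)
  n <- if (is.null(spec$n_points)) 121L else spec$n_points
  rng <- if (is.null(spec$freq_range)) c(0.01, 100) / lambda else
    spec$freq_range
  omega <- .log_space(rng[1], rng[2], n)
  wl <- omega * lambda
  gp <- G * wl^2 / (1 + wl^2)
  gpp <- G * wl / (1 + wl^2)
  noise <- withr::with_seed(.sub_seed(spec$seed, 1L),
                            matrix(stats::rnorm(2 * n,
                                                sd = spec$noise_sd_frac),
                                   nrow = 2))
  oscillatory_sweep(omega, gp * exp(noise[1L, ]), gpp * exp(noise[2L, ]),
                    sample = sample)
}
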