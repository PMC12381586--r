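#' Order parameter of restricted motion on a cone
#'
#' Scaling factor by which fast restricted reorientation averages a
#' second-rank (dipolar) interaction. Two conventions are provided:
#'
#' * `"legendre"` (default): \eqn{S(\theta) = (3\cos^2\theta - 1)/2},
#'   azimuthally random hopping of the vector at fixed cone angle
#'   \eqn{\theta}. S = 1 at 0 deg (rigid), 0 at the magic angle
#'   (54.7356 deg), -0.5 at 90 deg.
#' * `"cone"`: \eqn{S(\theta) = \cos\theta\,(1+\cos\theta)/2}, free wobbling
#'   (diffusion) inside a cone of semi-angle \eqn{\theta}. S = 1 at 0 deg,
#'   0 at 90 deg, strictly positive in between.
#'
#' @param theta Cone angle(s) in degrees, each in \[0, 90\].
#' @param model Order-parameter convention, see above.
#' @return Dimensionless order parameter(s), |S| <= 1. Vectorised over
#'   `theta`.
#' @examples
#' order_parameter(c(0, 30, 54.7356, 90))
#' order_parameter(90, model = "cone")  # 0: full averaging
#' @export
order_parameter <- function(theta, model = c("legendre", "cone")) {
  model <- match.arg(model)
  if (!is.numeric(theta) || anyNA(theta)) {
    stop("`theta` must be numeric with no NA", call. = FALSE)
  }
  if (any(theta < 0 | theta > 90)) {
    stop("`theta` must lie in [0, 90] degrees", call. = FALSE)
  }
  ct <- cos(theta * pi / 180)
  switch(model,
    legendre = (3 * ct^2 - 1) / 2,
    cone = ct * (1 + ct) / 2
  )
}

#' Effective correlation time of two independent motions
#'
#' For statistically independent overall tumbling and internal motion the
#' correlation functions multiply, so the rates add:
#' \eqn{1/\tau_e = 1/\tau_{macro} + 1/\tau_{internal}}. The result is always
#' smaller than either input; `Inf` acts as a "motion absent" sentinel.
#'
#' @param tau_macro,tau_internal Correlation times in seconds (> 0, `Inf`
#'   allowed).
#' @return Effective correlation time in seconds. Vectorised.
#' @examples
#' effective_correlation_time(1e-7, 1e-9)  # 9.90099e-10
#' effective_correlation_time(1e-7, Inf)   # 1e-7
#' @export
effective_correlation_time <- function(tau_macro, tau_internal) {
  if (!is.numeric(tau_macro) || !is.numeric(tau_internal) ||
      anyNA(tau_macro) || anyNA(tau_internal) ||
      any(tau_macro <= 0) || any(tau_internal <= 0)) {
    stop("correlation times must be positive (Inf allowed)", call. = FALSE)
  }
  1 / (1 / tau_macro + 1 / tau_internal)
}

## Lorentzian spectral density in angular-frequency convention
.lorentzian <- function(omega, tau) tau / (1 + (omega * tau)^2)

#' Model-free spectral density for composite motion
#'
#' Two-Lorentzian (model-free) form for slow isotropic tumbling plus fast
#' restricted internal motion:
#' \deqn{J(\omega) = S^2 \frac{\tau_{macro}}{1+\omega^2\tau_{macro}^2}
#'   + (1-S^2) \frac{\tau_e}{1+\omega^2\tau_e^2}}
#' with \eqn{\tau_e} the effective correlation time of the composite motion.
#'
#' @param omega Angular frequency in rad/s (>= 0).
#' @param S2 Squared order parameter, in \[0, 1\].
#' @param tau_macro Tumbling correlation time, s.
#' @param tau_e Effective correlation time, s (see
#'   [effective_correlation_time()]).
#' @return Spectral density in seconds. Vectorised over `omega` and `tau_e`.
#' @examples
#' spectral_density(0, 0.5, 1e-7, 1e-9)  # 5.05e-8
#' @export
spectral_density <- function(omega, S2, tau_macro, tau_e) {
  if (!is.numeric(S2) || anyNA(S2) || any(S2 < 0 | S2 > 1)) {
    stop("`S2` must lie in [0, 1]", call. = FALSE)
  }
  if (any(omega < 0)) stop("`omega` must be >= 0", call. = FALSE)
  if (any(tau_macro <= 0) || any(tau_e <= 0)) {
    stop("correlation times must be positive", call. = FALSE)
  }
  S2 * .lorentzian(omega, tau_macro) + (1 - S2) * .lorentzian(omega, tau_e)
}

#' Molecular-motion contribution to the 1H spin-lattice relaxation rate
#'
#' Relaxation driven by the internally modulated part of the dipolar
#' coupling (like-spin Solomon expression restricted to the
#' \eqn{(1-S^2)} component):
#' \deqn{R_1^{motion} = \frac{3}{10} d^2 (1-S^2)
#'   \left[ L(\omega_0, \tau_e) + 4 L(2\omega_0, \tau_e) \right]}
#' with \eqn{L(\omega,\tau) = \tau/(1+\omega^2\tau^2)}. Zero for a rigid
#' vector (theta = 0) and vanishing in both the very-fast and very-slow
#' internal-motion limits; maximal when \eqn{\omega_0 \tau_e \approx 0.616}.
#'
#' @param pair A [spin_pair()].
#' @param motion A [cone_motion()], or `NULL` if the vectorised arguments
#'   below are supplied.
#' @param S2,tau_e Optional vectorised override of the squared order
#'   parameter and effective correlation time (used by the grid evaluation).
#' @return Rate(s) in s^-1.
#' @export
r1_motion <- function(pair, motion = NULL, S2 = NULL, tau_e = NULL) {
  stopifnot(inherits(pair, "spin_pair"))
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "cone_motion"))
    S2 <- motion$order_parameter_S^2
    tau_e <- motion$tau_e
  }
  w0 <- pair$larmor_omega0
  d2 <- pair$dipolar_constant_d^2
  (3 / 10) * d2 * (1 - S2) *
    (.lorentzian(w0, tau_e) + 4 * .lorentzian(2 * w0, tau_e))
}

#' Spin-diffusion contribution to the 1H spin-lattice relaxation rate
#'
#' Cross-relaxation through the dipole-coupled 1H network (flip-flop-driven
#' transport of longitudinal magnetisation to relaxation sinks), in the
#' low-frequency limit appropriate for slow tumbling
#' (\eqn{\omega_0\tau_{macro} \gg 1}):
#' \deqn{R_1^{sd} = c_{sd}\, d^2 S^2 \tau_{macro}.}
#' The residual dipolar coupling that drives flip-flops is the motionally
#' averaged one, hence the \eqn{S^2} quench: large-amplitude internal motion
#' switches spin diffusion off. The dimensionless constant `c_sd` sets the
#' overall efficiency of magnetisation transport; by default it is
#' calibrated at regime-map construction so that the maximum spin-diffusion
#' rate on the grid is 10x the maximum motion rate (see
#' [calibrate_c_sd()]).
#'
#' @inheritParams r1_motion
#' @param c_sd Dimensionless transport constant.
#' @param tau_macro Tumbling correlation time in seconds (taken from
#'   `motion` when one is given).
#' @return Rate(s) in s^-1.
#' @export
r1_spin_diffusion <- function(pair, motion = NULL, c_sd, S2 = NULL,
                              tau_macro = NULL) {
  stopifnot(inherits(pair, "spin_pair"))
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "cone_motion"))
    S2 <- motion$order_parameter_S^2
    tau_macro <- motion$tau_macro
  }
  c_sd * pair$dipolar_constant_d^2 * S2 * tau_macro
}

#' Calibrate the spin-diffusion transport constant
#'
#' Chooses `c_sd` such that over the given (theta, tau) grid
#' `max(sd_matrix) / max(motion_matrix) = ratio`. The default ratio of 10
#' encodes the observation that in entangled HA gels the maximal
#' spin-diffusion rate is roughly an order of magnitude larger than the
#' maximal molecular-motion rate, so spin diffusion wins except near the
#' motion term's optimum.
#'
#' @param pair A [spin_pair()].
#' @param theta_grid Cone angles in degrees.
#' @param tau_grid Internal correlation times in seconds.
#' @param tau_macro Tumbling correlation time in seconds.
#' @param ratio Target max(sd)/max(motion) (default 10).
#' @param order_parameter_model Passed to [order_parameter()].
#' @return The dimensionless `c_sd`.
#' @export
calibrate_c_sd <- function(pair, theta_grid, tau_grid, tau_macro = 1e-7,
                           ratio = 10,
                           order_parameter_model = c("legendre", "cone")) {
  order_parameter_model <- match.arg(order_parameter_model)
  S <- order_parameter(theta_grid, model = order_parameter_model)
  tau_e <- effective_correlation_time(tau_macro, tau_grid)
  motion <- outer(1 - S^2, r1_motion(pair, S2 = 0, tau_e = tau_e))
  max_S2 <- max(S^2)
  if (max_S2 == 0) stop("grid has S = 0 everywhere; cannot calibrate",
                        call. = FALSE)
  ratio * max(motion) / (pair$dipolar_constant_d^2 * max_S2 * tau_macro)
}

#' Default grids for the regime map
#'
#' Cone angle 0--90 degrees in 1-degree steps; internal correlation time
#' log-spaced from 1e-12 to 1e-6 s at 25 points per decade, bracketing the
#' nanosecond window where the motion term can win.
#' @return Numeric vector of grid values.
#' @export
default_theta_grid <- function() seq(0, 90, by = 1)

#' @rdname default_theta_grid
#' @param tau_min,tau_max Range in seconds.
#' @param pts_per_decade Grid density.
#' @export
default_tau_grid <- function(tau_min = 1e-12, tau_max = 1e-6,
                             pts_per_decade = 25) {
  10^seq(log10(tau_min), log10(tau_max), by = 1 / pts_per_decade)
}

#' Compute the motion vs spin-diffusion regime map
#'
#' Evaluates the molecular-motion and spin-diffusion relaxation rates over a
#' (cone angle, internal correlation time) grid at fixed tumbling time
#' `tau_macro`, classifies each grid point by the dominant term, and
#' extracts the dominance boundary (onset angle and correlation-time
#' window). Ties classify as spin diffusion: spin diffusion dominates unless
#' the motion term strictly exceeds it.
#'
#' @param pair A [spin_pair()].
#' @param theta_grid Ascending cone angles in degrees
#'   (default [default_theta_grid()]).
#' @param tau_grid Ascending internal correlation times in seconds
#'   (default [default_tau_grid()]).
#' @param tau_macro Tumbling correlation time in seconds (default 1e-7 s,
#'   the slow-tumbling regime of an entangled HA gel).
#' @param order_parameter_model See [order_parameter()].
#' @param c_sd Spin-diffusion constant; `NULL` (default) calibrates it via
#'   [calibrate_c_sd()] with `calibration_ratio`.
#' @param calibration_ratio Target max(sd)/max(motion) used when `c_sd` is
#'   `NULL`.
#' @return An object of class `regime_map`: grids, the two rate matrices
#'   (rows = theta, cols = tau), the logical dominance matrix, `c_sd`,
#'   `max_ratio`, and the extracted `onset_angle` / `tau_window`
#'   (see [dominance_boundary()]).
#' @examples
#' map <- compute_regime_map(spin_pair())
#' map$onset_angle
#' @export
compute_regime_map <- function(pair,
                               theta_grid = default_theta_grid(),
                               tau_grid = default_tau_grid(),
                               tau_macro = 1e-7,
                               order_parameter_model = c("legendre", "cone"),
                               c_sd = NULL,
                               calibration_ratio = 10) {
  order_parameter_model <- match.arg(order_parameter_model)
  if (length(theta_grid) < 1L || length(tau_grid) < 1L) {
    stop("grids must be non-empty", call. = FALSE)
  }
  if (is.unsorted(theta_grid, strictly = TRUE) ||
      is.unsorted(tau_grid, strictly = TRUE)) {
    stop("grids must be strictly ascending", call. = FALSE)
  }
  S <- order_parameter(theta_grid, model = order_parameter_model)
  tau_e <- effective_correlation_time(tau_macro, tau_grid)
  ## both terms share d^2; factorise as theta-part x tau-part
  motion_tau <- r1_motion(pair, S2 = 0, tau_e = tau_e)   # (1-S2)=1 slice
  motion_matrix <- outer(1 - S^2, motion_tau)
  if (is.null(c_sd)) {
    c_sd <- calibrate_c_sd(pair, theta_grid, tau_grid, tau_macro,
                           ratio = calibration_ratio,
                           order_parameter_model = order_parameter_model)
  }
  sd_col <- r1_spin_diffusion(pair, c_sd = c_sd, S2 = S^2,
                              tau_macro = tau_macro)
  sd_matrix <- matrix(sd_col, nrow = length(theta_grid),
                      ncol = length(tau_grid))
  dimnames(motion_matrix) <- dimnames(sd_matrix) <-
    list(theta_deg = format(theta_grid), tau_s = format(tau_grid))
  map <- structure(
    list(
      theta_grid = theta_grid,
      tau_grid = tau_grid,
      tau_macro = tau_macro,
      motion_matrix = motion_matrix,
      sd_matrix = sd_matrix,
      dominant = motion_matrix > sd_matrix,   # TRUE = motion; ties -> sd
      c_sd = c_sd,
      order_parameter_model = order_parameter_model,
      max_ratio = max(sd_matrix) / max(motion_matrix),
      pair = pair
    ),
    class = "regime_map"
  )
  bnd <- dominance_boundary(map)
  map$onset_angle <- bnd$onset_angle
  map$tau_window <- bnd$tau_window
  map
}

#' Extract the dominance boundary from a regime map
#'
#' The onset angle is the smallest grid cone angle at which the motion term
#' strictly exceeds the spin-diffusion term for at least one internal
#' correlation time; the tau window is the (min, max) internal correlation
#' time over all grid points where motion dominates. If motion dominates
#' nowhere, both are returned as `NA` with `none = TRUE`.
#'
#' @param map A `regime_map`.
#' @return List with `onset_angle` (degrees or `NA`), `tau_window`
#'   (length-2 seconds or `c(NA, NA)`) and logical `none`.
#' @export
dominance_boundary <- function(map) {
  stopifnot(inherits(map, "regime_map"))
  dom <- map$dominant
  if (!any(dom)) {
    return(list(onset_angle = NA_real_, tau_window = c(NA_real_, NA_real_),
                none = TRUE))
  }
  list(
    onset_angle = map$theta_grid[which(rowSums(dom) > 0)[1L]],
    tau_window = range(map$tau_grid[colSums(dom) > 0]),
    none = FALSE
  )
}

#' @export
print.regime_map <- function(x, ...) {
  cat("<regime_map>\n")
  cat(sprintf("  grid          : %d angles x %d correlation times\n",
              length(x$theta_grid), length(x$tau_grid)))
  cat(sprintf("  tau_macro     : %.3g s;  order parameter: %s\n",
              x$tau_macro, x$order_parameter_model))
  cat(sprintf("  c_sd          : %.4g;  max(sd)/max(motion) = %.3g\n",
              x$c_sd, x$max_ratio))
  if (is.na(x$onset_angle)) {
    cat("  dominance     : spin diffusion everywhere\n")
  } else {
    cat(sprintf("  motion wins   : theta >= %g deg, tau in [%.3g, %.3g] s\n",
                x$onset_angle, x$tau_window[1], x$tau_window[2]))
  }
  invisible(x)
}

#' Regime map as a long-format data frame
#'
#' One row per (theta, tau) grid point with both rates and the dominant
#' term; the table written by the `regime-map` CLI command.
#' @param x A `regime_map`.
#' @param ... Unused.
#' @return A data.frame with columns `theta_deg`, `tau_s`, `r1_motion_s1`,
#'   `r1_sd_s1`, `dominant`.
#' @export
as.data.frame.regime_map <- function(x, ...) {
  data.frame(
    theta_deg = rep(x$theta_grid, times = length(x$tau_grid)),
    tau_s = rep(x$tau_grid, each = length(x$theta_grid)),
    r1_motion_s1 = as.vector(x$motion_matrix),
    r1_sd_s1 = as.vector(x$sd_matrix),
    dominant = ifelse(as.vector(x$dominant), "motion", "spin_diffusion")
  )
}
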