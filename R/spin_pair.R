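## Physical constants (SI)
.GAMMA_1H <- 2.6752218744e8   # 1H gyromagnetic ratio, rad s^-1 T^-1
.HBAR <- 1.054571817e-34      # J s
.MU0_4PI <- 1e-7              # T m A^-1

#' Dipolar-coupled proton pair
#'
#' Describes a pair of dipole-coupled protons at fixed separation in a static
#' field. The Larmor frequency and the dipolar coupling constant
#' \eqn{d = (\mu_0/4\pi)\,\hbar\,\gamma^2 / r^3} are derived on construction.
#' In hyaluronan gels the 1H--1H dipolar interaction is the dominant
#' spin-lattice relaxation pathway, so this pair is the elementary unit of the
#' regime-map simulation.
#'
#' @param field_mhz Proton Larmor frequency of the spectrometer in MHz
#'   (default 500, i.e. B0 = 11.74 T). Mutually exclusive with `field_tesla`.
#' @param r_hh_angstrom 1H--1H internuclear distance in Angstrom (default 2.0,
#'   a typical intra-ring / methyl separation). The dominance boundaries of
#'   the regime map are provably independent of this value.
#' @param field_tesla Static field B0 in tesla; overrides `field_mhz` if given.
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1 (default: 1H).
#'
#' @return An object of class `spin_pair`: a list with elements
#'   `gamma`, `distance_r` (m), `field_B0` (T), `larmor_omega0` (rad/s) and
#'   `dipolar_constant_d` (rad/s).
#' @examples
#' sp <- spin_pair(field_mhz = 500, r_hh_angstrom = 2.0)
#' sp$larmor_omega0 / (2 * pi)   # 5e8 Hz
#' @export
spin_pair <- function(field_mhz = 500, r_hh_angstrom = 2.0,
                      field_tesla = NULL, gamma = .GAMMA_1H) {
  if (!is.numeric(r_hh_angstrom) || length(r_hh_angstrom) != 1L ||
      !is.finite(r_hh_angstrom) || r_hh_angstrom <= 0) {
    stop("`r_hh_angstrom` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(gamma) || gamma <= 0) {
    stop("`gamma` must be positive", call. = FALSE)
  }
  if (is.null(field_tesla)) {
    if (!is.numeric(field_mhz) || field_mhz <= 0) {
      stop("`field_mhz` must be positive", call. = FALSE)
    }
    field_tesla <- 2 * pi * field_mhz * 1e6 / gamma
  } else if (!is.numeric(field_tesla) || field_tesla <= 0) {
    stop("`field_tesla` must be positive", call. = FALSE)
  }
  r <- r_hh_angstrom * 1e-10
  structure(
    list(
      gamma = gamma,
      distance_r = r,
      field_B0 = field_tesla,
      larmor_omega0 = gamma * field_tesla,
      dipolar_constant_d = .MU0_4PI * .HBAR * gamma^2 / r^3
    ),
    class = "spin_pair"
  )
}

#' @export
print.spin_pair <- function(x, ...) {
  cat("<spin_pair>\n")
  cat(sprintf("  B0            : %.4g T (%.1f MHz 1H)\n",
              x$field_B0, x$larmor_omega0 / (2 * pi * 1e6)))
  cat(sprintf("  r(HH)         : %.3g Angstrom\n", x$distance_r * 1e10))
  cat(sprintf("  d (dipolar)   : %.4g rad/s (%.3g kHz)\n",
              x$dipolar_constant_d, x$dipolar_constant_d / (2 * pi * 1e3)))
  invisible(x)
}

#' Restricted cone motion of a 1H--1H vector
#'
#' The motional model behind the regime map: the internuclear vector executes
#' fast random motion on a cone of (semi-)angle `theta` with correlation time
#' `tau_internal`, superimposed on slow isotropic tumbling with correlation
#' time `tau_macro`. The restricted motion scales the dipolar coupling by the
#' order parameter S(theta) (see [order_parameter()]).
#'
#' @param cone_angle_theta Cone angle in degrees, in \[0, 90\].
#' @param tau_internal Internal-motion correlation time in seconds (> 0;
#'   `Inf` is accepted as the "no internal motion" sentinel).
#' @param tau_macro Overall tumbling correlation time in seconds (> 0).
#' @param order_parameter_model Passed to [order_parameter()].
#' @return An object of class `cone_motion` with fields
#'   `cone_angle_theta` (deg), `tau_internal`, `tau_macro`, `tau_e`
#'   (effective correlation time of the composite motion) and
#'   `order_parameter_S`.
#' @examples
#' cone_motion(30, 1e-9, 1e-7)$order_parameter_S  # 0.625
#' @export
cone_motion <- function(cone_angle_theta, tau_internal, tau_macro = 1e-7,
                        order_parameter_model = c("legendre", "cone")) {
  order_parameter_model <- match.arg(order_parameter_model)
  if (!is.numeric(tau_internal) || length(tau_internal) != 1L ||
      is.na(tau_internal) || tau_internal <= 0) {
    stop("`tau_internal` must be a single positive number (Inf allowed)",
         call. = FALSE)
  }
  if (!is.numeric(tau_macro) || length(tau_macro) != 1L ||
      is.na(tau_macro) || tau_macro <= 0) {
    stop("`tau_macro` must be a single positive number", call. = FALSE)
  }
  S <- order_parameter(cone_angle_theta, model = order_parameter_model)
  structure(
    list(
      cone_angle_theta = cone_angle_theta,
      tau_internal = tau_internal,
      tau_macro = tau_macro,
      tau_e = effective_correlation_time(tau_macro, tau_internal),
      order_parameter_S = S,
      order_parameter_model = order_parameter_model
    ),
    class = "cone_motion"
  )
}
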