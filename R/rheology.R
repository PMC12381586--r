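#' An oscillatory rheology frequency sweep
#'
#' Storage and loss moduli versus angular frequency for one sample.
#'
#' @param omega Angular frequencies in rad/s, strictly ascending.
#' @param g_prime Storage moduli G' in Pa (> 0).
#' @param g_double_prime Loss moduli G'' in Pa (> 0).
#' @param sample Free-text sample label.
#' @return Object of class `oscillatory_sweep`.
#' @export
oscillatory_sweep <- function(omega, g_prime, g_double_prime,
                              sample = "sample") {
  if (!is.numeric(omega) || !is.numeric(g_prime) ||
      !is.numeric(g_double_prime) ||
      anyNA(omega) || anyNA(g_prime) || anyNA(g_double_prime)) {
    stop("sweep columns must be numeric with no NA", call. = FALSE)
  }
  n <- length(omega)
  if (n < 3L || length(g_prime) != n || length(g_double_prime) != n) {
    stop("sweep needs >= 3 points with equal-length columns", call. = FALSE)
  }
  if (is.unsorted(omega, strictly = TRUE)) {
    stop("`omega` must be strictly ascending", call. = FALSE)
  }
  if (any(omega <= 0) || any(g_prime <= 0) || any(g_double_prime <= 0)) {
    stop("frequencies and moduli must be strictly positive", call. = FALSE)
  }
  structure(
    list(omega = as.numeric(omega), g_prime = as.numeric(g_prime),
         g_double_prime = as.numeric(g_double_prime),
         sample = as.character(sample)),
    class = "oscillatory_sweep"
  )
}

#' Locate the G'/G'' crossover frequency
#'
#' The crossover frequency -- where the storage modulus overtakes the loss
#' modulus -- measures the intrinsic disentanglement rate of the polymer
#' network: at frequencies above it the network responds elastically, below
#' it chains disentangle within the oscillation period. Both moduli and the
#' frequency span decades, so the sign change of log(G'/G'') is located and
#' interpolated linearly against log(omega); the crossover modulus is
#' interpolated the same way. When several sign changes exist the first
#' (lowest-frequency) one is returned with a warning.
#'
#' @param sweep An [oscillatory_sweep()].
#' @return Object of class `crossover`: `omega_c` (rad/s), `g_c` (Pa),
#'   `bracket` (indices of the bracketing points) and the sample label.
#' @examples
#' sw <- gen_maxwell_sweep(G = 100, lambda = 0.1,
#'                         spec = generator_spec(seed = 1, noise_sd_frac = 0))
#' find_crossover(sw)$omega_c  # 10 rad/s = 1/lambda
#' @export
find_crossover <- function(sweep) {
  stopifnot(inherits(sweep, "oscillatory_sweep"))
  y <- log(sweep$g_prime) - log(sweep$g_double_prime)
  lw <- log(sweep$omega)
  sgn <- y[-length(y)] * y[-1L]
  brackets <- which(sgn < 0 | y[-length(y)] == 0)
  if (y[length(y)] == 0) brackets <- c(brackets, length(y) - 1L)
  brackets <- unique(brackets)
  if (length(brackets) == 0L) {
    stop("no crossover in range: log(G'/G'') never changes sign",
         call. = FALSE)
  }
  if (length(brackets) > 1L) {
    warning(sprintf("%d crossovers found; returning the first",
                    length(brackets)), call. = FALSE)
  }
  i <- brackets[1L]
  frac <- if (y[i] == y[i + 1L]) 0 else y[i] / (y[i] - y[i + 1L])
  lw_c <- lw[i] + frac * (lw[i + 1L] - lw[i])
  lg1 <- log(sweep$g_prime[i]) +
    frac * (log(sweep$g_prime[i + 1L]) - log(sweep$g_prime[i]))
  lg2 <- log(sweep$g_double_prime[i]) +
    frac * (log(sweep$g_double_prime[i + 1L]) - log(sweep$g_double_prime[i]))
  structure(
    list(omega_c = exp(lw_c), g_c = exp((lg1 + lg2) / 2),
         bracket = c(i, i + 1L), sample = sweep$sample),
    class = "crossover"
  )
}

#' @export
print.crossover <- function(x, ...) {
  cat(sprintf("<crossover> %s: omega_c = %.4g rad/s, G_c = %.4g Pa\n",
              x$sample, x$omega_c, x$g_c))
  invisible(x)
}

#' Ratio of two crossover frequencies
#'
#' Compares the disentanglement rates of two gels:
#' `omega_c(a) / omega_c(b)`. A softer, more mobile network (e.g. a dilute
#' HA gel) crosses over at higher frequency than a denser one.
#'
#' @param a,b [find_crossover()] results.
#' @return Positive dimensionless ratio.
#' @export
compare_crossovers <- function(a, b) {
  stopifnot(inherits(a, "crossover"), inherits(b, "crossover"))
  a$omega_c / b$omega_c
}
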