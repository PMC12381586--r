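## shared fixtures for the suite (all data generated in code)

quiet_fit <- function(curve, ...) suppressWarnings(fit_recovery(curve, ...))

## a pair of t1_fit objects built directly, for testing the comparison
## logic in isolation from the fitter
fake_fit <- function(t1, se, dof = 9L) {
  structure(
    list(t1 = t1, t1_se = se, m0 = 100, amplitude = 100, rss = 1,
         dof = dof, converged = TRUE, resonance = "x", sample = "s",
         scheme = "saturation"),
    class = "t1_fit"
  )
}

## analytic single-mode Maxwell sweep without the generator (independent
## construction used by the rheology tests)
maxwell_sweep <- function(G, lambda, omega, sample = "s") {
  wl <- omega * lambda
  oscillatory_sweep(omega, G * wl^2 / (1 + wl^2), G * wl / (1 + wl^2),
                    sample = sample)
}
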