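test_that("spin_pair derives Larmor frequency and dipolar constant", {
  sp <- spin_pair(field_mhz = 500, r_hh_angstrom = 2.0)
  expect_equal(sp$larmor_omega0, 2 * pi * 500e6)
  expect_gt(sp$dipolar_constant_d, 0)
  ## d scales as r^-3: doubling r divides d by 8
  sp2 <- spin_pair(field_mhz = 500, r_hh_angstrom = 4.0)
  expect_equal(sp$dipolar_constant_d / sp2$dipolar_constant_d, 8)
  expect_error(spin_pair(r_hh_angstrom = -1), "positive")
  expect_error(spin_pair(field_mhz = 0), "positive")
})

test_that("order_parameter matches hand-evaluated values and domain", {
  expect_equal(order_parameter(0), 1.0)
  expect_equal(order_parameter(54.7356), 0.0, tolerance = 1e-6)
  expect_equal(order_parameter(30), 0.625)     # (3*(sqrt(3)/2)^2 - 1)/2
  expect_equal(order_parameter(90), -0.5)
  ## continuous and decreasing up to the magic angle
  th <- seq(0, 54.7356, length.out = 200)
  expect_true(all(diff(order_parameter(th)) < 0))
  expect_true(all(abs(order_parameter(0:90)) <= 1))
  ## cone-diffusion alternative: 1 at 0, 0 at 90, monotone, positive
  expect_equal(order_parameter(0, model = "cone"), 1.0)
  expect_equal(order_parameter(90, model = "cone"), 0.0)
  sc <- order_parameter(seq(0, 90, by = 1), model = "cone")
  expect_true(all(diff(sc) < 0) && all(sc >= 0))
  expect_error(order_parameter(-1), "\\[0, 90\\]")
  expect_error(order_parameter(90.5), "\\[0, 90\\]")
})

test_that("effective_correlation_time is the harmonic composition", {
  expect_equal(effective_correlation_time(1e-7, 1e-9), 9.90099009900990e-10,
               tolerance = 1e-12)
  tau <- 3.7e-8
  expect_equal(effective_correlation_time(tau, tau), tau / 2)
  expect_equal(effective_correlation_time(1e-7, Inf), 1e-7)  # no internal motion
  expect_lt(effective_correlation_time(1e-7, 1e-9), 1e-9)
  expect_error(effective_correlation_time(0, 1e-9), "positive")
  expect_error(effective_correlation_time(1e-7, -1e-9), "positive")
})

test_that("spectral_density: closed-form values, positivity, monotonicity", {
  ## S2 = 1 collapses to the tumbling Lorentzian for any tau_e
  w <- 10^seq(6, 10, length.out = 9)
  expect_equal(spectral_density(w, 1, 1e-7, 1e-9),
               1e-7 / (1 + (w * 1e-7)^2))
  expect_equal(spectral_density(0, 0.5, 1e-7, 1e-9), 5.05e-8)
  ## frozen from an independent two-Lorentzian hand evaluation
  expect_equal(spectral_density(3.1416e9, 0.5, 1e-7, 1e-9),
               0.5 * 1e-7 / (1 + (3.1416e9 * 1e-7)^2) +
                 0.5 * 1e-9 / (1 + (3.1416e9 * 1e-9)^2),
               tolerance = 1e-12)
  expect_equal(spectral_density(3.1416e9, 0.5, 1e-7, 1e-9), 4.65e-11,
               tolerance = 1e-2)
  ## J >= 0 and decreasing in omega, over a sweep of parameter cases
  for (S2 in c(0, 0.3, 0.9)) {
    J <- spectral_density(w, S2, 1e-7, 2e-10)
    expect_true(all(J >= 0))
    expect_true(all(diff(J) < 0))
  }
  expect_error(spectral_density(1, 1.5, 1e-7, 1e-9), "\\[0, 1\\]")
})

test_that("r1_motion: rigid limit, distance scaling, optimum location", {
  sp <- spin_pair()
  expect_identical(r1_motion(sp, cone_motion(0, 1e-9)), 0)
  ## d^2 ~ r^-6: doubling r divides the rate by 64
  m <- cone_motion(40, 1e-9)
  expect_equal(r1_motion(spin_pair(r_hh_angstrom = 2), m) /
                 r1_motion(spin_pair(r_hh_angstrom = 4), m), 64)
  ## argmax over tau_e sits at omega0 * tau_e ~ 0.616 (dense-scan oracle
  ## on x/(1+x^2) + 4x/(1+4x^2))
  x <- seq(0.3, 1.0, by = 1e-5)
  oracle_x <- x[which.max(x / (1 + x^2) + 4 * x / (1 + 4 * x^2))]
  expect_equal(oracle_x, 0.616, tolerance = 1e-3)
  tau_e <- 10^seq(-11, -9, by = 1e-4)
  rates <- r1_motion(sp, S2 = 0.5, tau_e = tau_e)
  expect_equal(sp$larmor_omega0 * tau_e[which.max(rates)], oracle_x,
               tolerance = 1e-3)
  ## vanishes in both fast and slow internal-motion limits
  fast <- r1_motion(sp, cone_motion(40, 1e-15))
  slow <- r1_motion(sp, cone_motion(40, 1e3, tau_macro = 1e-7))
  peak <- r1_motion(sp, cone_motion(40, 2e-10))
  expect_lt(fast, 1e-3 * peak)
  expect_lt(slow, 1e-1 * peak)
})

test_that("r1_spin_diffusion: quench behaviour", {
  sp <- spin_pair()
  c_sd <- 0.01
  ## zero exactly at the quench angle of S(theta), maximal at theta = 0
  quench <- acos(sqrt(1 / 3)) * 180 / pi
  expect_equal(r1_spin_diffusion(sp, cone_motion(quench, 1e-9), c_sd = c_sd),
               0, tolerance = 1e-25)
  rates <- vapply(0:90, function(th) {
    r1_spin_diffusion(sp, cone_motion(th, 1e-9), c_sd = c_sd)
  }, numeric(1))
  expect_equal(which.max(rates), 1L)  # theta = 0
  ## non-increasing up to the quench angle
  expect_true(all(diff(rates[1:55]) <= 0))
  ## independent of tau_internal
  expect_equal(r1_spin_diffusion(sp, cone_motion(30, 1e-12), c_sd = c_sd),
               r1_spin_diffusion(sp, cone_motion(30, 1e-6), c_sd = c_sd))
})

test_that("compute_regime_map agrees with pointwise brute force", {
  sp <- spin_pair()
  th <- c(0, 15, 30, 45, 60, 75, 90)
  ta <- 10^seq(-11, -7, by = 0.5)
  map <- compute_regime_map(sp, theta_grid = th, tau_grid = ta)
  ## brute-force oracle: scalar evaluation through cone_motion objects
  for (i in seq_along(th)) {
    for (j in seq_along(ta)) {
      mo <- cone_motion(th[i], ta[j], tau_macro = 1e-7)
      expect_equal(map$motion_matrix[i, j], r1_motion(sp, mo))
      expect_equal(map$sd_matrix[i, j],
                   r1_spin_diffusion(sp, mo, c_sd = map$c_sd))
    }
  }
  ## calibration honoured on this grid
  expect_equal(max(map$sd_matrix) / max(map$motion_matrix), 10)
  ## sd matrix constant along the tau axis (formulation is tau_int-free)
  expect_equal(map$sd_matrix[, 1], map$sd_matrix[, ncol(map$sd_matrix)])
})

test_that("regime map guards and degenerate grids", {
  sp <- spin_pair()
  expect_error(compute_regime_map(sp, theta_grid = numeric(0)), "non-empty")
  expect_error(compute_regime_map(sp, theta_grid = c(10, 5)), "ascending")
  ## 1x1 grid at theta = 0: motion term is 0, spin diffusion wins (ties
  ## and zeros classify as spin diffusion)
  m0 <- compute_regime_map(sp, theta_grid = 0, tau_grid = 1e-9)
  expect_false(any(m0$dominant))
  bnd <- dominance_boundary(m0)
  expect_true(bnd$none)
  expect_true(is.na(bnd$onset_angle))
  ## c_sd = 0: motion dominates wherever its term is nonzero, so the onset
  ## is the smallest theta with a nonzero motion term
  mz <- compute_regime_map(sp, theta_grid = c(0, 10, 20), tau_grid = 1e-9,
                           c_sd = 0)
  expect_equal(dominance_boundary(mz)$onset_angle, 10)
})

test_that("dominance pattern is invariant to r_HH and gamma rescaling", {
  grids <- list(theta_grid = seq(0, 90, by = 5),
                tau_grid = 10^seq(-12, -6, by = 0.25))
  base <- do.call(compute_regime_map, c(list(spin_pair()), grids))
  for (pair in list(spin_pair(r_hh_angstrom = 3.1),
                    spin_pair(gamma = 1.7e8))) {
    alt <- do.call(compute_regime_map, c(list(pair), grids))
    expect_identical(alt$dominant, base$dominant)
    expect_equal(alt$onset_angle, base$onset_angle)
    expect_equal(alt$tau_window, base$tau_window)
    ## both terms carry d^2: matrix ratios are unchanged
    expect_equal(alt$motion_matrix / alt$sd_matrix,
                 base$motion_matrix / base$sd_matrix, tolerance = 1e-10)
  }
})

test_that("long-format export matches the matrices", {
  map <- compute_regime_map(spin_pair(), theta_grid = c(0, 45, 90),
                            tau_grid = c(1e-10, 1e-9))
  df <- as.data.frame(map)
  expect_equal(nrow(df), 6L)
  expect_named(df, c("theta_deg", "tau_s", "r1_motion_s1", "r1_sd_s1",
                     "dominant"))
  k <- which(df$theta_deg == 45 & df$tau_s == 1e-9)
  expect_equal(df$r1_motion_s1[k], map$motion_matrix["45", 2])
})
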